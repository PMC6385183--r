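Package: gaitasym
Title: Speed-Dependent Gait Asymmetry Analysis for Mouse and Human Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify left-right asymmetries in spatial and temporal
    gait metrics of quadruped (mouse) and biped (human) walkers. Derives
    stride velocity, stride length, step length, swing time and stance time
    from footfall event tables; detects asymmetries within a condition with
    nested-regression curve-sharing F tests over a clinically relevant speed
    range; and quantifies shifts in interlimb coordination between conditions
    with spatial and temporal alternation ratios analyzed by circular
    statistics (resultant vectors, Watson-Williams test). Includes Welch
    summary-statistic t tests for cohort tables, a configurable synthetic
    gait simulator with injectable asymmetries, CSV readers and writers, and
    an end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
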