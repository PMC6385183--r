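---
title: "Quantifying left-right gait asymmetries at walking speed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying left-right gait asymmetries at walking speed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitasym)
```

## The problem

Parkinsonian gait is often asymmetric, and the asymmetries can be spatial
(where the feet land) or temporal (when they land), independently of each
other. Detecting them quantitatively is complicated by the strong speed
dependence of every gait metric: a limb's stride length, swing time and
stance time all change with how fast the animal or person happens to be
walking, and walking speed itself changes with disease and across trials. A
left-right comparison that ignores speed confounds asymmetry with speed
differences; a comparison of raw means is dominated by whichever side
happened to be sampled at higher speeds.

`gaitasym` implements a speed-aware toolkit that works identically for
quadruped (mouse) and biped (human) walkers:

1. **Stride metrics from footfall events.** Each recorded paw/foot contact
   carries a position along the travel axis and the onset times of its
   stance and swing phases. Consecutive contacts of the same limb define a
   gait cycle: stride length (distance between placements), cycle duration
   (stance onset to next stance onset), stance time (stance to swing
   onset), swing time (the remainder), stride velocity (stride length over
   cycle duration). Step length — the distance by which a limb lands in
   front of the opposing homologous limb's most recent placement — is the
   one metric that couples the two sides.
2. **Curve-sharing F tests.** Each metric is regressed on stride velocity,
   and the left and right datasets are compared by asking whether a single
   curve (all parameters shared) fits the pooled data as well as two
   independent curves.
3. **Alternation ratios and circular statistics.** Interlimb coordination
   is expressed as ratios on the unit circle (0.5 = perfect alternation /
   symmetric placement), summarized by resultant vectors and compared
   between conditions with the Watson-Williams test.
4. **Cohort utilities** for human studies: Welch's t from published
   summary triplets, shorter-side re-assignment, subgroup splits, and
   Pearson correlation of asymmetry ratios.

## Regression model families and selection

Metrics are fitted against stride velocity with one of three families, in
the nomenclature commonly used by curve-fitting software:

* linear: $y = b_0 + b_1 v$;
* one-phase association: $y = Y_0 + (P - Y_0)(1 - e^{-K v})$, $K > 0$;
* two-phase association:
  $y = Y_0 + S_f (1 - e^{-K_f v}) + S_s (1 - e^{-K_s v})$, $K_f > K_s > 0$.

The exact functional forms are a package design choice (the workflow this
mirrors is the Prism convention); the two-phase labels are disambiguated by
sorting the rate constants. Model selection (`select_model()`) walks the
ladder from simple to complex and promotes only when the extra
sum-of-squares F test rejects at `alpha_select` (default 0.05, exposed as
configuration; the stringent 0.001 level is reserved for dataset
comparisons, see below). The simplest adequate family is preferred to avoid
overfitting, which would make statistically significant but biologically
irrelevant differences easy to manufacture. `sweep_speed_ranges()` repeats
the selection over windows that progressively omit the slowest (1-unit bins
from 0) and fastest (from 25 down) speeds and reports the widest window over
which a single family is selected consistently; for mouse walking/trotting
data shaped like the default simulator curves this is the 3–16 cm/s window,
and 0.3–1.5 m/s is the corresponding human analysis window.

Stance time is special: it falls hyperbolically with speed, so it is
analyzed on log coordinates, $Y = 1 - \log_{10}(\text{stance})$,
$X = \log_{10}(v) + 1$, with a linear model (`stance_transform()`). Any
fixed log base gives identical F tests for the linear family. Nonlinear fits
use bounded Levenberg–Marquardt least squares (via minpack.lm) with three to
four data-driven starts (anchor values at the extremes of the speed range, a
half-rise heuristic for the rate constant); non-convergence after all starts
is reported honestly and the fit is never used in an F test. Automatic
outlier elimination is deliberately absent from all validated paths.

## The curve-sharing F test

For datasets $A$ and $B$ with a family of $p$ parameters,
$SS_{sep} = SS_A + SS_B$ with $df_{sep} = n_A + n_B - 2p$ from independent
fits, and $SS_{sh}$, $df_{sh} = n_A + n_B - p$ from one fit to the pooled
points. Then

$$F = \frac{(SS_{sh} - SS_{sep}) / p}{SS_{sep} / df_{sep}}$$

is referred to $F(p,\, df_{sep})$. Sharing is all-or-nothing: for the linear
family the test captures slope and intercept together; partial sharing is
not implemented. The default comparison alpha is 0.001 — deliberately
stringent because many strides per subject inflate the effective sample
size (pseudo-replication), and because no multiple-comparison correction is
applied across metrics. If the optimizer leaves $SS_{sh}$ numerically below
$SS_{sep}$ the statistic is clamped to zero with a warning. Two companion
diagnostics guard the regression approach: the Wald–Wolfowitz runs test
(`runs_test()`, normal approximation by default, exact combinatorial
distribution on request) flags systematic deviation of a curve from the
data, and `averaged_analysis()` reruns the comparison on per-subject means
with a paired t test, which removes pseudo-replication at the cost of
collapsing the speed range.

## Alternation ratios and circular statistics

The spatial alternation ratio is step length divided by the opposing limb's
spanning stride length; the temporal alternation ratio is the offset of the
opposing footfall within the reference limb's cycle divided by cycle
duration. Both live on the unit circle — 0 and 1 denote coincident events —
so they are wrapped into $[0,1)$ and mapped to angles $\theta = 2\pi r$.
`circ_summary()` reports the mean direction and the resultant length
$r \in [0,1]$ (strength of clustering), the two quantities drawn in polar
plots. The Watson-Williams test compares mean directions between conditions
at alpha 0.05, with the standard $1 + 3/(8\hat\kappa)$ correction
($\hat\kappa$ from the pooled mean resultant length by Fisher's
approximation); the implementation is guarded in the test suite by a
permutation oracle. Because asymmetries can be speed-gated, `bin_by_speed()`
re-analyzes ratios within bins (mouse default 3–10 and 10–16 cm/s; a
boundary speed joins the upper bin). Each ratio carries the stride velocity
of the cycle-defining (denominator) limb, since the ratio is defined on that
limb's stride.

Two conventions worth noting: step lengths may be negative (limb placed
behind the opposing limb); negatives wrap circularly (a ratio of $-0.1$
becomes $0.9$), which is exactly the behaviour wanted on the circle. Values
with an undefined circular mean (resultant numerically zero, e.g. antipodal
ratios) are flagged rather than silently propagated.

## What the simulator emulates — and what it does not

`gait_profile()` + `generate_trial()` + `make_cohort()` generate footfall
events, not stride tables, so every synthetic dataset exercises the same
extraction code as real data. Per trial a target speed is drawn from the
profile's range and stride speeds jitter log-normally around it (relative SD
`noise$speed`, default 8% mouse / 6% human) — walking trials hold a roughly
steady pace, and large stride-to-stride speed jumps would be unphysiological.
The reference (left) limb advances by the stride-length curve value plus
noise per cycle; the opposing limb is placed at fraction `step_fraction` of
each stride and `phase_offset` of each cycle (both 0.5 for symmetric gait).
Stance is derived as cycle minus swing, never sampled, so the additivity
invariant holds exactly. Asymmetries are injected as changes of one side's
step length (multiplicative or additive) and/or a shift of the temporal
offset, optionally gated to a speed window — emulating, respectively, a
unilateral lesion (one-sided step shortening with intact stride length), a
bilateral lesion (symmetric scaling of stride length and swing curves via
`condition_scales`), and a control cohort (no change between conditions).

Default curve parameters are chosen to be realistic for walking/trotting
C57BL/6 mice (stride length saturating from ~4.5 to ~7.5 cm over
3–16 cm/s, swing 0.11–0.13 s) and adult human overground walking (stride
0.6–1.45 m over 0.3–1.5 m/s, swing ~0.38–0.41 s). Between-subject
variation is a 2% log-normal scaling of the curves, emulating a carefully
matched inbred cohort: the curve-sharing analyses assume subjects act as
their own controls with small within-group variation, and substantially
larger between-subject effects (combined with many strides per subject)
violate that premise — as they would for real data.

The simulator is deliberately not a biomechanical model: no forces, joint
kinematics, diagonal/ipsilateral couplings, freezing, festination or
dyskinesia. Passing scenario tests therefore shows that the statistical
pipeline detects (only) the asymmetries it should under idealized gait with
realistic noise magnitudes; it does not certify performance on pathologies
the generator does not produce.

A useful exactness detail: with zero noise and a *constant* trial speed,
every spatial and temporal ratio is exactly 0.5 for a symmetric profile, in
both pairing directions. With varying speeds the stepping-limb-in-reference-
stride direction remains exactly 0.5 but the reverse direction equals
$L_k/(L_k + L_{k+1})$, which is only 0.5 on average; the definitional
fixtures therefore use a degenerate speed range.

## Numerical and design choices

* Step-length pairing: "most recent opposing placement at or before the
  own stance onset", ties toward the earlier event; placements with no
  preceding opposing event keep `NA` step length (e.g. occluded opposing
  placements), and such records are dropped from ratio analyses and
  counted.
* Model fits require at least one residual degree of freedom; at three
  points only the linear family is attemptable and selection returns it.
* The sweep records windows with fewer than `min_n` points as unusable
  rather than fitting them.
* Welch's t from summary triplets reports the Satterthwaite df both raw
  and rounded (clinical tables print integers); a zero-variance pair with
  unequal means is flagged infinite rather than erroring.
* Asymmetry ratios for clinical correlations default to smaller/larger
  (bounded (0,1], 1 = symmetric) with a signed $(L-R)/(L+R)$ alternative;
  the convention is recorded in the result.
* All randomness flows from a single seed; `make_cohort()` draws subjects
  and trials sequentially from one stream, so identical seeds give
  bit-identical event tables.
* Problem sizes in the test suite are chosen to make Monte-Carlo checks
  sharp but quick: 2000 null replicates for the type-I calibration of the
  curve-sharing test, $10^4$ permutations for the Watson-Williams oracle,
  120 replicates for fit-bias checks.

## A worked mouse example

```{r example, eval = FALSE}
library(gaitasym)

# unilateral scenario: right step length shortened 18% after "lesion"
events <- make_cohort(
  gait_profile("mouse"), n_subjects = 6, n_trials = 4, n_strides = 18,
  condition_asymmetry = list(step_delta = -0.18, side = "right"),
  seed = 73)

report <- run_pipeline(events, analysis_config("mouse"))
report
```

The report lists, per condition, pair and metric, the selected family and
the curve-sharing verdict: in the post-lesion condition only step length
loses curve sharing, while stride length, swing and stance remain shared —
the signature of a unilateral spatial deficit. The alternation section shows
the spatial ratios' mean direction pulled away from 0.5 with the
Watson-Williams test significant between conditions.

## Known limitations

* The curve-sharing test treats strides as independent; it is valid for
  matched within-subject designs with small between-subject variation, and
  the stringent alpha is a mitigation, not a cure, for pseudo-replication.
  Mixed-effects extensions are out of scope.
* Only homologous (left-right) limb pairs are analyzed; diagonal and
  ipsilateral couplings are not.
* The Watson-Williams test assumes comparably concentrated samples; the
  implementation warns when the pooled mean resultant length drops below
  0.45 or samples are smaller than 5.
* Whether the von Mises correction factor was applied by any particular
  external toolbox cannot be known from published F values alone; this
  implementation always applies it and says so in its output structure.
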