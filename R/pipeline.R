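# End-to-end analysis pipeline and report serialization.

#' Analysis configuration
#'
#' Defaults mirror the validated study conditions: curve comparisons at the
#' stringent alpha of 0.001, circular tests at 0.05, mouse speed window
#' 3-16 cm/s (human 0.3-1.5 m/s), speed bins splitting at 10 cm/s.
#'
#' @param species `"mouse"` or `"human"`.
#' @param lo,hi Stride-velocity analysis window; `NULL` for the species
#'   default.
#' @param alpha_compare Curve-sharing F-test level.
#' @param alpha_circular Watson-Williams level.
#' @param model `"auto"` (ladder selection per metric) or a family name
#'   applied to all metrics. Stance time is always analyzed on its
#'   log-transformed coordinates with a linear model.
#' @param bins Speed-bin edges for alternation sub-analyses; `NULL` for the
#'   species default (mouse `c(3, 10, 16)`, human `c(0.3, 0.9, 1.5)`).
#' @param metrics Stride metrics to analyze.
#' @param alpha_select Model-promotion level for `model = "auto"`.
#' @param seed Optional seed recorded in the report.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(species = c("mouse", "human"),
                            lo = NULL, hi = NULL,
                            alpha_compare = 0.001, alpha_circular = 0.05,
                            model = "auto", bins = NULL,
                            metrics = c("step_length", "stride_length",
                                        "swing_time", "stance_time"),
                            alpha_select = 0.05, seed = NULL) {
  species <- match.arg(species)
  if (is.null(lo)) lo <- if (species == "mouse") 3 else 0.3
  if (is.null(hi)) hi <- if (species == "mouse") 16 else 1.5
  if (is.null(bins)) {
    bins <- if (species == "mouse") c(3, 10, 16) else c(0.3, 0.9, 1.5)
  }
  stopifnot(lo < hi, alpha_compare > 0, alpha_compare < 1,
            alpha_circular > 0, alpha_circular < 1)
  structure(list(species = species, lo = lo, hi = hi,
                 alpha_compare = alpha_compare,
                 alpha_circular = alpha_circular, model = model,
                 bins = bins, metrics = metrics,
                 alpha_select = alpha_select, seed = seed),
            class = "analysis_config")
}

#' Load an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [analysis_config()]; absent keys keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return An [analysis_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(analysis_config, vals)
}

metric_xy <- function(records, metric, limb) {
  sub <- records[records$limb == limb, , drop = FALSE]
  if (metric == "stance_time") {
    stance_transform(sub$stride_velocity, sub$stance_time)
  } else {
    out <- data.frame(x = sub$stride_velocity, y = sub[[metric]])
    out[is.finite(out$y), , drop = FALSE]
  }
}

pick_model <- function(data_a, data_b, metric, config) {
  if (metric == "stance_time") return(model_spec("log_linear_stance"))
  if (config$model != "auto") return(model_spec(config$model))
  pooled <- rbind(data_a, data_b)
  select_model(pooled$x, pooled$y, alpha_select = config$alpha_select)$model
}

#' Run the full asymmetry analysis pipeline
#'
#' Executes, per condition, metric and homologous pair: speed-window
#' filtering, model selection (or the configured family), the left-vs-right
#' curve-sharing F test; per limb: the between-condition step-length
#' comparison; and per pair: spatial and temporal alternation ratios with
#' Watson-Williams tests between conditions, over the whole window and per
#' speed bin. Every verdict records the model used and the number of points
#' per fit.
#'
#' @param events Footfall-event data frame (e.g. from [read_footfalls()] or
#'   [make_cohort()]).
#' @param config An [analysis_config()].
#' @return Object of class `gait_report`: list with `config`,
#'   `side_comparisons`, `condition_comparisons`, `alternation` and `log`
#'   entries.
#' @export
run_pipeline <- function(events, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  dataset <- strides_from_footfalls(events, config$species)
  dataset <- filter_speed_range(dataset, config$lo, config$hi, quiet = TRUE)
  records <- dataset$records
  pairs <- species_pairs(config$species)
  conditions <- unique(records$condition)
  log <- list()

  side_rows <- list()
  for (cond in conditions) {
    rc <- records[records$condition == cond, , drop = FALSE]
    for (pn in names(pairs)) {
      for (metric in config$metrics) {
        da <- metric_xy(rc, metric, pairs[[pn]]["left"])
        db <- metric_xy(rc, metric, pairs[[pn]]["right"])
        if (nrow(da) < 8 || nrow(db) < 8) {
          log[[length(log) + 1L]] <- list(
            stage = "side_comparison", condition = cond, pair = pn,
            metric = metric, skipped = "too few points",
            n = c(nrow(da), nrow(db)))
          next
        }
        model <- pick_model(da, db, metric, config)
        cmp <- tryCatch(compare_curves(da, db, model, config$alpha_compare),
                        error = function(e) e)
        if (inherits(cmp, "error")) {
          log[[length(log) + 1L]] <- list(
            stage = "side_comparison", condition = cond, pair = pn,
            metric = metric, error = conditionMessage(cmp))
          next
        }
        side_rows[[length(side_rows) + 1L]] <- data.frame(
          condition = cond, pair = pn, metric = metric,
          model = model$family, n_left = nrow(da), n_right = nrow(db),
          F = cmp$F, df_num = cmp$df_num, df_den = cmp$df_den, p = cmp$p,
          shared = cmp$shared, stringsAsFactors = FALSE)
      }
    }
  }

  cond_rows <- list()
  if (length(conditions) >= 2) {
    for (limb in species_limbs(config$species)) {
      for (ci in 2:length(conditions)) {
        r1 <- records[records$condition == conditions[1], , drop = FALSE]
        r2 <- records[records$condition == conditions[ci], , drop = FALSE]
        da <- metric_xy(r1, "step_length", limb)
        db <- metric_xy(r2, "step_length", limb)
        if (nrow(da) < 8 || nrow(db) < 8) next
        model <- pick_model(da, db, "step_length", config)
        cmp <- tryCatch(compare_curves(da, db, model, config$alpha_compare),
                        error = function(e) NULL)
        if (is.null(cmp)) next
        cond_rows[[length(cond_rows) + 1L]] <- data.frame(
          limb = limb, metric = "step_length",
          condition_a = conditions[1], condition_b = conditions[ci],
          model = model$family, F = cmp$F, p = cmp$p, shared = cmp$shared,
          stringsAsFactors = FALSE)
      }
    }
  }

  alt <- list()
  ev_window <- events  # ratios are speed-filtered via their attached speeds
  for (pn in names(pairs)) {
    limbs <- pairs[[pn]]
    series <- list()
    for (cond in conditions) {
      ec <- ev_window[ev_window$condition == cond, , drop = FALSE]
      ea <- ec[ec$limb == limbs["right"], , drop = FALSE]
      eb <- ec[ec$limb == limbs["left"], , drop = FALSE]
      for (kind in c("spatial", "temporal")) {
        s <- if (kind == "spatial") spatial_ratios(ea, eb) else
          temporal_ratios(ea, eb)
        keep <- s$speed >= config$lo & s$speed <= config$hi
        series[[paste(cond, kind, sep = ".")]] <-
          new_alternation_series(s$ratio[keep], s$speed[keep], kind, pn, cond)
      }
    }
    pair_out <- list(summaries = lapply(series, circ_summary))
    if (length(conditions) >= 2) {
      tests <- list()
      for (kind in c("spatial", "temporal")) {
        s1 <- series[[paste(conditions[1], kind, sep = ".")]]
        for (ci in 2:length(conditions)) {
          s2 <- series[[paste(conditions[ci], kind, sep = ".")]]
          key <- paste(kind, conditions[ci], sep = ".")
          tests[[key]] <- tryCatch(
            suppressWarnings(watson_williams(s1, s2, config$alpha_circular)),
            error = function(e) list(error = conditionMessage(e)))
          bins1 <- bin_by_speed(s1, config$bins)
          bins2 <- bin_by_speed(s2, config$bins)
          for (bn in names(bins1)) {
            tests[[paste(key, bn, sep = " ")]] <- tryCatch(
              suppressWarnings(watson_williams(bins1[[bn]], bins2[[bn]],
                                               config$alpha_circular)),
              error = function(e) list(error = conditionMessage(e)))
          }
        }
      }
      pair_out$tests <- tests
    }
    alt[[pn]] <- pair_out
  }

  structure(list(config = config,
                 side_comparisons = if (length(side_rows))
                   do.call(rbind, side_rows) else NULL,
                 condition_comparisons = if (length(cond_rows))
                   do.call(rbind, cond_rows) else NULL,
                 alternation = alt, log = log,
                 n_strides = nrow(records)),
            class = "gait_report")
}

#' @export
print.gait_report <- function(x, ...) {
  cat("<gait_report> ", x$config$species, ", window [", x$config$lo, ", ",
      x$config$hi, "], ", x$n_strides, " strides analyzed\n", sep = "")
  if (!is.null(x$side_comparisons)) {
    cat("\nLeft vs right curve-sharing tests (alpha = ",
        x$config$alpha_compare, "):\n", sep = "")
    df <- x$side_comparisons
    df$F <- signif(df$F, 4); df$p <- signif(df$p, 4)
    print(df, row.names = FALSE)
  }
  if (!is.null(x$condition_comparisons)) {
    cat("\nBetween-condition step-length tests:\n")
    df <- x$condition_comparisons
    df$F <- signif(df$F, 4); df$p <- signif(df$p, 4)
    print(df, row.names = FALSE)
  }
  for (pn in names(x$alternation)) {
    tests <- x$alternation[[pn]]$tests
    if (is.null(tests)) next
    cat("\nAlternation-ratio Watson-Williams tests (", pn, " pair):\n",
        sep = "")
    for (nm in names(tests)) {
      tt <- tests[[nm]]
      if (!is.null(tt$error)) {
        cat("  ", nm, ": not testable (", tt$error, ")\n", sep = "")
      } else {
        cat("  ", nm, ": F = ", signif(tt$F, 4), ", p = ", signif(tt$p, 4),
            if (tt$significant) " *", "\n", sep = "")
      }
    }
  }
  invisible(x)
}

#' Serialize a pipeline report
#'
#' Writes the curve-comparison tables as CSV and the full report (including
#' circular summaries and test metadata, at full precision) as JSON.
#'
#' @param report A `gait_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "gait_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character()
  if (!is.null(report$side_comparisons)) {
    f <- file.path(dir, "side_comparisons.csv")
    utils::write.csv(report$side_comparisons, f, row.names = FALSE)
    written <- c(written, f)
  }
  if (!is.null(report$condition_comparisons)) {
    f <- file.path(dir, "condition_comparisons.csv")
    utils::write.csv(report$condition_comparisons, f, row.names = FALSE)
    written <- c(written, f)
  }
  strip <- function(x) {
    if (inherits(x, "circ_summary")) {
      unclass(x)
    } else if (inherits(x, "watson_williams")) {
      x[c("F", "df_num", "df_den", "p", "correction", "kappa",
          "significant")]
    } else if (is.list(x)) {
      lapply(x, strip)
    } else {
      x
    }
  }
  f <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(config = unclass(report$config),
         side_comparisons = report$side_comparisons,
         condition_comparisons = report$condition_comparisons,
         alternation = strip(report$alternation),
         log = report$log),
    f, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  written <- c(written, f)
  invisible(written)
}
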