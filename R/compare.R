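# Curve-sharing F test between two datasets, runs test, and the per-subject
# averaged analysis.

#' Curve-sharing F test between two datasets
#'
#' Tests whether two datasets (e.g. left vs right limb, or baseline vs
#' lesioned condition) follow the same metric-vs-speed curve. One parameter
#' set is fitted to the pooled points (shared fit) and independent sets to
#' each dataset (separate fits); the extra sum-of-squares F statistic
#' \deqn{F = \frac{(SS_{shared} - SS_{sep})/(df_{shared} - df_{sep})}
#'            {SS_{sep}/df_{sep}}}
#' with `SS_sep = SS_A + SS_B`, `df_sep = n_A + n_B - 2p`,
#' `df_shared = n_A + n_B - p`, is referred to the F distribution. Sharing
#' all `p` parameters is tested, so for the linear family both slope and
#' intercept are compared. The stringent default `alpha = 0.001` guards
#' against biologically meaningless rejections driven by many strides per
#' subject.
#'
#' @param data_a,data_b Data frames with columns `x` (speed) and `y`
#'   (metric), both non-empty after speed filtering.
#' @param model A [model_spec()] shared by both datasets.
#' @param alpha Significance level for the "curves differ" verdict.
#' @return Object of class `curve_comparison`: `F`, `df_num`, `df_den`, `p`,
#'   `alpha`, `shared` (logical verdict that one curve suffices),
#'   `shared_fit`, `fit_a`, `fit_b`.
#' @export
compare_curves <- function(data_a, data_b, model = model_spec("linear"),
                           alpha = 0.001) {
  stopifnot(is.data.frame(data_a), is.data.frame(data_b))
  data_a <- data_a[is.finite(data_a$x) & is.finite(data_a$y), , drop = FALSE]
  data_b <- data_b[is.finite(data_b$x) & is.finite(data_b$y), , drop = FALSE]
  if (!nrow(data_a) || !nrow(data_b)) stop("both datasets must be non-empty")
  p <- model$n_params
  n_tot <- nrow(data_a) + nrow(data_b)
  if (n_tot - 2 * p <= 0) {
    stop("not enough points for separate fits (df_sep <= 0)")
  }
  fit_a <- fit_model(data_a$x, data_a$y, model)
  fit_b <- fit_model(data_b$x, data_b$y, model)
  if (!fit_a$converged || !fit_b$converged) {
    stop("separate fit did not converge; cannot run the curve-sharing test")
  }
  pooled <- rbind(data_a[c("x", "y")], data_b[c("x", "y")])
  shared_fit <- fit_model(pooled$x, pooled$y, model)
  if (!shared_fit$converged) stop("shared fit did not converge")
  ss_sep <- fit_a$ss_resid + fit_b$ss_resid
  df_sep <- n_tot - 2 * p
  df_shared <- n_tot - p
  f <- ((shared_fit$ss_resid - ss_sep) / (df_shared - df_sep)) /
    (ss_sep / df_sep)
  if (f < 0) {
    warning("SS_shared < SS_separate numerically; F clamped to 0")
    f <- 0
  }
  p_val <- stats::pf(f, p, df_sep, lower.tail = FALSE)
  structure(list(F = f, df_num = p, df_den = df_sep, p = p_val,
                 alpha = alpha, shared = p_val >= alpha,
                 shared_fit = shared_fit, fit_a = fit_a, fit_b = fit_b),
            class = "curve_comparison")
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat("<curve_comparison> ", x$fit_a$model$family,
      ": F(", x$df_num, ", ", x$df_den, ") = ", signif(x$F, 4),
      ", p = ", signif(x$p, 4),
      if (x$shared) " -> shared curve" else " -> curves differ",
      " (alpha = ", x$alpha, ")\n", sep = "")
  invisible(x)
}

# Exact null distribution of the number of runs given n1 values above and
# n2 below the reference (all arrangements equally likely).
runs_exact_pmf <- function(n1, n2) {
  n <- n1 + n2
  r <- 2:n
  pr <- vapply(r, function(ri) {
    if (ri %% 2 == 0) {
      k <- ri / 2
      2 * choose(n1 - 1, k - 1) * choose(n2 - 1, k - 1)
    } else {
      k <- (ri - 1) / 2
      choose(n1 - 1, k - 1) * choose(n2 - 1, k) +
        choose(n1 - 1, k) * choose(n2 - 1, k - 1)
    }
  }, 0) / choose(n, n1)
  stats::setNames(pr, r)
}

#' Wald-Wolfowitz runs test for randomness about a reference value
#'
#' Tests whether a sequence (e.g. residuals in stride order, or residuals of
#' a fitted curve ordered by speed) deviates systematically from a reference
#' value. Values equal to the reference are dropped. The default reports the
#' large-sample normal approximation
#' `Z = (R - mu_R) / sigma_R` with `mu_R = 2 n1 n2 / n + 1` and
#' `sigma_R^2 = 2 n1 n2 (2 n1 n2 - n) / (n^2 (n - 1))`;
#' `method = "exact"` uses the exact combinatorial distribution of the
#' number of runs (two-sided: twice the smaller tail, capped at 1).
#'
#' @param values Numeric sequence in its meaningful order.
#' @param reference Reference level (default: the mean of `values`).
#' @param method `"normal"` (default) or `"exact"`.
#' @return Object of class `runs_test`: `n_runs`, `n_above`, `n_below`, `Z`
#'   (normal method), `p`, `method`.
#' @export
runs_test <- function(values, reference = mean(values),
                      method = c("normal", "exact")) {
  method <- match.arg(method)
  s <- sign(values - reference)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  n <- n1 + n2
  if (n < 2) stop("need at least 2 values not equal to the reference")
  if (n1 == 0 || n2 == 0) {
    stop("all values on one side of the reference; runs test undefined")
  }
  r_obs <- 1L + sum(diff(s) != 0)
  if (method == "normal") {
    mu <- 2 * n1 * n2 / n + 1
    sigma2 <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
    z <- (r_obs - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    structure(list(n_runs = r_obs, n_above = n1, n_below = n2,
                   Z = z, p = min(p, 1), method = "normal"),
              class = "runs_test")
  } else {
    pmf <- runs_exact_pmf(n1, n2)
    r <- as.integer(names(pmf))
    p_lo <- sum(pmf[r <= r_obs])
    p_hi <- sum(pmf[r >= r_obs])
    structure(list(n_runs = r_obs, n_above = n1, n_below = n2,
                   Z = NA_real_, p = min(1, 2 * min(p_lo, p_hi)),
                   method = "exact"),
              class = "runs_test")
  }
}

#' @export
print.runs_test <- function(x, ...) {
  if (!is.null(x$error)) {
    cat("<runs_test> undefined: ", x$error, "\n", sep = "")
    return(invisible(x))
  }
  cat("<runs_test> runs = ", x$n_runs, " (", x$n_above, " above, ",
      x$n_below, " below)", sep = "")
  if (x$method == "normal") cat(", Z = ", signif(x$Z, 4), sep = "")
  cat(", p = ", signif(x$p, 4), " [", x$method, "]\n", sep = "")
  invisible(x)
}

#' Per-subject averaged left/right analysis
#'
#' Guards against pseudo-replication: averages a metric and the stride
#' velocity per subject and side, reruns the curve-sharing test on the
#' averaged points, and compares sides with a two-tailed paired t test.
#' Subjects missing a side are excluded and reported.
#'
#' @param dataset A [gait_dataset()] or stride data frame.
#' @param metric Stride-metric column name (e.g. `"step_length"`).
#' @param pair Homologous pair name (`"hind"`, `"fore"` or `"legs"`).
#' @param model Model for the averaged-point comparison (default linear;
#'   averaged datasets are few points, so the simplest family is used).
#' @param alpha Curve-comparison significance level.
#' @return List with `means` (subject x side table of mean metric and mean
#'   speed), `comparison` ([compare_curves()] on averaged points), `t_test`
#'   (paired t), `excluded` (subjects lacking a side).
#' @export
averaged_analysis <- function(dataset, metric, pair = "hind",
                              model = model_spec("linear"), alpha = 0.001) {
  records <- if (inherits(dataset, "gait_dataset")) dataset$records else dataset
  species <- if (inherits(dataset, "gait_dataset")) dataset$species else
    if (all(records$limb %in% c("L", "R"))) "human" else "mouse"
  limbs <- species_pairs(species)[[pair]]
  if (is.null(limbs)) stop("unknown pair '", pair, "' for species ", species)
  sub <- records[records$limb %in% limbs & is.finite(records[[metric]]), ]
  agg <- stats::aggregate(sub[c(metric, "stride_velocity")],
                          by = list(subject_id = sub$subject_id,
                                    limb = sub$limb),
                          FUN = mean)
  left <- agg[agg$limb == limbs["left"], ]
  right <- agg[agg$limb == limbs["right"], ]
  common <- intersect(left$subject_id, right$subject_id)
  excluded <- setdiff(unique(agg$subject_id), common)
  if (length(excluded)) {
    message("excluded subject(s) missing a side: ",
            paste(excluded, collapse = ", "))
  }
  left <- left[match(common, left$subject_id), ]
  right <- right[match(common, right$subject_id), ]
  cmp <- compare_curves(
    data.frame(x = left$stride_velocity, y = left[[metric]]),
    data.frame(x = right$stride_velocity, y = right[[metric]]),
    model, alpha)
  d <- left[[metric]] - right[[metric]]
  tt <- if (stats::sd(d) == 0) {
    # degenerate paired t: identical sides give t = 0, p = 1
    list(statistic = c(t = 0), parameter = c(df = length(d) - 1),
         p.value = if (mean(d) == 0) 1 else 0, estimate = mean(d))
  } else {
    stats::t.test(left[[metric]], right[[metric]], paired = TRUE)
  }
  means <- data.frame(subject_id = common,
                      left = left[[metric]], right = right[[metric]],
                      speed_left = left$stride_velocity,
                      speed_right = right$stride_velocity)
  list(means = means, comparison = cmp, t_test = tt, excluded = excluded)
}
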