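# Speed-dependent regression: model families in the curve-fitting convention
# of common graphing software (linear, one-phase association, two-phase
# association) plus the log-linear stance transform.

#' Specify a regression model family
#'
#' Families used for gait metric vs stride velocity curves:
#' * `linear`: `y = intercept + slope * x` (2 parameters)
#' * `one_phase_assoc`: `y = Y0 + (Plateau - Y0) * (1 - exp(-K * x))`
#'   (3 parameters, `K > 0`)
#' * `two_phase_assoc`: `y = Y0 + SpanFast * (1 - exp(-KFast * x)) +
#'   SpanSlow * (1 - exp(-KSlow * x))` (5 parameters, `KFast > KSlow > 0`)
#' * `log_linear_stance`: linear model on log-transformed stance/speed
#'   coordinates (see [stance_transform()]; 2 parameters)
#'
#' @param family One of the family names above.
#' @return An object of class `model_spec` with fields `family`, `n_params`
#'   and parameter names.
#' @export
model_spec <- function(family = c("linear", "one_phase_assoc",
                                  "two_phase_assoc", "log_linear_stance")) {
  family <- match.arg(family)
  par_names <- switch(family,
    linear = c("intercept", "slope"),
    one_phase_assoc = c("Y0", "Plateau", "K"),
    two_phase_assoc = c("Y0", "SpanFast", "KFast", "SpanSlow", "KSlow"),
    log_linear_stance = c("intercept", "slope"))
  structure(list(family = family, n_params = length(par_names),
                 par_names = par_names),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$family, " (", x$n_params, " parameters: ",
      paste(x$par_names, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Evaluate a model family at given speeds
#'
#' @param model A [model_spec()].
#' @param params Numeric parameter vector of length `model$n_params`, in the
#'   order given by `model$par_names`.
#' @param x Speed values.
#' @return Predicted metric values.
#' @export
#' @examples
#' eval_model(model_spec("one_phase_assoc"), c(0.6, 0.1, 0.3), 5)
eval_model <- function(model, params, x) {
  stopifnot(inherits(model, "model_spec"), length(params) == model$n_params)
  p <- unname(params)
  switch(model$family,
    linear = ,
    log_linear_stance = p[1] + p[2] * x,
    one_phase_assoc = {
      if (p[3] <= 0) stop("rate constant K must be positive")
      p[1] + (p[2] - p[1]) * (1 - exp(-p[3] * x))
    },
    two_phase_assoc = {
      if (p[3] <= 0 || p[5] <= 0) stop("rate constants must be positive")
      p[1] + p[2] * (1 - exp(-p[3] * x)) + p[4] * (1 - exp(-p[5] * x))
    })
}

fit_linear <- function(x, y) {
  fit <- stats::lm.fit(cbind(1, x), y)
  list(params = c(fit$coefficients[1], fit$coefficients[2]),
       ss = sum(fit$residuals^2), converged = TRUE)
}

# Data-driven starting values; multi-start over rate-constant scalings.
one_phase_starts <- function(x, y, scales = c(0.3, 1, 3)) {
  y0 <- y[which.min(x)]
  yp <- y[which.max(x)]
  half <- (y0 + yp) / 2
  xh <- x[which.min(abs(y - half))]
  k0 <- log(2) / max(xh - min(x), diff(range(x)) / 10, 1e-6)
  lapply(scales, function(s) list(Y0 = y0, Plateau = yp, K = k0 * s))
}

try_nls <- function(formula, data, start, lower) {
  suppressWarnings(tryCatch({
    fit <- minpack.lm::nlsLM(formula, data = data, start = start,
                             lower = lower,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200, ftol = 1e-12, ptol = 1e-12))
    list(params = stats::coef(fit), ss = sum(stats::residuals(fit)^2),
         converged = TRUE)
  }, error = function(e) NULL))
}

#' Fit a gait-metric curve by least squares
#'
#' Linear families are solved exactly; the exponential association families
#' use bounded Levenberg-Marquardt least squares with multiple data-driven
#' starts (rate constants constrained positive; for the two-phase family the
#' fast/slow labels are resolved by sorting `KFast > KSlow`). No automatic
#' outlier elimination is performed.
#'
#' @param x,y Speed and metric values (equal length, `length(x) >
#'   model$n_params`).
#' @param model A [model_spec()].
#' @param runs Attach a [runs_test()] on the residuals ordered by `x`
#'   (reference 0), to flag systematic deviation of the curve from the data.
#' @return An object of class `gait_fit`: fields `model`, `params`,
#'   `ss_resid`, `n`, `df`, `converged`, `fitted`, `x`, `y` and optionally
#'   `runs_test`. Non-convergence after all restarts is reported honestly via
#'   `converged = FALSE`.
#' @export
fit_model <- function(x, y, model, runs = FALSE) {
  stopifnot(inherits(model, "model_spec"), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n <= model$n_params) {
    stop("need more points (", n, ") than parameters (", model$n_params, ")")
  }
  res <- switch(model$family,
    linear = ,
    log_linear_stance = fit_linear(x, y),
    one_phase_assoc = {
      dat <- data.frame(x = x, y = y)
      fits <- lapply(one_phase_starts(x, y), function(st) {
        try_nls(y ~ Y0 + (Plateau - Y0) * (1 - exp(-K * x)), dat, st,
                lower = c(Y0 = -Inf, Plateau = -Inf, K = 1e-8))
      })
      fits <- Filter(Negate(is.null), fits)
      if (length(fits)) fits[[which.min(vapply(fits, `[[`, 0, "ss"))]] else
        list(params = rep(NA_real_, 3), ss = NA_real_, converged = FALSE)
    },
    two_phase_assoc = {
      dat <- data.frame(x = x, y = y)
      base <- fit_model(x, y, model_spec("one_phase_assoc"))
      k1 <- if (base$converged) unname(base$params["K"]) else
        2 / max(diff(range(x)), 1e-6)
      span <- if (base$converged) {
        unname(base$params["Plateau"] - base$params["Y0"])
      } else {
        diff(range(y))
      }
      y0 <- y[which.min(x)]
      starts <- list(
        list(Y0 = y0, SpanFast = 0.7 * span, KFast = 3 * k1,
             SpanSlow = 0.3 * span, KSlow = 0.3 * k1),
        list(Y0 = y0, SpanFast = 0.5 * span, KFast = 5 * k1,
             SpanSlow = 0.5 * span, KSlow = 0.5 * k1),
        list(Y0 = y0, SpanFast = 0.9 * span, KFast = 2 * k1,
             SpanSlow = 0.1 * span, KSlow = 0.1 * k1),
        list(Y0 = y0, SpanFast = 0.95 * span, KFast = k1,
             SpanSlow = 0.05 * span, KSlow = k1 / 3))
      fits <- lapply(starts, function(st) {
        try_nls(y ~ Y0 + SpanFast * (1 - exp(-KFast * x)) +
                  SpanSlow * (1 - exp(-KSlow * x)), dat, st,
                lower = c(Y0 = -Inf, SpanFast = -Inf, KFast = 1e-8,
                          SpanSlow = -Inf, KSlow = 1e-8))
      })
      fits <- Filter(Negate(is.null), fits)
      if (length(fits)) {
        best <- fits[[which.min(vapply(fits, `[[`, 0, "ss"))]]
        p <- best$params
        if (p["KFast"] < p["KSlow"]) {  # undo label switching
          p[c("SpanFast", "KFast", "SpanSlow", "KSlow")] <-
            p[c("SpanSlow", "KSlow", "SpanFast", "KFast")]
        }
        best$params <- p
        best
      } else {
        list(params = rep(NA_real_, 5), ss = NA_real_, converged = FALSE)
      }
    })
  params <- stats::setNames(as.numeric(res$params), model$par_names)
  out <- structure(list(model = model, params = params,
                        ss_resid = res$ss, n = n, df = n - model$n_params,
                        converged = isTRUE(res$converged),
                        x = x, y = y,
                        fitted = if (isTRUE(res$converged))
                          eval_model(model, params, x) else rep(NA_real_, n)),
                   class = "gait_fit")
  if (runs && out$converged) {
    ord <- order(x)
    out$runs_test <- tryCatch(
      runs_test((y - out$fitted)[ord], reference = 0),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "runs_test"))
  }
  out
}

#' @export
print.gait_fit <- function(x, ...) {
  cat("<gait_fit> ", x$model$family,
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  print(signif(x$params, 6))
  cat("  n = ", x$n, ", df = ", x$df, ", SS_resid = ",
      signif(x$ss_resid, 6), "\n", sep = "")
  invisible(x)
}

#' Extra sum-of-squares F test between nested fits
#'
#' Compares a simpler against a more complex model fitted to the same data:
#' `F = ((SS_s - SS_c) / (df_s - df_c)) / (SS_c / df_c)`, with the p-value
#' from the upper tail of the F distribution. A numerically negative
#' numerator (optimizer noise) is clamped to `F = 0`.
#'
#' @param simple,complex Converged [fit_model()] results on the same data,
#'   with `complex` having more parameters.
#' @return List with `F`, `df_num`, `df_den`, `p`.
#' @export
extra_ss_ftest <- function(simple, complex) {
  stopifnot(inherits(simple, "gait_fit"), inherits(complex, "gait_fit"))
  if (!simple$converged || !complex$converged) {
    stop("both fits must have converged")
  }
  if (simple$n != complex$n) stop("fits must share the same data")
  if (complex$model$n_params <= simple$model$n_params) {
    stop("'complex' must have more parameters than 'simple'")
  }
  if (complex$df <= 0) stop("complex fit has no residual degrees of freedom")
  df_num <- simple$df - complex$df
  f <- ((simple$ss_resid - complex$ss_resid) / df_num) /
    (complex$ss_resid / complex$df)
  f <- max(f, 0)
  list(F = f, df_num = df_num, df_den = complex$df,
       p = stats::pf(f, df_num, complex$df, lower.tail = FALSE))
}

#' Default model-selection ladder
#'
#' Simple-to-complex order used when picking the family for a metric.
#' @return List of [model_spec()] objects.
#' @export
model_ladder <- function() {
  list(model_spec("linear"), model_spec("one_phase_assoc"),
       model_spec("two_phase_assoc"))
}

#' Select the simplest adequate model family
#'
#' Walks a simple-to-complex ladder, promoting to the next family only when
#' the extra sum-of-squares F test rejects the simpler fit at
#' `alpha_select`. The simplest non-rejected family is returned, guarding
#' against overfitting. Families with no residual degrees of freedom on the
#' data are skipped.
#'
#' @inheritParams fit_model
#' @param ladder Ordered list of [model_spec()] (default [model_ladder()]).
#' @param alpha_select Promotion threshold (default 0.05).
#' @return List with `model` (the selected [model_spec()]), `fit`
#'   (its [fit_model()] result) and `steps` (per-comparison F/p trail).
#' @export
select_model <- function(x, y, ladder = model_ladder(), alpha_select = 0.05) {
  usable <- Filter(function(m) length(x) - m$n_params >= 1, ladder)
  if (!length(usable)) stop("no model in the ladder is fittable on ",
                            length(x), " points")
  current <- fit_model(x, y, usable[[1]])
  if (!current$converged) stop("simplest model failed to converge")
  steps <- list()
  for (m in usable[-1]) {
    cand <- fit_model(x, y, m)
    if (!cand$converged) break
    test <- extra_ss_ftest(current, cand)
    steps[[m$family]] <- test
    if (test$p < alpha_select) current <- cand else break
  }
  list(model = current$model, fit = current, steps = steps)
}

#' Sweep speed windows and record the selected family in each
#'
#' Scans windows formed by omitting increasing ranges of the slowest speeds
#' (lower bound rising in 1-unit bins) and/or of the highest speeds (upper
#' bound falling in 1-unit bins), selecting a model family in each window.
#' Identifies the widest window over which a single family is consistently
#' selected, i.e. the window and all grid windows nested inside it agree.
#'
#' @inheritParams select_model
#' @param lo_values,hi_values Candidate window bounds (defaults `0:12` and
#'   `25:16`, the mouse convention; pass your own for human speeds).
#' @param min_n Windows with fewer points than this are skipped (recorded
#'   with `NA` family).
#' @return List with `grid` (data frame of lo, hi, n, selected family) and
#'   `window`/`family` for the widest consistent window (`NULL` when none).
#' @export
sweep_speed_ranges <- function(x, y, ladder = model_ladder(),
                               alpha_select = 0.05,
                               lo_values = 0:12, hi_values = 25:16,
                               min_n = 8) {
  grid <- expand.grid(lo = lo_values, hi = hi_values)
  grid <- grid[grid$lo < grid$hi, , drop = FALSE]
  pick <- function(lo, hi) {
    keep <- x >= lo & x <= hi
    if (sum(keep) < min_n) return(list(n = sum(keep), family = NA_character_))
    sel <- tryCatch(select_model(x[keep], y[keep], ladder, alpha_select),
                    error = function(e) NULL)
    list(n = sum(keep),
         family = if (is.null(sel)) NA_character_ else sel$model$family)
  }
  res <- Map(pick, grid$lo, grid$hi)
  grid$n <- vapply(res, `[[`, 0, "n")
  grid$family <- vapply(res, `[[`, "", "family")
  ok <- !is.na(grid$family)
  best <- NULL
  if (any(ok)) {
    width <- grid$hi - grid$lo
    for (i in order(-width)) {
      if (!ok[i]) next
      inside <- ok & grid$lo >= grid$lo[i] & grid$hi <= grid$hi[i]
      if (all(grid$family[inside] == grid$family[i])) {
        best <- list(window = c(lo = grid$lo[i], hi = grid$hi[i]),
                     family = grid$family[i])
        break
      }
    }
  }
  list(grid = grid, window = best$window, family = best$family)
}

#' Log-transform stance time against speed
#'
#' Stance time shortens hyperbolically with speed; on the transformed
#' coordinates `Y = 1 - log10(stance time)`, `X = log10(speed) + 1` the
#' relationship is well captured by a linear model, for mouse and human
#' alike. Records with non-positive stance time or speed are excluded and
#' counted. Any fixed log base yields identical curve-sharing F tests for
#' the linear family; base 10 is used.
#'
#' @param speed,stance_time Positive stride velocities and stance times.
#' @return Data frame with `x`, `y`; attribute `n_excluded`.
#' @seealso [stance_backtransform()]
#' @export
stance_transform <- function(speed, stance_time) {
  stopifnot(length(speed) == length(stance_time))
  ok <- is.finite(speed) & is.finite(stance_time) & speed > 0 & stance_time > 0
  out <- data.frame(x = log10(speed[ok]) + 1, y = 1 - log10(stance_time[ok]))
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Invert the stance-time log transform
#'
#' @param x,y Transformed coordinates from [stance_transform()].
#' @return Data frame with `speed` and `stance_time`.
#' @export
stance_backtransform <- function(x, y) {
  data.frame(speed = 10^(x - 1), stance_time = 10^(1 - y))
}
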