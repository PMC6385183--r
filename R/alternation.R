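# Spatial and temporal alternation ratios: interlimb coordination expressed
# as circular data on [0,1), where 0 and 1 both denote coincident events and
# 0.5 denotes perfect alternation.

wrap_unit <- function(x) x - floor(x)

new_alternation_series <- function(ratio, speed, kind, limb_pair = NA,
                                   condition = NA) {
  stopifnot(length(ratio) == length(speed))
  structure(data.frame(ratio = wrap_unit(ratio), speed = speed),
            kind = kind, limb_pair = limb_pair, condition = condition,
            class = c("alternation_series", "data.frame"))
}

#' @export
print.alternation_series <- function(x, ...) {
  cat("<alternation_series> ", attr(x, "kind"), ", ", nrow(x), " ratios",
      if (!is.na(attr(x, "limb_pair"))) paste0(", pair ", attr(x, "limb_pair")),
      if (!is.na(attr(x, "condition"))) paste0(", condition ",
                                               attr(x, "condition")),
      "\n", sep = "")
  if (nrow(x)) {
    s <- circ_summary(x)
    cat("  circular mean ratio ", signif(s$mean_ratio, 4), ", r = ",
        signif(s$r, 4), "\n", sep = "")
  }
  invisible(x)
}

# Shared per-trial machinery. ref = cycle-defining limb B, opp = stepping
# limb A; both single-limb, single-trial event tables.
trial_spatial_ratios <- function(events_a, events_b) {
  a <- events_a[order(events_a$stance_onset), , drop = FALSE]
  b <- events_b[order(events_b$stance_onset), , drop = FALSE]
  if (nrow(a) < 1 || nrow(b) < 2) {
    return(list(ratio = numeric(), speed = numeric(), n_skipped = 0L))
  }
  j <- findInterval(a$stance_onset, b$stance_onset)
  ratio <- speed <- rep(NA_real_, nrow(a))
  skipped <- 0L
  for (i in seq_len(nrow(a))) {
    if (j[i] < 1L || j[i] >= nrow(b)) next  # no spanning stride of B
    stride_b <- b$position[j[i] + 1L] - b$position[j[i]]
    if (stride_b == 0) { skipped <- skipped + 1L; next }
    ratio[i] <- (a$position[i] - b$position[j[i]]) / stride_b
    speed[i] <- stride_b / (b$stance_onset[j[i] + 1L] - b$stance_onset[j[i]])
  }
  ok <- is.finite(ratio)
  list(ratio = ratio[ok], speed = speed[ok], n_skipped = skipped)
}

trial_temporal_ratios <- function(events_a, events_b) {
  a <- sort(events_a$stance_onset)
  b <- events_b[order(events_b$stance_onset), , drop = FALSE]
  if (length(a) < 1 || nrow(b) < 2) {
    return(list(ratio = numeric(), speed = numeric(), n_skipped = 0L))
  }
  ratio <- speed <- numeric(0)
  skipped <- 0L
  for (i in seq_len(nrow(b) - 1L)) {
    t0 <- b$stance_onset[i]; t1 <- b$stance_onset[i + 1L]
    inside <- a[a >= t0 & a < t1]
    if (length(inside) != 1L) { skipped <- skipped + 1L; next }
    ratio <- c(ratio, (inside - t0) / (t1 - t0))
    speed <- c(speed, (b$position[i + 1L] - b$position[i]) / (t1 - t0))
  }
  list(ratio = ratio, speed = speed, n_skipped = skipped)
}

alternation_ratios_impl <- function(events_a, events_b, kind) {
  stopifnot(is.data.frame(events_a), is.data.frame(events_b))
  if (!homologous_pair(events_a$limb[1], events_b$limb[1])) {
    stop("limbs '", events_a$limb[1], "' and '", events_b$limb[1],
         "' are not a homologous pair")
  }
  key_a <- interaction(events_a$subject_id, events_a$condition,
                       events_a$trial_id, drop = TRUE)
  key_b <- interaction(events_b$subject_id, events_b$condition,
                       events_b$trial_id, drop = TRUE)
  fun <- if (kind == "spatial") trial_spatial_ratios else trial_temporal_ratios
  ratio <- speed <- numeric(0)
  skipped <- 0L
  for (k in levels(key_a)) {
    ea <- events_a[key_a == k, , drop = FALSE]
    eb <- events_b[key_b == k, , drop = FALSE]
    if (!nrow(eb)) next
    res <- fun(ea, eb)
    ratio <- c(ratio, res$ratio)
    speed <- c(speed, res$speed)
    skipped <- skipped + res$n_skipped
  }
  out <- new_alternation_series(ratio, speed, kind,
                                condition = as.character(
                                  events_a$condition[1]))
  attr(out, "n_skipped") <- skipped
  out
}

#' Spatial alternation ratios of a homologous limb pair
#'
#' For each placement of the stepping limb A, the ratio of its step length to
#' the length of the opposing limb B's stride that spans the placement:
#' `(x_A - x_B) / stride_length(B)`, wrapped into `[0,1)`. A ratio of 0.5
#' marks symmetric foot placement. Each ratio carries the spanning stride's
#' velocity (the ratio is defined on that limb's stride) for speed-binned
#' analyses. Placements without a spanning opposing stride, or with a
#' zero-length opposing stride, are skipped and counted.
#'
#' @param events_a Footfall events of the stepping limb (one or more trials).
#' @param events_b Footfall events of the opposing homologous limb.
#' @return An `alternation_series` (data frame `ratio`, `speed` with
#'   attributes `kind`, `condition`, `n_skipped`).
#' @export
spatial_ratios <- function(events_a, events_b) {
  alternation_ratios_impl(events_a, events_b, "spatial")
}

#' Temporal alternation ratios of a homologous limb pair
#'
#' For each gait cycle of the reference limb B spanning `[t_i, t_{i+1})`,
#' the time offset of the single opposing footfall of limb A inside it,
#' divided by the cycle duration; 0.5 marks perfect alternation. Cycles
#' containing zero or two or more opposing footfalls (arrhythmic stepping)
#' are skipped and counted. The cycle's stride velocity is attached.
#'
#' @inheritParams spatial_ratios
#' @return An `alternation_series`.
#' @export
temporal_ratios <- function(events_a, events_b) {
  alternation_ratios_impl(events_a, events_b, "temporal")
}

#' Circular summary of alternation ratios
#'
#' Maps ratios to angles `theta = 2*pi*ratio`, sums unit vectors and reports
#' the mean direction and the resultant length `r` (1 = perfect clustering,
#' 0 = uniform dispersion), the quantities drawn as radial lines in polar
#' plots.
#'
#' @param ratios Numeric ratios on any scale (wrapped into `[0,1)`), or an
#'   `alternation_series`.
#' @return Object of class `circ_summary`: `mean_direction` (radians in
#'   `[0, 2*pi)`), `r`, `n`, `mean_ratio` (`mean_direction / (2*pi)`), and
#'   `mean_defined` (`FALSE` when the resultant is numerically zero, e.g.
#'   antipodal ratios).
#' @export
circ_summary <- function(ratios) {
  if (inherits(ratios, "alternation_series")) ratios <- ratios$ratio
  stopifnot(length(ratios) >= 1)
  theta <- 2 * pi * wrap_unit(ratios)
  cc <- sum(cos(theta)); ss <- sum(sin(theta))
  n <- length(theta)
  r <- sqrt(cc^2 + ss^2) / n
  defined <- r > 1e-12
  mu <- if (defined) atan2(ss, cc) %% (2 * pi) else NA_real_
  structure(list(mean_direction = mu, r = r, n = n,
                 mean_ratio = if (defined) mu / (2 * pi) else NA_real_,
                 mean_defined = defined),
            class = "circ_summary")
}

#' @export
print.circ_summary <- function(x, ...) {
  if (x$mean_defined) {
    cat("<circ_summary> mean ratio ", signif(x$mean_ratio, 4), ", r = ",
        signif(x$r, 4), ", n = ", x$n, "\n", sep = "")
  } else {
    cat("<circ_summary> mean direction undefined (r = 0), n = ", x$n, "\n",
        sep = "")
  }
  invisible(x)
}

# Fisher's approximation for the concentration parameter of a von Mises
# distribution given a mean resultant length.
kappa_from_rbar <- function(rbar) {
  if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
}

#' Watson-Williams test for equality of two circular means
#'
#' Two-sample circular analogue of the t test, used to compare alternation
#' ratios between conditions. With resultant lengths `R1`, `R2` of the
#' samples and `R` of the pooled sample (`N = n1 + n2`),
#' \deqn{F = c \; \frac{(N-2)(R_1+R_2-R)}{N-(R_1+R_2)}}
#' referred to `F(1, N-2)`, with the standard multiplicative correction
#' `c = 1 + 3/(8*kappa)` where `kappa` is estimated from the pooled mean
#' resultant length. The test assumes comparable, reasonably high
#' concentration; a warning is issued when the pooled mean resultant length
#' falls below 0.45 or a sample has fewer than 5 values.
#'
#' @param a,b Ratio vectors on `[0,1)` or `alternation_series` objects.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `watson_williams`: `F`, `df_num`, `df_den`, `p`,
#'   `correction`, `kappa`, `significant`, plus per-sample summaries.
#' @export
watson_williams <- function(a, b, alpha = 0.05) {
  if (inherits(a, "alternation_series")) a <- a$ratio
  if (inherits(b, "alternation_series")) b <- b$ratio
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  if (n1 < 5 || n2 < 5) {
    warning("Watson-Williams test with fewer than 5 values per sample")
  }
  s1 <- circ_summary(a); s2 <- circ_summary(b)
  if (!s1$mean_defined || !s2$mean_defined) {
    stop("mean direction undefined in one of the samples")
  }
  theta <- 2 * pi * wrap_unit(c(a, b))
  r_pool <- sqrt(sum(cos(theta))^2 + sum(sin(theta))^2)
  r1 <- n1 * s1$r; r2 <- n2 * s2$r
  rbar <- (r1 + r2) / n
  if (rbar < 0.45) {
    warning("pooled mean resultant length ", signif(rbar, 3),
            " < 0.45; Watson-Williams assumptions questionable")
  }
  kappa <- kappa_from_rbar(rbar)
  corr <- 1 + 3 / (8 * kappa)
  f <- corr * (n - 2) * (r1 + r2 - r_pool) / (n - (r1 + r2))
  f <- max(f, 0)
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  structure(list(F = f, df_num = 1L, df_den = n - 2L, p = p,
                 correction = corr, kappa = kappa, alpha = alpha,
                 significant = p < alpha, summary_a = s1, summary_b = s2),
            class = "watson_williams")
}

#' @export
print.watson_williams <- function(x, ...) {
  cat("<watson_williams> F(1, ", x$df_den, ") = ", signif(x$F, 4),
      ", p = ", signif(x$p, 4),
      if (x$significant) " -> mean directions differ" else
        " -> no difference detected",
      " (alpha = ", x$alpha, ")\n", sep = "")
  cat("  mean ratios: ", signif(x$summary_a$mean_ratio, 4), " (r = ",
      signif(x$summary_a$r, 3), ") vs ", signif(x$summary_b$mean_ratio, 4),
      " (r = ", signif(x$summary_b$r, 3), ")\n", sep = "")
  invisible(x)
}

#' Partition an alternation series into speed bins
#'
#' Asymmetries can be speed-gated, so ratios are re-analyzed within speed
#' bins (mouse default 3-10 and 10-16 cm/s). Bins are half-open on the left,
#' closed at the final edge: a boundary speed is assigned to the upper bin.
#'
#' @param series An `alternation_series` with attached speeds.
#' @param breaks Ascending bin edges (default `c(3, 10, 16)`).
#' @return Named list of `alternation_series`, one per bin; empty bins are
#'   retained (zero rows).
#' @export
bin_by_speed <- function(series, breaks = c(3, 10, 16)) {
  stopifnot(inherits(series, "alternation_series"),
            length(breaks) >= 2, !is.unsorted(breaks, strictly = TRUE))
  n_bins <- length(breaks) - 1L
  out <- vector("list", n_bins)
  names(out) <- paste0("[", breaks[-length(breaks)], ",", breaks[-1],
                       c(rep(")", n_bins - 1L), "]"))
  for (i in seq_len(n_bins)) {
    keep <- series$speed >= breaks[i] &
      (if (i == n_bins) series$speed <= breaks[i + 1] else
         series$speed < breaks[i + 1])
    out[[i]] <- new_alternation_series(series$ratio[keep], series$speed[keep],
                                       attr(series, "kind"),
                                       attr(series, "limb_pair"),
                                       attr(series, "condition"))
  }
  out
}

#' Plot-ready polar table of circular summaries and raw ratios
#'
#' Flattens circular summaries (resultant vectors: angle = mean ratio,
#' radius = r) and optional raw ratios (unit-radius points) into one table
#' for polar plotting or export.
#'
#' @param summaries Named list of [circ_summary()] objects (names become
#'   group labels).
#' @param ratios Optional named list of raw ratio vectors.
#' @return Data frame with `group`, `type` (`"summary"`/`"raw"`),
#'   `ratio`, `angle_rad`, `radius`.
#' @export
polar_export <- function(summaries = list(), ratios = list()) {
  rows <- list()
  for (g in names(summaries)) {
    s <- summaries[[g]]
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, type = "summary",
      ratio = s$mean_ratio,
      angle_rad = s$mean_direction,
      radius = s$r, stringsAsFactors = FALSE)
  }
  for (g in names(ratios)) {
    r <- wrap_unit(ratios[[g]])
    if (!length(r)) next
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, type = "raw", ratio = r,
      angle_rad = 2 * pi * r, radius = 1, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(group = character(), type = character(),
                      ratio = numeric(), angle_rad = numeric(),
                      radius = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
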