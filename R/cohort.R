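# Human-cohort utilities: Welch's t from published summary statistics,
# shorter-side re-assignment, subgroup splits, asymmetry-ratio correlations.

#' Group summary triplet
#'
#' Holds the (n, mean, SD) of one group as printed in clinical summary
#' tables, for recomputation of Welch's t tests.
#'
#' @param n Group size (>= 2).
#' @param mean Group mean.
#' @param sd Group standard deviation (>= 0).
#' @param label Optional group label.
#' @return Object of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd, label = "") {
  stopifnot(n >= 2, sd >= 0)
  structure(list(n = n, mean = mean, sd = sd, label = label),
            class = "group_summary")
}

#' Welch's two-sample t test from group summaries
#'
#' Two-tailed unpaired t test with Welch's correction for unequal variances
#' and sample sizes, computed from (n, mean, SD) triplets:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom. The df is reported both raw and rounded to the
#' nearest integer, as clinical tables print integers.
#'
#' @param g1,g2 [group_summary()] objects (or lists with `n`, `mean`, `sd`).
#' @return Object of class `welch_t`: `t`, `abs_t`, `df`, `df_rounded`, `p`,
#'   and `infinite` flag (both SDs zero with unequal means).
#' @export
#' @examples
#' welch_t(group_summary(12, 999, 549), group_summary(15, 479, 358))
welch_t <- function(g1, g2) {
  v1 <- g1$sd^2 / g1$n
  v2 <- g2$sd^2 / g2$n
  if (v1 + v2 == 0) {
    if (g1$mean == g2$mean) {
      return(structure(list(t = 0, abs_t = 0, df = NA_real_,
                            df_rounded = NA_integer_, p = 1,
                            infinite = FALSE), class = "welch_t"))
    }
    return(structure(list(t = sign(g1$mean - g2$mean) * Inf, abs_t = Inf,
                          df = NA_real_, df_rounded = NA_integer_, p = 0,
                          infinite = TRUE), class = "welch_t"))
  }
  t_stat <- (g1$mean - g2$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(list(t = t_stat, abs_t = abs(t_stat), df = df,
                 df_rounded = as.integer(round(df)), p = p,
                 infinite = FALSE),
            class = "welch_t")
}

#' @export
print.welch_t <- function(x, ...) {
  if (x$infinite) {
    cat("<welch_t> |t| infinite (zero variance, unequal means)\n")
    return(invisible(x))
  }
  cat("<welch_t> t = ", signif(x$t, 4), " (df = ", x$df_rounded, "), p = ",
      signif(x$p, 4), "\n", sep = "")
  invisible(x)
}

#' Re-assign sides so the shorter-step side is uniformly "right"
#'
#' Asymmetries in patients fall on either side at random, which obscures
#' group-level left/right comparisons. Subjects clinically rated as
#' asymmetric with the shorter step on the left get all left and right limb
#' labels swapped, so that the shorter-step side is "right" for every
#' asymmetric subject; symmetric subjects and controls are left unchanged.
#' Applying the remap twice restores the original labels.
#'
#' @param dataset A [gait_dataset()] or stride/footfall data frame with
#'   `subject_id` and `limb` columns.
#' @param assignments Data frame with `subject_id` and `shorter_side`
#'   (`"left"`, `"right"` or `"none"`), covering every subject.
#' @return Object of the same type with limbs remapped; attribute `swapped`
#'   lists the remapped subjects.
#' @export
assign_sides <- function(dataset, assignments) {
  records <- if (inherits(dataset, "gait_dataset")) dataset$records else dataset
  stopifnot(all(c("subject_id", "shorter_side") %in% names(assignments)))
  bad <- setdiff(unique(records$subject_id), assignments$subject_id)
  if (length(bad)) {
    stop("missing side assignment for subject(s): ",
         paste(bad, collapse = ", "))
  }
  if (!all(assignments$shorter_side %in% c("left", "right", "none"))) {
    stop("shorter_side must be 'left', 'right' or 'none'")
  }
  swap_subjects <- assignments$subject_id[assignments$shorter_side == "left"]
  swap_map <- c(L = "R", R = "L", LH = "RH", RH = "LH", LF = "RF", RF = "LF")
  sel <- records$subject_id %in% swap_subjects
  records$limb[sel] <- unname(swap_map[records$limb[sel]])
  if (inherits(dataset, "gait_dataset")) {
    dataset$records <- records
    attr(dataset, "swapped") <- intersect(swap_subjects, records$subject_id)
    dataset
  } else {
    attr(records, "swapped") <- intersect(swap_subjects, records$subject_id)
    records
  }
}

#' Split a cohort by clinical subgroup labels
#'
#' Partitions per-subject data by externally supplied labels (e.g.
#' tremor-dominant vs postural-instability-gait-difficulty subtype, or
#' clinically asymmetric vs symmetric). Subjects labeled `"indeterminate"`
#' are excluded from the subgroup analysis and counted.
#'
#' @param dataset A [gait_dataset()] or data frame with `subject_id`.
#' @param labels Data frame with `subject_id` and `label`; every subject in
#'   the dataset must be labeled.
#' @return Named list of per-label datasets plus attribute `excluded`
#'   (indeterminate subject ids). An empty subgroup is an error.
#' @export
split_cohort <- function(dataset, labels) {
  records <- if (inherits(dataset, "gait_dataset")) dataset$records else dataset
  stopifnot(all(c("subject_id", "label") %in% names(labels)))
  lab <- labels$label[match(records$subject_id, labels$subject_id)]
  if (anyNA(lab)) {
    stop("unlabeled subject(s): ",
         paste(unique(records$subject_id[is.na(lab)]), collapse = ", "))
  }
  keep_levels <- setdiff(unique(labels$label), "indeterminate")
  if (!length(keep_levels)) stop("no non-indeterminate labels supplied")
  out <- lapply(keep_levels, function(lv) {
    sub <- records[lab == lv, , drop = FALSE]
    if (!nrow(sub)) stop("subgroup '", lv, "' is empty")
    if (inherits(dataset, "gait_dataset")) {
      gait_dataset(sub, dataset$species, dataset$units, dataset$metadata)
    } else {
      sub
    }
  })
  names(out) <- keep_levels
  attr(out, "excluded") <-
    unique(labels$subject_id[labels$label == "indeterminate"])
  out
}

#' Asymmetry ratio of two side values
#'
#' `"min_max"` (default): smaller over larger side mean, bounded (0, 1]
#' with 1 = perfectly symmetric. `"signed"`: `(L - R) / (L + R)`, signed and
#' bounded (-1, 1) with 0 = symmetric.
#'
#' @param left,right Side values (vectors).
#' @param type Ratio convention.
#' @return Numeric vector of ratios.
#' @export
asymmetry_ratio <- function(left, right, type = c("min_max", "signed")) {
  type <- match.arg(type)
  if (type == "min_max") {
    pmin(left, right) / pmax(left, right)
  } else {
    (left - right) / (left + right)
  }
}

#' Correlate gait asymmetry with clinical asymmetry across subjects
#'
#' Computes per-subject asymmetry ratios for a gait metric (from left/right
#' side means) and for a clinical sub-score (e.g. rigidity or bradykinesia),
#' then the two-tailed Pearson correlation between them.
#'
#' @param gait_left,gait_right Per-subject side means of the gait metric.
#' @param clinical_left,clinical_right Per-subject clinical sub-scores.
#' @param type Asymmetry-ratio convention (see [asymmetry_ratio()]); the
#'   choice is recorded in the result.
#' @return List with `r`, `p`, `n`, `type`, `gait_ratio`, `clinical_ratio`,
#'   and `undefined` flag (zero variance in either ratio).
#' @export
asymmetry_corr <- function(gait_left, gait_right, clinical_left,
                           clinical_right, type = c("min_max", "signed")) {
  type <- match.arg(type)
  stopifnot(length(gait_left) == length(gait_right),
            length(clinical_left) == length(clinical_right),
            length(gait_left) == length(clinical_left))
  gr <- asymmetry_ratio(gait_left, gait_right, type)
  cr <- asymmetry_ratio(clinical_left, clinical_right, type)
  ok <- is.finite(gr) & is.finite(cr)
  gr <- gr[ok]; cr <- cr[ok]
  if (length(gr) < 3) stop("need at least 3 subjects with defined ratios")
  if (stats::sd(gr) == 0 || stats::sd(cr) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(gr), type = type,
                gait_ratio = gr, clinical_ratio = cr, undefined = TRUE))
  }
  ct <- stats::cor.test(gr, cr, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(gr), type = type,
       gait_ratio = gr, clinical_ratio = cr, undefined = FALSE)
}
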