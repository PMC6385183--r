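#' @keywords internal
#' @importFrom stats setNames pf pt pnorm sd aggregate t.test cor.test
#'   runif rnorm
"_PACKAGE"

# Required columns of a footfall-event table and of a stride table.
FOOTFALL_COLS <- c("subject_id", "condition", "trial_id", "limb",
                   "position", "stance_onset", "swing_onset")
STRIDE_COLS <- c("subject_id", "condition", "trial_id", "limb", "t_start",
                 "x_start", "stride_velocity", "stride_length", "step_length",
                 "swing_time", "stance_time", "cycle_duration")

#' Limb codes valid for a species
#'
#' Quadrupeds use hind/fore left/right codes; bipeds use `L`/`R`.
#'
#' @param species `"mouse"` or `"human"`.
#' @return Character vector of valid limb codes.
#' @export
species_limbs <- function(species = c("mouse", "human")) {
  species <- match.arg(species)
  if (species == "mouse") c("LH", "RH", "LF", "RF") else c("L", "R")
}

#' Homologous limb pairs for a species
#'
#' @inheritParams species_limbs
#' @return Named list of left/right limb code pairs (`hind`, `fore` for mouse;
#'   `legs` for human).
#' @export
species_pairs <- function(species = c("mouse", "human")) {
  species <- match.arg(species)
  if (species == "mouse") {
    list(hind = c(left = "LH", right = "RH"),
         fore = c(left = "LF", right = "RF"))
  } else {
    list(legs = c(left = "L", right = "R"))
  }
}

#' Validate a footfall-event table
#'
#' A footfall event is one paw or foot contact: the limb, its placement
#' position along the travel axis, and the onset times of the stance and
#' swing phases. Checks column presence and types, that swing onset follows
#' stance onset, and that within each (subject, condition, trial, limb)
#' series events are strictly ordered in time with non-decreasing positions
#' along the travel direction.
#'
#' @param events Data frame with columns `subject_id`, `condition`,
#'   `trial_id`, `limb`, `position`, `stance_onset`, `swing_onset`.
#' @param species Optional species; if given, limb codes are checked.
#' @return The validated data frame, invisibly.
#' @export
validate_footfalls <- function(events, species = NULL) {
  stopifnot(is.data.frame(events))
  missing_cols <- setdiff(FOOTFALL_COLS, names(events))
  if (length(missing_cols)) {
    stop("footfall table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("position", "stance_onset", "swing_onset")) {
    if (!is.numeric(events[[col]])) {
      stop("footfall column '", col, "' must be numeric")
    }
    bad <- which(!is.finite(events[[col]]))
    if (length(bad)) {
      stop("non-finite value in column '", col, "' at row ", bad[1])
    }
  }
  if (!is.null(species)) {
    bad <- which(!events$limb %in% species_limbs(species))
    if (length(bad)) {
      stop("invalid limb code '", events$limb[bad[1]], "' for species '",
           species, "' at row ", bad[1])
    }
  }
  bad <- which(events$swing_onset <= events$stance_onset)
  if (length(bad)) {
    stop("swing_onset must exceed stance_onset; violated at row ", bad[1])
  }
  key <- interaction(events$subject_id, events$condition, events$trial_id,
                     events$limb, drop = TRUE)
  dup <- duplicated(paste(key, events$stance_onset))
  if (any(dup)) {
    stop("duplicate (subject, condition, trial, limb, stance_onset) at row ",
         which(dup)[1])
  }
  for (g in split(seq_len(nrow(events)), key)) {
    idx <- g[order(events$stance_onset[g])]
    if (length(idx) >= 2 && any(diff(events$position[idx]) < 0)) {
      stop("positions must be non-decreasing along travel within a trial ",
           "(limb ", events$limb[idx[1]], ", trial ", events$trial_id[idx[1]],
           ")")
    }
  }
  invisible(events)
}

empty_strides <- function() {
  df <- data.frame(subject_id = character(), condition = character(),
                   trial_id = character(), limb = character(),
                   t_start = numeric(), x_start = numeric(),
                   stride_velocity = numeric(), stride_length = numeric(),
                   step_length = numeric(), swing_time = numeric(),
                   stance_time = numeric(), cycle_duration = numeric(),
                   stringsAsFactors = FALSE)
  df
}

#' Extract stride metrics from the footfall events of one limb
#'
#' Consecutive placements of the same limb within a trial define one gait
#' cycle each: stride length is the distance between the two placements,
#' cycle duration the interval between their stance onsets, stance time the
#' interval from stance onset to swing onset, and swing time the remainder of
#' the cycle. Stride velocity is stride length over cycle duration. Step
#' length is left unset here; see [pair_step_lengths()].
#'
#' @param events Footfall events of a single limb within a single trial.
#' @return Data frame of stride records (one fewer than the number of
#'   events); empty for fewer than two events. Strides with non-positive
#'   cycle duration are dropped with a warning.
#' @seealso [strides_from_footfalls()] for whole-dataset extraction.
#' @export
#' @examples
#' ev <- data.frame(subject_id = "m1", condition = "base", trial_id = "t1",
#'                  limb = "LH", position = c(0, 6),
#'                  stance_onset = c(0, 0.6), swing_onset = c(0.4, 1.0))
#' extract_strides(ev)  # 6 cm stride at 10 cm/s
extract_strides <- function(events) {
  stopifnot(is.data.frame(events))
  if (length(unique(events$limb)) > 1 || length(unique(events$trial_id)) > 1) {
    stop("extract_strides() expects events of one limb within one trial")
  }
  if (nrow(events) < 2) return(empty_strides())
  events <- events[order(events$stance_onset), , drop = FALSE]
  n <- nrow(events)
  i <- seq_len(n - 1L)
  cycle <- diff(events$stance_onset)
  out <- data.frame(
    subject_id = as.character(events$subject_id[i]),
    condition = as.character(events$condition[i]),
    trial_id = as.character(events$trial_id[i]),
    limb = as.character(events$limb[i]),
    t_start = events$stance_onset[i],
    x_start = events$position[i],
    stride_velocity = diff(events$position) / cycle,
    stride_length = diff(events$position),
    step_length = NA_real_,
    swing_time = events$stance_onset[i + 1L] - events$swing_onset[i],
    stance_time = events$swing_onset[i] - events$stance_onset[i],
    cycle_duration = cycle,
    stringsAsFactors = FALSE
  )
  bad <- out$cycle_duration <= 0
  if (any(bad)) {
    warning(sum(bad), " stride(s) with non-positive cycle duration dropped")
    out <- out[!bad, , drop = FALSE]
  }
  out
}

homologous_pair <- function(limb_a, limb_b) {
  pairs <- list(c("LH", "RH"), c("LF", "RF"), c("L", "R"))
  any(vapply(pairs, function(p) all(sort(c(limb_a, limb_b)) == sort(p)),
             logical(1)))
}

#' Fill step lengths by pairing a limb's strides with the opposing limb
#'
#' Step length is the distance by which a limb is placed in front of (or,
#' when negative, behind) the most recent placement of the opposing
#' homologous limb. For each stride's starting placement of limb A at
#' position x_A, the opposing placement is the latest event of limb B with
#' stance onset at or before A's stance onset; ties resolve toward the
#' earlier opposing event. Placements with no preceding opposing event keep
#' `NA` step length.
#'
#' @param strides Stride records of one limb within one trial (from
#'   [extract_strides()]).
#' @param events_opposite Footfall events of the opposing homologous limb in
#'   the same trial.
#' @return `strides` with `step_length` filled where defined.
#' @export
pair_step_lengths <- function(strides, events_opposite) {
  if (nrow(strides) == 0) return(strides)
  if (!homologous_pair(strides$limb[1], events_opposite$limb[1])) {
    stop("limbs '", strides$limb[1], "' and '", events_opposite$limb[1],
         "' are not a homologous pair")
  }
  if (!all(strides$trial_id == events_opposite$trial_id[1]) ||
      !all(strides$subject_id == events_opposite$subject_id[1]) ||
      !all(strides$condition == events_opposite$condition[1])) {
    stop("stride and opposing-event tables must come from the same ",
         "subject/condition/trial")
  }
  opp <- events_opposite[order(events_opposite$stance_onset), , drop = FALSE]
  # index of latest opposing stance onset <= own stance onset (0 if none)
  j <- findInterval(strides$t_start, opp$stance_onset)
  has <- j >= 1L
  strides$step_length[has] <- strides$x_start[has] - opp$position[j[has]]
  strides
}

#' Gait dataset container
#'
#' Bundles stride records with the species and measurement units so that
#' downstream analyses know the valid limb codes and the speed scale
#' (cm and s for mouse, m and s for human).
#'
#' @param records Stride-record data frame (see [extract_strides()]).
#' @param species `"mouse"` or `"human"`.
#' @param units Optional list with `length` and `time`; defaults per species.
#' @param metadata Optional free-form list of labels.
#' @return An object of class `gait_dataset`.
#' @export
gait_dataset <- function(records, species = c("mouse", "human"),
                         units = NULL, metadata = list()) {
  species <- match.arg(species)
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(setdiff(STRIDE_COLS, c("t_start", "x_start")),
                          names(records))
  if (length(missing_cols)) {
    stop("stride table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(!records$limb %in% species_limbs(species))
  if (length(bad)) {
    stop("limb code '", records$limb[bad[1]], "' invalid for species '",
         species, "'")
  }
  if (is.null(units)) {
    units <- if (species == "mouse") {
      list(length = "cm", time = "s")
    } else {
      list(length = "m", time = "s")
    }
  }
  structure(list(records = records, species = species, units = units,
                 metadata = metadata),
            class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  r <- x$records
  cat("<gait_dataset> ", x$species, ", ", nrow(r), " strides, ",
      length(unique(r$subject_id)), " subject(s), conditions: ",
      paste(unique(r$condition), collapse = ", "), "\n", sep = "")
  if (nrow(r)) {
    cat("  speed range: ", signif(min(r$stride_velocity), 4), "-",
        signif(max(r$stride_velocity), 4), " ", x$units$length, "/",
        x$units$time, "\n", sep = "")
  }
  invisible(x)
}

#' Derive all stride records from a footfall-event table
#'
#' Runs [extract_strides()] per (subject, condition, trial, limb) and fills
#' step lengths for every homologous pair in both directions. Strides are
#' never formed across trial boundaries.
#'
#' @param events Footfall-event data frame (validated with
#'   [validate_footfalls()]).
#' @inheritParams gait_dataset
#' @param pair_steps Fill step lengths (default `TRUE`).
#' @return A [gait_dataset()].
#' @export
strides_from_footfalls <- function(events, species = c("mouse", "human"),
                                   pair_steps = TRUE, metadata = list()) {
  species <- match.arg(species)
  validate_footfalls(events, species)
  key <- interaction(events$subject_id, events$condition, events$trial_id,
                     drop = TRUE)
  pairs <- species_pairs(species)
  chunks <- lapply(split(seq_len(nrow(events)), key), function(idx) {
    trial <- events[idx, , drop = FALSE]
    by_limb <- split(trial, trial$limb)
    strides <- lapply(by_limb, extract_strides)
    if (pair_steps) {
      for (p in pairs) {
        for (side in 1:2) {
          a <- p[side]; b <- p[3 - side]
          if (!is.null(strides[[a]]) && nrow(strides[[a]]) &&
              !is.null(by_limb[[b]])) {
            strides[[a]] <- pair_step_lengths(strides[[a]], by_limb[[b]])
          }
        }
      }
    }
    do.call(rbind, strides)
  })
  records <- do.call(rbind, chunks)
  if (is.null(records)) records <- empty_strides()
  rownames(records) <- NULL
  gait_dataset(records, species, metadata = metadata)
}

#' Restrict a gait dataset to a stride-velocity window
#'
#' Analyses are run over the speed range where the regression families hold
#' (3-16 cm/s in mouse, 0.3-1.5 m/s in human); this keeps only records with
#' `lo <= stride_velocity <= hi`.
#'
#' @param dataset A [gait_dataset()] or stride data frame.
#' @param lo,hi Window bounds (must satisfy `lo < hi`), in the dataset's
#'   speed units.
#' @param quiet Suppress the retention message.
#' @return Object of the same type with only in-window records; an empty
#'   result is permitted and flagged with a warning.
#' @export
filter_speed_range <- function(dataset, lo, hi, quiet = FALSE) {
  stopifnot(lo < hi)
  records <- if (inherits(dataset, "gait_dataset")) dataset$records else dataset
  keep <- records$stride_velocity >= lo & records$stride_velocity <= hi
  if (!quiet) {
    message("speed window [", lo, ", ", hi, "]: retained ", sum(keep),
            " of ", length(keep), " strides")
  }
  if (!any(keep)) warning("speed window [", lo, ", ", hi, "] left no strides")
  out <- records[keep, , drop = FALSE]
  if (inherits(dataset, "gait_dataset")) {
    dataset$records <- out
    dataset
  } else {
    out
  }
}
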