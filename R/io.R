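# CSV readers/writers for footfall-event and stride tables.

#' Read a footfall-event CSV
#'
#' Expected columns: `subject_id`, `condition`, `trial_id`, `limb`,
#' `position`, `stance_onset`, `swing_onset` (header required, UTF-8,
#' decimal point). Onsets recorded as video frame numbers can be converted
#' to seconds with `frames = TRUE` (default rate 120 frames/s, the usual
#' high-speed video convention for mouse runways). Parse problems report the
#' offending row.
#'
#' @param path CSV file path.
#' @param species Optional species for limb-code validation.
#' @param frames Are `stance_onset`/`swing_onset` given in frames?
#' @param fps Frame rate used when `frames = TRUE`.
#' @return Validated footfall-event data frame.
#' @export
read_footfalls <- function(path, species = NULL, frames = FALSE, fps = 120) {
  events <- utils::read.csv(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  missing_cols <- setdiff(FOOTFALL_COLS, names(events))
  if (length(missing_cols)) {
    stop("'", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("position", "stance_onset", "swing_onset")) {
    v <- events[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop("non-numeric value '", v[bad[1]], "' in column '", col,
             "' at data row ", bad[1], " of '", path, "'")
      }
      events[[col]] <- num
    }
  }
  if (frames) {
    events$stance_onset <- events$stance_onset / fps
    events$swing_onset <- events$swing_onset / fps
  }
  validate_footfalls(events, species)
  events
}

#' Write stride records to CSV
#'
#' @param dataset A [gait_dataset()] or stride data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_strides <- function(dataset, path) {
  records <- if (inherits(dataset, "gait_dataset")) dataset$records else dataset
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read pre-computed stride records from CSV
#'
#' Accepts tables written by [write_strides()] or external stride exports
#' with at least `subject_id`, `condition`, `trial_id`, `limb`,
#' `stride_velocity`, `stride_length`, `step_length`, `swing_time`,
#' `stance_time` (a missing `cycle_duration` is reconstructed as stride
#' length over velocity).
#'
#' @param path CSV file path.
#' @param species `"mouse"` or `"human"`.
#' @return A [gait_dataset()].
#' @export
read_strides <- function(path, species = c("mouse", "human")) {
  species <- match.arg(species)
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8")
  if (is.null(records$cycle_duration)) {
    records$cycle_duration <- records$stride_length / records$stride_velocity
  }
  gait_dataset(records, species)
}
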