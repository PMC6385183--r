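# Synthetic footfall-event generator: quadruped and biped walkers whose
# stride metrics follow configurable speed-dependent curve families, with
# stride-to-stride noise and injectable spatial/temporal asymmetries. The
# test bed for every analysis path in the package.

curve_spec <- function(family, params) {
  m <- model_spec(family)
  stopifnot(length(params) == m$n_params)
  list(model = m, params = stats::setNames(as.numeric(params), m$par_names))
}

eval_curve <- function(curve, v) eval_model(curve$model, curve$params, v)

# Multiplicative scaling of a curve in its value (y) dimension.
scale_curve <- function(curve, factor) {
  idx <- switch(curve$model$family,
    linear = ,
    log_linear_stance = 1:2,
    one_phase_assoc = 1:2,
    two_phase_assoc = c(1, 2, 4))
  curve$params[idx] <- curve$params[idx] * factor
  curve
}

#' Synthetic gait profile
#'
#' Defines the walker the simulator emulates: speed-dependent curves for
#' stride length and swing time, the speed distribution, the opposing-limb
#' spatial and temporal offsets, stride-to-stride noise, and an optional
#' injected asymmetry. Stance time is not sampled independently: the cycle
#' duration is stride length over speed and stance is cycle minus swing, so
#' the additivity invariant holds by construction and stance emerges with
#' the hyperbolic speed dependence seen in real data.
#'
#' Species defaults emulate walking/trotting mice (3-16 cm/s; stride length
#' saturating one-phase curve from ~4.5 to ~7.5 cm; swing ~0.11-0.13 s) and
#' human overground walking (0.3-1.5 m/s; stride length linear 0.6-1.45 m;
#' swing ~0.38-0.41 s).
#'
#' @param species `"mouse"` or `"human"`.
#' @param stride_length,swing_time Curve specifications: lists with `family`
#'   (see [model_spec()]) and `params`; `NULL` for the species default.
#' @param speed_range Window from which each trial's target speed is drawn
#'   uniformly (equal bounds give constant speed); stride speeds fluctuate
#'   around the target by `noise$speed`. Units: cm/s (mouse) or m/s (human).
#' @param phase_offset Temporal fraction of the reference cycle at which the
#'   opposing limb lands (0.5 = perfect alternation).
#' @param step_fraction Spatial fraction of the reference stride at which
#'   the opposing limb is placed (0.5 = symmetric placement).
#' @param noise Named list of stride-to-stride SDs: `stride_length` (length
#'   units), `swing_time` (s), `step_fraction`, `phase` (fractions), `speed`
#'   (relative SD of stride speed about the trial target). All 0 =
#'   deterministic gait.
#' @param asymmetry Named list: `step_delta` (change of the affected side's
#'   step length; fraction if `step_mode = "multiplicative"`, length units
#'   if `"additive"`), `phase_delta` (shift of the temporal offset),
#'   `side` (`"right"` or `"left"`), `speed_gate` (optional `c(lo, hi)`
#'   window outside which no asymmetry is applied).
#' @param fore_lead Quadruped only: distance by which the forelimb pair
#'   leads the hindlimb pair along the travel axis.
#' @return Object of class `gait_profile`.
#' @export
gait_profile <- function(species = c("mouse", "human"),
                         stride_length = NULL, swing_time = NULL,
                         speed_range = NULL,
                         phase_offset = 0.5, step_fraction = 0.5,
                         noise = list(), asymmetry = list(),
                         fore_lead = 2.5) {
  species <- match.arg(species)
  if (species == "mouse") {
    if (is.null(stride_length)) {
      stride_length <- curve_spec("one_phase_assoc",
                                  c(Y0 = 2.5, Plateau = 8, K = 0.15))
    }
    if (is.null(swing_time)) {
      swing_time <- curve_spec("linear", c(intercept = 0.14, slope = -0.002))
    }
    if (is.null(speed_range)) speed_range <- c(3, 16)
    noise_def <- list(stride_length = 0.4, swing_time = 0.008,
                      step_fraction = 0.03, phase = 0.03, speed = 0.08)
  } else {
    if (is.null(stride_length)) {
      stride_length <- curve_spec("linear", c(intercept = 0.4, slope = 0.7))
    }
    if (is.null(swing_time)) {
      swing_time <- curve_spec("linear", c(intercept = 0.42, slope = -0.03))
    }
    if (is.null(speed_range)) speed_range <- c(0.3, 1.5)
    noise_def <- list(stride_length = 0.06, swing_time = 0.015,
                      step_fraction = 0.02, phase = 0.02, speed = 0.06)
  }
  if (!is.list(stride_length) || is.null(stride_length$model)) {
    stride_length <- curve_spec(stride_length$family, stride_length$params)
  }
  noise <- utils::modifyList(noise_def, noise)
  asym_def <- list(step_delta = 0, step_mode = "multiplicative",
                   phase_delta = 0, side = "right", speed_gate = NULL)
  asymmetry <- utils::modifyList(asym_def, asymmetry)
  stopifnot(speed_range[1] > 0, speed_range[1] <= speed_range[2],
            asymmetry$side %in% c("left", "right"))
  structure(list(species = species, stride_length = stride_length,
                 swing_time = swing_time, speed_range = speed_range,
                 phase_offset = phase_offset, step_fraction = step_fraction,
                 noise = noise, asymmetry = asymmetry,
                 fore_lead = fore_lead),
            class = "gait_profile")
}

#' @export
print.gait_profile <- function(x, ...) {
  cat("<gait_profile> ", x$species, ", speeds [",
      x$speed_range[1], ", ", x$speed_range[2], "], phase offset ",
      x$phase_offset, ", step fraction ", x$step_fraction, "\n", sep = "")
  if (x$asymmetry$step_delta != 0 || x$asymmetry$phase_delta != 0) {
    cat("  asymmetry on ", x$asymmetry$side, " side: step_delta ",
        x$asymmetry$step_delta, " (", x$asymmetry$step_mode,
        "), phase_delta ", x$asymmetry$phase_delta,
        if (!is.null(x$asymmetry$speed_gate))
          paste0(", gated to [", x$asymmetry$speed_gate[1], ", ",
                 x$asymmetry$speed_gate[2], "]"),
        "\n", sep = "")
  }
  invisible(x)
}

# Generate one homologous pair of event trains. The left limb is the
# reference train; the right limb is placed at configured spatial/temporal
# fractions of each left stride.
gen_pair <- function(profile, n_strides, limbs, x0,
                     subject_id, condition, trial_id, v_target) {
  nz <- profile$noise
  # stride speeds fluctuate around the trial's target speed, as in real
  # walking trials; large stride-to-stride speed jumps do not occur
  v <- v_target * exp(stats::rnorm(n_strides, 0, nz$speed))
  v <- pmin(pmax(v, profile$speed_range[1]), profile$speed_range[2])
  len <- eval_curve(profile$stride_length, v) +
    stats::rnorm(n_strides, 0, nz$stride_length)
  if (any(len <= 0)) stop("profile produced non-positive stride length")
  cyc <- len / v
  swing <- eval_curve(profile$swing_time, v) +
    stats::rnorm(n_strides, 0, nz$swing_time)
  if (any(swing <= 0) || any(swing >= cyc)) {
    stop("profile produced swing times incompatible with cycle durations")
  }
  t_left <- cumsum(c(0, cyc))            # n_strides + 1 stance onsets
  x_left <- x0 + cumsum(c(0, len))
  stance <- cyc - swing
  swing_on_left <- c(t_left[seq_len(n_strides)] + stance,
                     t_left[n_strides + 1] + stance[n_strides])

  asym <- profile$asymmetry
  gated <- if (is.null(asym$speed_gate)) rep(TRUE, n_strides) else
    v >= asym$speed_gate[1] & v <= asym$speed_gate[2]
  frac <- profile$step_fraction +
    stats::rnorm(n_strides, 0, nz$step_fraction)
  if (asym$step_delta != 0) {
    if (asym$side == "right") {
      frac[gated] <- if (asym$step_mode == "multiplicative") {
        frac[gated] * (1 + asym$step_delta)
      } else {
        frac[gated] + asym$step_delta / len[gated]
      }
    } else {
      # shorten/stretch the LEFT step: left step = (1 - frac) * stride
      frac[gated] <- if (asym$step_mode == "multiplicative") {
        1 - (1 - frac[gated]) * (1 + asym$step_delta)
      } else {
        1 - ((1 - frac[gated]) + asym$step_delta / len[gated])
      }
    }
  }
  phase <- profile$phase_offset + stats::rnorm(n_strides, 0, nz$phase)
  phase <- phase + ifelse(gated, asym$phase_delta, 0)
  if (any(frac <= 0 | frac >= 1) || any(phase <= 0 | phase >= 1)) {
    stop("asymmetry/noise pushed step fraction or phase outside (0, 1)")
  }
  t_right <- t_left[seq_len(n_strides)] + phase * cyc
  x_right <- x_left[seq_len(n_strides)] + frac * len
  cyc_r <- diff(t_right)
  v_r <- diff(x_right) / cyc_r
  swing_r <- eval_curve(profile$swing_time, v_r) +
    stats::rnorm(length(v_r), 0, nz$swing_time)
  swing_r <- pmin(pmax(swing_r, 1e-4), cyc_r - 1e-4)
  stance_r <- cyc_r - swing_r
  swing_on_right <- c(t_right[seq_along(stance_r)] + stance_r,
                      t_right[n_strides] + stance_r[length(stance_r)])

  mk <- function(limb, t, x, swing_on) {
    data.frame(subject_id = subject_id, condition = condition,
               trial_id = trial_id, limb = unname(limb), position = unname(x),
               stance_onset = t, swing_onset = swing_on,
               stringsAsFactors = FALSE)
  }
  rbind(mk(limbs["left"], t_left, x_left, swing_on_left),
        mk(limbs["right"], t_right, x_right, swing_on_right))
}

#' Generate one synthetic walking trial
#'
#' Lays down footfall events for every limb of the profiled walker: a trial
#' target speed is drawn from `speed_range`, per stride the speed jitters
#' around that target, the reference (left) limb advances by the
#' stride-length curve value plus noise over a cycle of stride length over
#' speed, and the opposing limb is placed at the configured spatial and
#' temporal fractions of that stride. Quadrupeds get an independent fore
#' pair leading the hind pair by `fore_lead`. Output is bit-reproducible
#' under a fixed seed.
#'
#' @param profile A [gait_profile()].
#' @param n_strides Number of reference-limb strides per pair.
#' @param subject_id,condition,trial_id Identifiers stamped on the events.
#' @param seed Optional integer seed; `NULL` uses the current RNG state (as
#'   when called from [make_cohort()]).
#' @return Footfall-event data frame (passes [validate_footfalls()]).
#' @export
generate_trial <- function(profile, n_strides = 25, subject_id = "s1",
                           condition = "baseline", trial_id = "t1",
                           seed = NULL) {
  stopifnot(inherits(profile, "gait_profile"), n_strides >= 2)
  if (!is.null(seed)) set.seed(seed)
  pairs <- species_pairs(profile$species)
  offsets <- c(hind = 0, fore = profile$fore_lead, legs = 0)
  v_target <- stats::runif(1, profile$speed_range[1], profile$speed_range[2])
  events <- do.call(rbind, lapply(names(pairs), function(nm) {
    gen_pair(profile, n_strides, pairs[[nm]], offsets[[nm]],
             subject_id, condition, trial_id, v_target)
  }))
  rownames(events) <- NULL
  validate_footfalls(events, profile$species)
  events
}

#' Generate a synthetic cohort across conditions
#'
#' Simulates `n_subjects` walkers, each measured under each condition with
#' `n_trials` trials. Between-subject variation is a multiplicative
#' log-normal random effect on the stride-length and swing-time curves.
#' Non-baseline conditions can apply an injected asymmetry (e.g. unilateral
#' step shortening) and/or bilateral scaling of the curves (e.g. symmetric
#' stride-length and swing reduction), emulating unilateral-lesion,
#' bilateral-lesion and control experiments.
#'
#' @param profile Baseline [gait_profile()].
#' @param n_subjects Number of subjects.
#' @param conditions Character vector of condition labels; the first is
#'   baseline.
#' @param n_trials,n_strides Trials per subject per condition, strides per
#'   trial.
#' @param subject_sd SD of the log-normal per-subject curve scaling. The
#'   default (0.02) emulates a carefully matched inbred cohort; the
#'   curve-sharing analyses assume small within-group variation (subjects
#'   as their own controls), so large values violate their premises.
#' @param condition_asymmetry Asymmetry list (see [gait_profile()]) applied
#'   in every non-baseline condition; `NULL` keeps the profile's own.
#' @param condition_scales Named list, e.g.
#'   `list(stride_length = 0.8, swing_time = 0.85)`, multiplying the curves
#'   in non-baseline conditions (bilateral effect).
#' @param seed Optional integer seed for the whole cohort.
#' @return Footfall-event data frame covering all subjects and conditions.
#' @export
make_cohort <- function(profile, n_subjects, conditions = c("baseline", "post"),
                        n_trials = 4, n_strides = 20, subject_sd = 0.02,
                        condition_asymmetry = NULL, condition_scales = NULL,
                        seed = NULL) {
  stopifnot(inherits(profile, "gait_profile"), n_subjects >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_subjects * length(conditions) * n_trials)
  k <- 0L
  for (s in seq_len(n_subjects)) {
    fac_len <- exp(stats::rnorm(1, 0, subject_sd))
    fac_sw <- exp(stats::rnorm(1, 0, subject_sd))
    subj_profile <- profile
    subj_profile$stride_length <- scale_curve(profile$stride_length, fac_len)
    subj_profile$swing_time <- scale_curve(profile$swing_time, fac_sw)
    for (ci in seq_along(conditions)) {
      cond_profile <- subj_profile
      if (ci > 1) {
        if (!is.null(condition_asymmetry)) {
          cond_profile$asymmetry <- utils::modifyList(cond_profile$asymmetry,
                                                      condition_asymmetry)
        }
        if (!is.null(condition_scales)) {
          for (nm in names(condition_scales)) {
            cond_profile[[nm]] <- scale_curve(cond_profile[[nm]],
                                              condition_scales[[nm]])
          }
        }
      }
      for (tr in seq_len(n_trials)) {
        k <- k + 1L
        out[[k]] <- generate_trial(cond_profile, n_strides,
                                   subject_id = sprintf("s%02d", s),
                                   condition = conditions[ci],
                                   trial_id = sprintf("s%02d_%s_t%d", s,
                                                      conditions[ci], tr))
      }
    }
  }
  events <- do.call(rbind, out)
  rownames(events) <- NULL
  events
}
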