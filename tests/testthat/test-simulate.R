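test_that("generation is deterministic under a fixed seed", {
  p <- gait_profile("mouse")
  a <- generate_trial(p, 15, seed = 61)
  b <- generate_trial(p, 15, seed = 61)
  expect_identical(a, b)
  c_ <- generate_trial(p, 15, seed = 62)
  expect_false(identical(a, c_))
  ch1 <- make_cohort(p, 2, n_trials = 2, n_strides = 10, seed = 63)
  ch2 <- make_cohort(p, 2, n_trials = 2, n_strides = 10, seed = 63)
  expect_identical(ch1, ch2)
})

test_that("generated events satisfy every footfall invariant", {
  for (species in c("mouse", "human")) {
    ev <- make_cohort(gait_profile(species), 2, n_trials = 2,
                      n_strides = 12, seed = 64)
    expect_silent(validate_footfalls(ev, species))
    expect_setequal(unique(ev$limb), species_limbs(species))
  }
})

test_that("zero-noise metrics equal the profile curves exactly", {
  p <- zero_noise_profile("mouse")
  ev <- generate_trial(p, 20, seed = 65)
  r <- strides_from_footfalls(ev, "mouse")$records
  lh <- r[r$limb == "LH", ]
  expect_equal(lh$stride_length,
               eval_model(model_spec("one_phase_assoc"), c(2.5, 8, 0.15),
                          lh$stride_velocity), tolerance = 1e-9)
  expect_equal(lh$swing_time, 0.14 - 0.002 * lh$stride_velocity,
               tolerance = 1e-9)
})

test_that("fits on noisy simulated metrics are unbiased within 3 SE", {
  set.seed(66)
  p <- gait_profile("mouse",
                    stride_length = list(family = "linear",
                                         params = c(intercept = 3,
                                                    slope = 0.3)))
  slopes <- vapply(seq_len(120), function(i) {
    # pool several trials so the speeds span the range
    ev <- do.call(rbind, lapply(1:3, function(tr) {
      generate_trial(p, 15, trial_id = paste0("t", tr))
    }))
    r <- strides_from_footfalls(ev, "mouse", pair_steps = FALSE)$records
    lh <- r[r$limb == "LH", ]
    unname(fit_model(lh$stride_velocity, lh$stride_length,
                     model_spec("linear"))$params["slope"])
  }, 0)
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.3), 3 * se)
})

test_that("unilateral scenario: step-length-only asymmetry, side verified", {
  set.seed(67)
  prof <- gait_profile("mouse")
  ev <- make_cohort(prof, n_subjects = 8, n_trials = 4, n_strides = 18,
                    condition_asymmetry = list(step_delta = -0.18,
                                               side = "right"))
  ds <- strides_from_footfalls(ev, "mouse")
  post <- ds$records[ds$records$condition == "post", ]
  xy <- function(limb, metric) {
    s <- post[post$limb == limb, ]
    data.frame(x = s$stride_velocity, y = s[[metric]])
  }
  step_cmp <- compare_curves(xy("LH", "step_length"),
                             xy("RH", "step_length"))
  stride_cmp <- compare_curves(xy("LH", "stride_length"),
                               xy("RH", "stride_length"))
  swing_cmp <- compare_curves(xy("LH", "swing_time"), xy("RH", "swing_time"))
  expect_false(step_cmp$shared)
  expect_true(stride_cmp$shared)
  expect_true(swing_cmp$shared)
  # shorter step on the lesioned (right) side
  expect_lt(mean(xy("RH", "step_length")$y, na.rm = TRUE),
            mean(xy("LH", "step_length")$y, na.rm = TRUE))
})

test_that("bilateral scenario: curves shift but no left-right asymmetry", {
  set.seed(68)
  ev <- make_cohort(gait_profile("mouse"), n_subjects = 8, n_trials = 4,
                    n_strides = 18,
                    condition_scales = list(stride_length = 0.8,
                                            swing_time = 0.85))
  ds <- strides_from_footfalls(ev, "mouse")
  post <- ds$records[ds$records$condition == "post", ]
  xy <- function(limb, metric) {
    s <- post[post$limb == limb, ]
    data.frame(x = s$stride_velocity, y = s[[metric]])
  }
  for (metric in c("step_length", "stride_length", "swing_time")) {
    expect_true(compare_curves(xy("LH", metric), xy("RH", metric))$shared)
  }
})

test_that("control scenario: no change between repeated assessments", {
  set.seed(69)
  ev <- make_cohort(gait_profile("mouse"), n_subjects = 8, n_trials = 4,
                    n_strides = 18, conditions = c("test1", "test2"))
  ds <- strides_from_footfalls(ev, "mouse")
  r <- ds$records
  for (cond in c("test1", "test2")) {
    rc <- r[r$condition == cond & r$limb %in% c("LH", "RH"), ]
    xy <- function(limb) {
      s <- rc[rc$limb == limb, ]
      data.frame(x = s$stride_velocity, y = s$step_length)
    }
    expect_true(compare_curves(xy("LH"), xy("RH"))$shared)
  }
})

test_that("temporal phase offset is recovered by the circular mean", {
  p <- zero_noise_profile("mouse", phase_offset = 0.4,
                          speed_range = c(10, 10))
  ev <- generate_trial(p, 30, seed = 70)
  tp <- temporal_ratios(ev[ev$limb == "RH", ], ev[ev$limb == "LH", ])
  expect_equal(circ_summary(tp)$mean_ratio, 0.4, tolerance = 1e-9)
})
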