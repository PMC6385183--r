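test_that("stride metrics follow directly from footfall definitions", {
  s <- extract_strides(toy_events())
  expect_equal(nrow(s), 1)
  expect_equal(s$stride_length, 6)
  expect_equal(s$cycle_duration, 0.6)
  expect_equal(s$stance_time, 0.4)
  expect_equal(s$swing_time, 0.2)
  expect_equal(s$stride_velocity, 10)
  # single event is a degenerate, not an error
  expect_equal(nrow(extract_strides(toy_events()[1, ])), 0)
})

test_that("stride extraction round-trips the simulator's closed forms", {
  p <- symmetric_profile(speed = 12)
  ev <- generate_trial(p, n_strides = 15, seed = 11)
  ds <- strides_from_footfalls(ev, "mouse")
  r <- ds$records
  expect_true(all(abs(r$stride_velocity - 12) < 1e-9))
  L <- eval_model(model_spec("one_phase_assoc"), c(2.5, 8, 0.15), 12)
  sw <- 0.14 - 0.002 * 12
  expect_true(all(abs(r$stride_length - L) < 1e-9))
  expect_true(all(abs(r$swing_time - sw) < 1e-9))
  # additivity invariant holds for every extracted stride
  expect_true(all(abs(r$swing_time + r$stance_time - r$cycle_duration) < 1e-9))
})

test_that("stride metrics are invariant to translating the origins", {
  p <- gait_profile("mouse")
  ev <- generate_trial(p, n_strides = 12, seed = 3)
  shifted <- ev
  shifted$position <- shifted$position + 123.4
  shifted$stance_onset <- shifted$stance_onset + 55
  shifted$swing_onset <- shifted$swing_onset + 55
  a <- strides_from_footfalls(ev, "mouse")$records
  b <- strides_from_footfalls(shifted, "mouse")$records
  cols <- c("stride_velocity", "stride_length", "step_length", "swing_time",
            "stance_time")
  expect_equal(a[cols], b[cols], tolerance = 1e-9)
})

test_that("step-length pairing uses the most recent opposing placement", {
  left <- data.frame(subject_id = "m1", condition = "c", trial_id = "t",
                     limb = "LH", position = c(5, 11),
                     stance_onset = c(1, 2), swing_onset = c(1.5, 2.5))
  right <- data.frame(subject_id = "m1", condition = "c", trial_id = "t",
                      limb = "RH", position = c(2, 12),
                      stance_onset = c(0.5, 1.6), swing_onset = c(1.1, 2.1))
  s <- pair_step_lengths(extract_strides(left), right)
  expect_equal(s$step_length, 3)  # 5 - 2
  # placed behind the opposing limb: negative step length preserved
  right2 <- right
  right2$position <- c(6, 12)
  s2 <- pair_step_lengths(extract_strides(left), right2)
  expect_equal(s2$step_length, -1)
  # non-homologous pair is an error
  fore <- right
  fore$limb <- "RF"
  expect_error(pair_step_lengths(extract_strides(left), fore),
               "homologous")
  # mismatched trial is an error
  other <- right
  other$trial_id <- "t2"
  expect_error(pair_step_lengths(extract_strides(left), other), "same")
})

test_that("steady symmetric gait: left step + right step = stride length", {
  ev <- generate_trial(symmetric_profile(), n_strides = 20, seed = 7)
  ds <- strides_from_footfalls(ev, "mouse")
  r <- ds$records[ds$records$limb %in% c("LH", "RH"), ]
  lh <- mean(r$step_length[r$limb == "LH"], na.rm = TRUE)
  rh <- mean(r$step_length[r$limb == "RH"], na.rm = TRUE)
  expect_equal(lh + rh, mean(r$stride_length), tolerance = 1e-9)
})

test_that("speed-range filtering keeps the closed window", {
  rec <- extract_strides(toy_events())
  rec <- rec[rep(1, 3), ]
  rec$stride_velocity <- c(2, 5, 17)
  out <- filter_speed_range(rec, 3, 16, quiet = TRUE)
  expect_equal(nrow(out), 1)
  expect_equal(out$stride_velocity, 5)
  # identity when all speeds inside; empty result warns
  expect_equal(nrow(filter_speed_range(rec, 1, 20, quiet = TRUE)), 3)
  expect_warning(filter_speed_range(rec, 30, 40, quiet = TRUE), "no strides")
  expect_error(filter_speed_range(rec, 16, 3), "lo < hi")
})

test_that("footfall validation pinpoints bad rows", {
  ev <- toy_events()
  ev$swing_onset[2] <- 0.5  # before its stance onset
  expect_error(validate_footfalls(ev), "row 2")
  ev2 <- toy_events()
  ev2$limb <- "L"
  expect_error(validate_footfalls(ev2, "mouse"), "invalid limb")
  ev3 <- rbind(toy_events(), toy_events()[1, ])
  expect_error(validate_footfalls(ev3), "duplicate")
})
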