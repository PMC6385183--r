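test_that("alternation ratios follow their definitions", {
  # reference limb B strides 0->6 over [0, 0.6); stepping limb A events
  b <- data.frame(subject_id = "m1", condition = "c", trial_id = "t",
                  limb = "LH", position = c(0, 6, 12),
                  stance_onset = c(0, 0.6, 1.2),
                  swing_onset = c(0.4, 1.0, 1.6))
  a <- data.frame(subject_id = "m1", condition = "c", trial_id = "t",
                  limb = "RH", position = c(3, 8),
                  stance_onset = c(0.3, 0.75),
                  swing_onset = c(0.55, 1.05))
  sp <- spatial_ratios(a, b)
  expect_equal(sp$ratio, c(0.5, 1 / 3))     # steps 3 and 2 over stride 6
  expect_equal(sp$speed, c(10, 10))
  tp <- temporal_ratios(a, b)
  expect_equal(tp$ratio, c(0.5, 0.25))      # offsets 0.3 and 0.15 of 0.6 s
  # negative step wraps circularly: -0.1 -> 0.9
  a2 <- a[1, ]; a2$position <- -0.6
  expect_equal(spatial_ratios(a2, b)$ratio, 0.9)
  # a cycle with no opposing footfall is skipped and counted
  a3 <- a[1, ]
  tp3 <- temporal_ratios(a3, b)
  expect_equal(nrow(tp3), 1)
  expect_equal(attr(tp3, "n_skipped"), 1L)
})

test_that("circular summary matches the naive vector-sum oracle", {
  expect_equal(circ_summary(c(0.5, 0.5, 0.5))$mean_ratio, 0.5)
  expect_equal(circ_summary(c(0.5, 0.5, 0.5))$r, 1)
  # antipodal ratios cancel: undefined mean flagged
  s <- circ_summary(c(0, 0.5))
  expect_false(s$mean_defined)
  expect_lt(s$r, 1e-12)
  set.seed(41)
  ratios <- runif(1000)
  got <- circ_summary(ratios)
  want <- oracle_circ(ratios)
  expect_equal(got$mean_ratio, want$mean_ratio, tolerance = 1e-12)
  expect_equal(got$r, want$r, tolerance = 1e-12)
})

test_that("circular summaries are rotation- and reflection-equivariant", {
  set.seed(42)
  ratios <- rnorm(200, 0.5, 0.05) %% 1
  base <- circ_summary(ratios)
  for (delta in c(0.1, 0.37, 0.9)) {
    rot <- circ_summary((ratios + delta) %% 1)
    expect_equal(rot$r, base$r, tolerance = 1e-12)
    d <- (rot$mean_ratio - base$mean_ratio) %% 1
    expect_equal(min(abs(d - delta), abs(d - delta + 1)), 0,
                 tolerance = 1e-9)
  }
  refl <- circ_summary((1 - ratios) %% 1)
  expect_equal(refl$r, base$r, tolerance = 1e-12)
  circ_dist <- function(a, b) {
    d <- abs(a - b) %% 1
    min(d, 1 - d)
  }
  expect_equal(circ_dist(refl$mean_ratio, (1 - base$mean_ratio) %% 1), 0,
               tolerance = 1e-9)
})

test_that("Watson-Williams detects concentrated mean-direction shifts", {
  set.seed(43)
  a <- rnorm(50, 0.50, 0.03) %% 1
  b <- rnorm(50, 0.40, 0.03) %% 1
  ww <- watson_williams(a, b)
  expect_lt(ww$p, 0.05)
  expect_true(ww$significant)
  # identical samples: F = 0, p = 1
  ww0 <- watson_williams(a, a)
  expect_equal(ww0$F, 0, tolerance = 1e-9)
  expect_equal(ww0$p, 1, tolerance = 1e-9)
  # invariant under a common rotation of both samples
  ww_rot <- watson_williams((a + 0.25) %% 1, (b + 0.25) %% 1)
  expect_equal(ww$F, ww_rot$F, tolerance = 1e-9)
})

test_that("Watson-Williams p tracks a permutation oracle", {
  set.seed(44)
  for (shift in c(0.012, 0.02)) {
    a <- rnorm(40, 0.5, 0.04) %% 1
    b <- rnorm(40, 0.5 + shift, 0.04) %% 1
    p_param <- watson_williams(a, b)$p
    p_perm <- oracle_ww_perm_p(a, b, n_perm = 4000)
    expect_lt(abs(p_param - p_perm), 0.01)
  }
})

test_that("speed bins split half-open with the boundary in the upper bin", {
  s <- new_series_for_test <- structure(
    data.frame(ratio = c(0.5, 0.6, 0.4), speed = c(5, 10, 12)),
    kind = "spatial", limb_pair = "hind", condition = "c",
    class = c("alternation_series", "data.frame"))
  bins <- bin_by_speed(s, c(3, 10, 16))
  expect_equal(nrow(bins[[1]]), 1)
  expect_equal(nrow(bins[[2]]), 2)   # speed 10 goes to the upper bin
  expect_equal(bins[[2]]$speed, c(10, 12))
})

test_that("speed-gated asymmetry shows up in the upper bin only", {
  set.seed(45)
  base_prof <- gait_profile("mouse")
  lesion_prof <- gait_profile("mouse", asymmetry = list(
    step_delta = -0.22, side = "right", speed_gate = c(10, 16)))
  get_series <- function(prof, cond) {
    ev <- do.call(rbind, lapply(1:10, function(i) {
      generate_trial(prof, 25, subject_id = sprintf("s%d", i),
                     condition = cond, trial_id = sprintf("%s_%d", cond, i))
    }))
    spatial_ratios(ev[ev$limb == "RH", ], ev[ev$limb == "LH", ])
  }
  s1 <- get_series(base_prof, "base")
  s2 <- get_series(lesion_prof, "post")
  b1 <- bin_by_speed(s1); b2 <- bin_by_speed(s2)
  low <- watson_williams(b1[[1]], b2[[1]])
  high <- watson_williams(b1[[2]], b2[[2]])
  expect_gt(low$p, 0.05)
  expect_lt(high$p, 0.05)
})

test_that("polar export flattens summaries and raw ratios losslessly", {
  s <- circ_summary(c(0.5, 0.5))
  tab <- polar_export(list(base = s), list(base = c(0.5, 0.5)))
  srow <- tab[tab$type == "summary", ]
  expect_equal(srow$angle_rad, pi)
  expect_equal(srow$radius, 1)
  # empty input: header-only table
  empty <- polar_export()
  expect_equal(nrow(empty), 0)
  expect_equal(names(empty),
               c("group", "type", "ratio", "angle_rad", "radius"))
  # round-trip through CSV preserves the summary numerically
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  back <- utils::read.csv(f)
  expect_equal(back$radius, tab$radius, tolerance = 1e-12)
  expect_equal(back$angle_rad, tab$angle_rad, tolerance = 1e-12)
})
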