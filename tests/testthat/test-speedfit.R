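test_that("model families evaluate to their closed forms", {
  lin <- model_spec("linear")
  expect_equal(eval_model(lin, c(0, 1), 7), 7)
  op <- model_spec("one_phase_assoc")
  # asymptote: large K saturates at the plateau
  expect_equal(eval_model(op, c(0, 1, 1e6), 3), 1, tolerance = 1e-12)
  expect_equal(eval_model(op, c(0.6, 0.1, 0.3), 5),
               0.6 + (0.1 - 0.6) * (1 - exp(-1.5)))
  expect_error(eval_model(op, c(0, 1, -1), 2), "positive")
  tp <- model_spec("two_phase_assoc")
  expect_equal(eval_model(tp, c(1, 2, 0.9, 3, 0.1), 4),
               1 + 2 * (1 - exp(-3.6)) + 3 * (1 - exp(-0.4)))
})

test_that("fitting recovers exact and noiseless parameters", {
  # collinear points: zero residual, exact parameters
  f <- fit_model(c(1, 2, 3), c(3, 5, 7), model_spec("linear"))
  expect_equal(f$ss_resid, 0, tolerance = 1e-20)
  expect_equal(unname(f$params), c(1, 2))
  # noiseless one-phase and two-phase recovery to 1e-6 relative error
  x <- seq(0.5, 25, length.out = 20)
  truth1 <- c(1, 8, 0.25)
  y1 <- eval_model(model_spec("one_phase_assoc"), truth1, x)
  f1 <- fit_model(x, y1, model_spec("one_phase_assoc"))
  expect_true(f1$converged)
  expect_lt(max(abs(f1$params - truth1) / truth1), 1e-6)
  truth2 <- c(0.5, 3, 1.2, 4, 0.12)
  y2 <- eval_model(model_spec("two_phase_assoc"), truth2, x)
  f2 <- fit_model(x, y2, model_spec("two_phase_assoc"))
  expect_true(f2$converged)
  expect_lt(max(abs(f2$params - truth2) / abs(truth2)), 1e-6)
  # fast/slow label switching is resolved
  expect_gt(f2$params["KFast"], f2$params["KSlow"])
})

test_that("linear slope estimate lands within 3 SE of truth", {
  set.seed(42)
  x <- runif(200, 0, 10)
  y <- x + rnorm(200)
  f <- fit_model(x, y, model_spec("linear"))
  se <- sqrt((f$ss_resid / f$df) / sum((x - mean(x))^2))
  expect_lt(abs(f$params["slope"] - 1), 3 * se)
})

test_that("extra sum-of-squares F test follows its definition", {
  x <- seq(1, 20); set.seed(1)
  y <- 2 + 0.1 * x + rnorm(20, 0, 0.1)
  fs <- fit_model(x, y, model_spec("linear"))
  fc <- fit_model(x, y, model_spec("one_phase_assoc"))
  t1 <- extra_ss_ftest(fs, fc)
  expect_equal(t1$F, max(0, ((fs$ss_resid - fc$ss_resid) / 1) /
                 (fc$ss_resid / fc$df)))
  # hand-built SS/df arithmetic: SS 10 -> 5, df 18 -> 17 gives F = 17
  fake_s <- structure(list(model = model_spec("linear"), ss_resid = 10,
                           n = 20, df = 18, converged = TRUE),
                      class = "gait_fit")
  fake_c <- structure(list(model = model_spec("one_phase_assoc"),
                           ss_resid = 5, n = 20, df = 17, converged = TRUE),
                      class = "gait_fit")
  t2 <- extra_ss_ftest(fake_s, fake_c)
  expect_equal(t2$F, 17)
  # equal SS: F = 0, p = 1
  fake_c2 <- fake_c; fake_c2$ss_resid <- 10
  t3 <- extra_ss_ftest(fake_s, fake_c2)
  expect_equal(t3$F, 0)
  expect_equal(t3$p, 1)
})

test_that("model selection promotes only on evidence of curvature", {
  set.seed(5)
  x <- runif(80, 3, 16)
  y_lin <- 1 + 0.2 * x + rnorm(80, 0, 0.1)
  expect_equal(select_model(x, y_lin)$model$family, "linear")
  y_sat <- eval_model(model_spec("one_phase_assoc"), c(1, 5, 0.4), x) +
    rnorm(80, 0, 0.1)
  expect_equal(select_model(x, y_sat)$model$family, "one_phase_assoc")
  # too few points: degrees of freedom force the linear family
  sel <- select_model(c(1, 2, 3), c(1.1, 2.2, 2.8))
  expect_equal(sel$model$family, "linear")
})

test_that("residual SS is non-increasing along the model ladder", {
  set.seed(8)
  x <- runif(60, 1, 20)
  y <- eval_model(model_spec("one_phase_assoc"), c(0.5, 4, 0.3), x) +
    rnorm(60, 0, 0.2)
  fits <- lapply(model_ladder(), function(m) fit_model(x, y, m))
  ss <- vapply(fits, `[[`, 0, "ss_resid")
  expect_true(all(diff(ss) <= 1e-8))
})

test_that("speed-range sweep maps where each family holds", {
  set.seed(9)
  x <- runif(400, 0.5, 25)
  y <- 1 + 0.2 * x + rnorm(400, 0, 0.1)
  sw <- sweep_speed_ranges(x, y, lo_values = 0:4, hi_values = 25:21)
  expect_true(all(sw$grid$family[!is.na(sw$grid$family)] == "linear"))
  expect_equal(sw$family, "linear")
  # curvature confined below 3: windows excluding it go linear
  y2 <- y + ifelse(x < 3, 3 * (3 - x)^2, 0)
  sw2 <- sweep_speed_ranges(x, y2, lo_values = 0:4, hi_values = 25:21)
  g <- sw2$grid
  above <- g[g$lo >= 3 & !is.na(g$family), ]
  expect_true(all(above$family == "linear"))
  # windows containing the strongly curved region are never called linear
  low <- g[g$lo <= 1 & !is.na(g$family), ]
  expect_true(all(low$family != "linear"))
  # the widest consistently-linear window sits above the curved region
  expect_equal(sw2$family, "linear")
  expect_gt(sw2$window["lo"], 1)
})

test_that("stance transform is the documented bijection", {
  expect_equal(stance_transform(5, 1)$y, 1)    # log10(1) = 0
  expect_equal(stance_transform(1, 0.5)$x, 1)  # log10(1) + 1 = 1
  speed <- c(0.4, 0.9, 1.4)
  stance <- c(1.1, 0.8, 0.6)
  tr <- stance_transform(speed, stance)
  back <- stance_backtransform(tr$x, tr$y)
  expect_equal(back$speed, speed, tolerance = 1e-12)
  expect_equal(back$stance_time, stance, tolerance = 1e-12)
  # non-positive inputs are excluded and counted
  tr2 <- stance_transform(c(1, -1, 2), c(1, 1, 0))
  expect_equal(nrow(tr2), 1)
  expect_equal(attr(tr2, "n_excluded"), 2)
})

test_that("runs test matches its closed-form normal approximation", {
  # (+,+,+,-,-,-): R = 2, mu = 4, sigma^2 = 1.2
  rt <- runs_test(c(1, 1, 1, -1, -1, -1), reference = 0)
  expect_equal(rt$n_runs, 2)
  expect_equal(rt$Z, (2 - 4) / sqrt(1.2))
  # maximal alternation gives Z > 0
  rt2 <- runs_test(rep(c(1, -1), 3), reference = 0)
  expect_equal(rt2$n_runs, 6)
  expect_gt(rt2$Z, 0)
  expect_error(runs_test(c(1, 2, 3), reference = 0), "one side")
})

test_that("exact runs-test p agrees with brute-force enumeration", {
  set.seed(13)
  for (rep in 1:8) {
    n <- sample(5:10, 1)
    signs <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(signs)) < 2) signs[1] <- -signs[2]
    p_exact <- runs_test(signs, reference = 0, method = "exact")$p
    expect_equal(p_exact, oracle_runs_p(signs), tolerance = 1e-12)
  }
})

test_that("per-subject averaged analysis matches the paired-t formula", {
  p <- gait_profile("mouse")
  ev <- make_cohort(p, n_subjects = 5, conditions = "baseline",
                    n_trials = 2, n_strides = 15, seed = 21)
  ds <- strides_from_footfalls(ev, "mouse")
  out <- averaged_analysis(ds, "step_length", pair = "hind")
  d <- out$means$left - out$means$right
  t_hand <- mean(d) * sqrt(length(d)) / sd(d)
  expect_equal(unname(out$t_test$statistic), t_hand, tolerance = 1e-12)
  # identical sides: t = 0, p = 1
  sym <- ds$records
  sym_r <- sym[sym$limb == "LH", ]
  sym_r$limb <- "RH"
  both <- rbind(sym[sym$limb == "LH", ], sym_r)
  out2 <- suppressWarnings(
    averaged_analysis(gait_dataset(both, "mouse"), "step_length",
                      pair = "hind"))
  expect_equal(unname(out2$t_test$statistic[[1]]), 0)
  expect_equal(out2$t_test$p.value, 1)
})
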