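# Shared fixtures: all synthetic, built in code at test time.

# Two-event left-hind trial with hand-computable metrics.
toy_events <- function() {
  data.frame(subject_id = "m1", condition = "base", trial_id = "t1",
             limb = "LH",
             position = c(0, 6), stance_onset = c(0, 0.6),
             swing_onset = c(0.4, 1.0), stringsAsFactors = FALSE)
}

# Deterministic symmetric walker: zero noise, constant speed, so every
# spatial and temporal alternation ratio is exactly 0.5.
no_noise <- list(stride_length = 0, swing_time = 0, step_fraction = 0,
                 phase = 0, speed = 0)

symmetric_profile <- function(species = "mouse", speed = 12) {
  gait_profile(species, noise = no_noise, speed_range = c(speed, speed))
}

zero_noise_profile <- function(species = "mouse", ...) {
  gait_profile(species, noise = no_noise, ...)
}

# Independent vector-sum oracle for circular summaries (kept deliberately
# naive: loop accumulation, no shared code with circ_summary).
oracle_circ <- function(ratios) {
  cc <- 0; ss <- 0
  for (r in ratios) {
    a <- 2 * pi * (r - floor(r))
    cc <- cc + cos(a)
    ss <- ss + sin(a)
  }
  mu <- atan2(ss, cc)
  if (mu < 0) mu <- mu + 2 * pi
  list(mean_ratio = mu / (2 * pi),
       r = sqrt(cc^2 + ss^2) / length(ratios))
}

# Brute-force runs-test tail probabilities: enumerate every arrangement of
# n1 "+" and n2 "-" signs, count runs, and accumulate the exact two-sided
# p for an observed run count.
oracle_runs_p <- function(signs) {
  n1 <- sum(signs > 0); n2 <- sum(signs < 0); n <- n1 + n2
  count_runs <- function(s) 1L + sum(diff(s) != 0)
  r_obs <- count_runs(signs)
  pos_sets <- utils::combn(n, n1)
  total <- ncol(pos_sets)
  lo <- 0L; hi <- 0L
  for (j in seq_len(total)) {
    s <- rep(-1L, n)
    s[pos_sets[, j]] <- 1L
    r <- count_runs(s)
    if (r <= r_obs) lo <- lo + 1L
    if (r >= r_obs) hi <- hi + 1L
  }
  min(1, 2 * min(lo / total, hi / total))
}

# Permutation oracle for the Watson-Williams test: permutes group labels and
# uses the absolute circular mean-direction difference as the statistic.
oracle_ww_perm_p <- function(a, b, n_perm = 1e4) {
  ang <- 2 * pi * ((c(a, b)) %% 1)
  n1 <- length(a)
  circ_mean <- function(th) atan2(sum(sin(th)), sum(cos(th)))
  ang_diff <- function(x, y) {
    d <- abs(x - y) %% (2 * pi)
    min(d, 2 * pi - d)
  }
  obs <- ang_diff(circ_mean(ang[seq_len(n1)]), circ_mean(ang[-seq_len(n1)]))
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(ang), n1)
    d <- ang_diff(circ_mean(ang[idx]), circ_mean(ang[-idx]))
    if (d >= obs) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}
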