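ramp_trace <- function(baseline = 0) {
  t <- seq(0, 120, by = 0.1)
  f <- rep(baseline, length(t))
  rising <- t > 20 & t <= 70
  f[rising] <- baseline + (t[rising] - 20) * 2   # 0 -> 100 mN in 50 ms
  f[t > 70] <- baseline + 100
  tr <- force_trace(t, f)
  attr(tr, "stim_events") <- stim_events("train", 20, 120,
                                         frequency_hz = 400)
  tr
}

test_that("MRFD is exact on a linear ramp", {
  m <- mrfd(ramp_trace())
  expect_equal(m$mrfd_mN_per_ms, 2, tolerance = 1e-6)
  expect_equal(m$f_max_mN, 100, tolerance = 1e-6)
  expect_equal(m$mrfd_over_fmax, 0.02, tolerance = 1e-6)
})

test_that("MRFD recovers the analytic slope of an exponential rise", {
  gt <- ground_truth(F_opt = 200, rise_tau = 20, noise_sd = 0)
  tr <- simulate_tetanus_trace(gt, duration_ms = 150, sampling_hz = 10000)
  m <- mrfd(tr)
  expect_equal(m$mrfd_mN_per_ms, 10, tolerance = 0.02)
})

test_that("MRFD is invariant to a baseline offset", {
  m0 <- mrfd(ramp_trace(baseline = 0))
  m50 <- mrfd(ramp_trace(baseline = 50))
  expect_equal(m50$mrfd_mN_per_ms, m0$mrfd_mN_per_ms, tolerance = 1e-9)
  expect_equal(m50$f_max_mN, m0$f_max_mN, tolerance = 1e-9)
})

test_that("MRFD on a noisy train stays near the analytic value", {
  gt <- ground_truth(F_opt = 200, rise_tau = 20, noise_sd = 2)
  tr <- simulate_tetanus_trace(gt, duration_ms = 150, sampling_hz = 10000,
                               seed = 42)
  m <- mrfd(tr)
  expect_equal(m$mrfd_mN_per_ms, 10, tolerance = 0.1)
})

test_that("MRFD rejects a rise shorter than its smoothing window", {
  t <- seq(0, 30, by = 0.1)
  f <- ifelse(t < 20, 0, pmin((t - 20) * 50, 100))  # 2-ms rise
  tr <- force_trace(t, f)
  ev <- stim_events("train", 20, 30, frequency_hz = 400)
  expect_error(mrfd(tr, ev, smooth_ms = 5), "smooth")
})

test_that("force-frequency normalization peaks at exactly one", {
  act <- c(50, 120, 200, 240, 250)
  curve <- force_frequency_curve(c(5, 20, 50, 100, 150), act + 10,
                                 passive_force_mN = 10)
  expect_equal(curve$relative_force, act / 250)
  expect_equal(max(curve$relative_force), 1)
  expect_equal(curve$relative_force[1], 0.2)

  flat <- force_frequency_curve(c(5, 50, 150), rep(80, 3), 0)
  expect_equal(flat$relative_force, rep(1, 3))
})

test_that("force-frequency matches the brute-force division oracle", {
  f <- c(5, 10, 20, 40, 80, 150, 250)
  total <- 250 / (1 + exp(-(f - 40) / 15)) + 12
  curve <- force_frequency_curve(f, total, passive_force_mN = 12)
  oracle <- (total - 12) / max(total - 12)
  expect_identical(curve$relative_force, oracle)
  expect_true(all(diff(curve$relative_force) >= 0))  # monotone input
})

test_that("force-frequency input validation", {
  expect_error(force_frequency_curve(c(5, 50), c(1, 2), 0), "3 frequencies")
  expect_error(force_frequency_curve(c(5, 50, 100), c(1, 2, 3), 10),
               "not positive")
})

test_that("fatigue index trivial and scaling properties", {
  expect_equal(fatigue_index(rep(100, 10))$fatigue_index_pct, 0)
  expect_equal(fatigue_index(c(100, 90, 75, 60))$fatigue_index_pct, 40)
  pk <- c(100, 95, 80, 70, 66)
  expect_equal(fatigue_index(pk * 3.7)$fatigue_index_pct,
               fatigue_index(pk)$fatigue_index_pct, tolerance = 1e-12)
  expect_error(fatigue_index(100), "2 contractions")
  expect_error(fatigue_index(c(0, 0)), "positive")
  mk <- fatigue_index(pk, f_end_rule = "mean_last_k", k = 2)
  expect_equal(mk$F_end, 68)
})

test_that("contraction peaks are recovered from a 1-Hz trace", {
  t <- seq(0, 4999, by = 1)
  f <- rep(2, length(t))
  true_peaks <- c(100, 90, 82, 76, 72)
  for (k in 0:4) {
    w <- t >= k * 1000 + 100 & t <= k * 1000 + 400
    f[w] <- true_peaks[k + 1] * sin((t[w] - (k * 1000 + 100)) / 300 * pi)
  }
  pk <- extract_contraction_peaks(force_trace(t, f), period_ms = 1000)
  expect_equal(pk, true_peaks, tolerance = 0.01)
})

test_that("force traces enforce uniform sampling", {
  expect_error(force_trace(c(0, 1, 2.5, 3), rep(0, 4)), "non-uniform")
  expect_error(force_trace(c(0, 1, 1), rep(0, 3)), "increasing")
  tr <- force_trace(seq(0, 10, 0.5), rep(1, 21))
  expect_equal(attr(tr, "sampling_rate_hz"), 2000)
})
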