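test_that("ground truth validates its invariants", {
  expect_error(ground_truth(L_opt = 12, L_slack = 12), "L_slack")
  expect_error(ground_truth(L_opt = 12, L_slack = 13), "L_slack")
  expect_error(ground_truth(noise_sd = -1), "noise_sd")
  expect_error(ground_truth(F_opt = 0), "F_opt")
  expect_error(ground_truth(fatigue_asymptote_frac = 1.2),
               "fatigue_asymptote_frac")
  expect_error(ground_truth(rise_tau = -5), "rise_tau")
})

test_that("noise-free length series equals the analytic decomposition", {
  gt <- gt_noiseless()
  L <- seq(11, 16, by = 0.5)
  s <- simulate_length_series(gt, L, seed = 1)
  expect_equal(active_curve(gt, 15), 300)
  expect_equal(active_curve(gt, 11), 0)
  # total - passive reproduces the analytic active curve to machine precision
  expect_equal(s$total_force_mN - s$passive_force_mN, active_curve(gt, L),
               tolerance = 1e-12)
  expect_equal(s$passive_force_mN, passive_curve(gt, L), tolerance = 1e-12)
})

test_that("length-series generator enforces its preconditions", {
  gt <- gt_noiseless()
  expect_error(simulate_length_series(gt, c(11, 12, 13, 14, 15)), "6")
  expect_error(simulate_length_series(gt, c(11, 13, 12, 14, 15, 16)),
               "increasing")
})

test_that("generators are bit-reproducible for a fixed seed", {
  gt <- gt_study()
  L <- seq(11, 16, by = 0.5)
  expect_identical(simulate_length_series(gt, L, seed = 42),
                   simulate_length_series(gt, L, seed = 42))
  expect_false(isTRUE(all.equal(
    simulate_length_series(gt, L, seed = 42)$total_force_mN,
    simulate_length_series(gt, L, seed = 43)$total_force_mN)))
  expect_identical(simulate_fatigue_series(gt, 50, seed = 7),
                   simulate_fatigue_series(gt, 50, seed = 7))
  expect_identical(simulate_tetanus_trace(gt, 50, seed = 9)$force_mN,
                   simulate_tetanus_trace(gt, 50, seed = 9)$force_mN)
})

test_that("tetanus trace follows the saturating exponential", {
  gt <- ground_truth(F_opt = 200, rise_tau = 20, noise_sd = 0)
  tr <- simulate_tetanus_trace(gt, duration_ms = 200, sampling_hz = 10000)
  # plateau approaches F_opt
  expect_equal(max(tr$force_mN), 200 * (1 - exp(-200 / 20)),
               tolerance = 1e-9)
  # steepest raw rise approximates the analytic slope F_opt / tau
  dt <- 0.1
  expect_equal(max(diff(tr$force_mN)) / dt, 10, tolerance = 0.02)
  expect_error(simulate_tetanus_trace(gt, 150, sampling_hz = 500),
               "sampling_hz")
})

test_that("fatigue series matches its closed form", {
  gt0 <- ground_truth(fatigue_asymptote_frac = 1, noise_sd = 0)
  expect_equal(fatigue_index(
    simulate_fatigue_series(gt0, 120, seed = 1))$fatigue_index_pct, 0)
  gt1 <- ground_truth(fatigue_asymptote_frac = 0.6, fatigue_rate = 2,
                      noise_sd = 0)
  expect_equal(fatigue_index(
    simulate_fatigue_series(gt1, 120, seed = 1))$fatigue_index_pct, 40,
    tolerance = 1e-6)
  gt2 <- ground_truth(fatigue_asymptote_frac = 0.84, fatigue_rate = 0.05,
                      noise_sd = 0)
  pk <- simulate_fatigue_series(gt2, 120, seed = 1)
  a <- 0.84; r <- 0.05
  closed <- 100 * (1 - (a + (1 - a) * exp(-r * 119)))
  expect_equal(fatigue_index(pk)$fatigue_index_pct, closed,
               tolerance = 1e-9)
})

test_that("fiber cohort carries exact sarcomere bookkeeping", {
  spec <- fiber_cohort_spec(n_fibers = 20, nuclei_per_mm = 0)
  coh <- simulate_fiber_cohort(spec, seed = 3)
  expect_true(all(coh$counted_profiles == 0))
  # serial sarcomere number recomputed from the cohort's own columns
  expect_equal(serial_sarcomere_number(coh$fiber_length_mm, coh$mean_sl_um),
               coh$n_sarcomeres, tolerance = 1e-12)
})

test_that("nucleus-slab sampling obeys the section-correction expectation", {
  counts <- sample_nucleus_profiles(440, 4400, nucleus_um = 12,
                                    section_um = 10, n_slabs = 1e4,
                                    seed = 11)
  expect_equal(mean(counts), 440 * 22 / 4400, tolerance = 0.02)
  expect_error(sample_nucleus_profiles(10, 20, nucleus_um = 12,
                                       section_um = 10), "exceeds")
})

test_that("section-corrected counting inverts the slab sampling", {
  # recovery experiment: per-fiber profile counts averaged over 25 random
  # sections each, so the assertion probes bias rather than sampling noise
  spec <- fiber_cohort_spec(n_fibers = 500, nuclei_per_mm = 100)
  coh <- simulate_fiber_cohort(spec, seed = 5, n_slabs = 25)
  est <- myonuclei_per_fiber(coh$counted_profiles,
                             coh$fiber_length_mm * 1000)
  bias <- (mean(est) - mean(coh$true_nuclei)) / mean(coh$true_nuclei)
  expect_lt(abs(bias), 0.02)
})

test_that("synthetic sections honour their geometric spec", {
  sp0 <- section_spec(n_fibers = 16, endomysium_thickness_um = 0,
                      mean_fiber_diameter_um = 30, pixel_size_um = 1)
  s0 <- simulate_section(sp0, seed = 2)
  expect_equal(sum(s0$connective), 0)

  sp <- section_spec(n_fibers = 25, endomysium_thickness_um = 3,
                     mean_fiber_diameter_um = 40, pixel_size_um = 1)
  s <- simulate_section(sp, seed = 2)
  truth <- attr(s, "truth")
  meas <- fiber_csa_stats(s, warn_below = 0)$per_fiber
  expect_identical(truth$area_um2, meas$area_um2)  # truth == mask by construction
  expect_error(section_spec(n_fibers = 100, mean_fiber_diameter_um = 40,
                            pixel_size_um = 0.5, image_size_px = 100),
               "too small")
})
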