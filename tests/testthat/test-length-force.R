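test_that("passive force is the mean between second twitch and tetanus", {
  flat <- passive_protocol_trace(function(t) rep(5, length(t)))
  expect_equal(extract_passive_force(flat$trace, flat$events), 5)

  zero <- passive_protocol_trace(function(t) rep(0, length(t)))
  expect_equal(extract_passive_force(zero$trace, zero$events), 0)

  # baseline drifting linearly 4 -> 6 mN across the (400, 800) ms window
  drift <- passive_protocol_trace(function(t) {
    ifelse(t <= 400, 4, ifelse(t >= 800, 6, 4 + (t - 400) / 400 * 2))
  })
  expect_equal(extract_passive_force(drift$trace, drift$events), 5,
               tolerance = 1e-9)
})

test_that("missing stimulation markers are reported by name", {
  p <- passive_protocol_trace(function(t) rep(5, length(t)))
  one_twitch <- p$events[c(1, 3), ]
  expect_error(extract_passive_force(p$trace, one_twitch), "twitch")
  no_tet <- p$events[1:2, ]
  expect_error(extract_passive_force(p$trace, no_tet), "tetanus")
})

test_that("passive fit recovers exponential coefficients from clean data", {
  L <- seq(11, 16, length.out = 8)
  y <- exp(-12 + 0.9 * L) + 1
  fit <- fit_passive(L, y)
  expect_equal(unname(fit$coefficients),
               c(-12, 0.9, 1), tolerance = 1e-3)
  expect_lt(fit$rss, 1e-8)
  expect_equal(predict(fit, L), y, tolerance = 1e-5)
})

test_that("passive fit handles the quadratic form and degenerate input", {
  L <- seq(11, 16, length.out = 8)
  yq <- exp(-40 + 5 * L - 0.12 * L^2)
  fq <- fit_passive(L, yq, form = "exp-quadratic")
  expect_equal(predict(fq, L), yq, tolerance = 1e-6)

  zero <- fit_passive(L, rep(0, 8))
  expect_true(zero$degenerate)
  expect_equal(predict(zero, L), rep(0, 8))

  expect_error(fit_passive(c(11, 12, 13), c(1, 2, 3)), "4 points")
})

test_that("active force is total minus measured passive, unclipped", {
  pts <- length_force_points(c(11, 12, 13, 14, 15, 16),
                             c(5, 40, 150, 280, 310, 250),
                             c(6, 10, 12, 15, 10, 20))
  a <- active_forces(pts)
  expect_equal(a$active_force_mN,
               c(-1, 30, 138, 265, 300, 230))  # negatives retained
})

test_that("order selection finds the generating polynomial order", {
  x <- seq(11, 16, length.out = 10)
  parab <- 300 - 12 * (x - 15)^2
  expect_equal(select_polynomial_order(x, parab)$order, 2)

  cubic <- 300 - 12 * (x - 15)^2 + 4 * (x - 15)^3
  sel <- select_polynomial_order(x, cubic)
  expect_equal(sel$order, 3)
  # the 2 -> 3 step's F statistic matches the direct extra-RSS computation
  f2 <- lm(cubic ~ poly(x, 2, raw = TRUE))
  f3 <- lm(cubic ~ poly(x, 3, raw = TRUE))
  step <- sel$selection_table[1, ]
  expect_equal(step$rss_low, sum(residuals(f2)^2), tolerance = 1e-8)
  expect_lt(step$p, 0.05)
})

test_that("order selection is invariant to force rescaling", {
  set.seed(31)
  x <- seq(11, 16, length.out = 11)
  for (i in 1:20) {
    y <- 300 - 12 * (x - 15)^2 + 4 * (x - 15)^3 + rnorm(11, 0, 6)
    o1 <- select_polynomial_order(x, y)$order
    o2 <- select_polynomial_order(x, y * 1e3)$order
    expect_identical(o1, o2)
  }
})

test_that("order selection degrades gracefully with few points", {
  x <- seq(11, 16, length.out = 6)
  y <- 300 - 12 * (x - 15)^2
  expect_warning(sel <- select_polynomial_order(x, y), "capped")
  expect_equal(sel$order, 2)
  expect_error(select_polynomial_order(x[1:3], y[1:3]), "4 points")
})

test_that("optimum extraction is analytic on known polynomials", {
  # 300 - (L - 15)^2 = 75 + 30 L - L^2
  opt <- extract_optimum(c(75, 30, -1), c(11, 16))
  expect_equal(opt$L_mao, 15)
  expect_equal(opt$F_mao, 300)
  expect_false(opt$boundary)

  # monotone increasing cubic: boundary optimum at the top of the range
  coefs <- c(0, 1, 0.1, 0.01)
  opt2 <- extract_optimum(coefs, c(11, 16))
  expect_equal(opt2$L_mao, 16)
  expect_equal(opt2$F_mao, poly_eval_for_tests(coefs, 16))
  expect_true(opt2$boundary)
})

test_that("optimum matches a dense-grid argmax on random quartics", {
  set.seed(99)
  worst <- 0
  for (i in 1:100) {
    coefs <- rnorm(5) * c(100, 50, 10, 2, 0.5)
    opt <- extract_optimum(coefs, c(11, 16))
    g <- seq(11, 16, by = 1e-4)
    L_grid <- g[which.max(poly_eval_for_tests(coefs, g))]
    worst <- max(worst, abs(opt$L_mao - L_grid))
  }
  expect_lt(worst, 1e-3)
})

test_that("active slack is the x-intercept below the optimum", {
  # 300 * (1 - ((L - 15)/4)^2): roots at 11 and 19
  coefs <- c(300 - 300 * 225 / 16, 300 * 30 / 16, -300 / 16)
  L_mas <- extract_active_slack(coefs, 15, c(11, 16))
  expect_equal(L_mas, 11, tolerance = 1e-6)

  # positive throughout the window: slack not bracketed
  expect_error(extract_active_slack(c(50, 0, -0.1), 15, c(14, 16)),
               "not bracketed")
})

test_that("full fit recovers a noiseless synthetic muscle", {
  gt <- gt_noiseless()
  s <- simulate_length_series(gt, seq(11, 16, by = 0.5), seed = 1)
  fit <- fit_series(s)
  expect_equal(fit$L_mao, 15, tolerance = 1e-2)
  expect_equal(fit$F_mao, 300, tolerance = 300 * 1e-3)
  expect_equal(fit$L_mas, 11, tolerance = 1e-2)
  expect_lt(fit$L_mas, fit$L_mao)
  # fitted active force vanishes at the slack length
  expect_lt(abs(poly_eval_for_tests(fit$coefficients, fit$L_mas)),
            1e-3 * fit$F_mao)
})

test_that("slack-ordering and zero-at-slack hold across noisy fits", {
  gt <- gt_study()
  for (seed in 1:20) {
    s <- simulate_length_series(gt, seq(11, 16, by = 0.5), seed = seed)
    fit <- fit_series(s)
    expect_lt(fit$L_mas, fit$L_mao)
    expect_lt(abs(poly_eval_for_tests(fit$coefficients, fit$L_mas)),
              1e-3 * abs(fit$F_mao))
  }
})

test_that("normalization reproduces tibia-relative ratios", {
  vals <- list(L_mao = 15.2, L_mas = 11.1, F_mao = 294)
  nrm <- normalize_length_force(vals, tibia_mm = 18.89, body_mass_g = 32.8)
  expect_equal(round(nrm$L_mao_over_Ltibia, 2), 0.80)
  expect_equal(round(nrm$L_mas_over_Ltibia, 2), 0.59)
  expect_equal(nrm$F_mao_over_BM_mN_per_g, 294 / 32.8)
  same <- normalize_length_force(list(L_mao = 7, L_mas = 3.5, F_mao = 1),
                                 tibia_mm = 7)
  expect_equal(same$L_mao_over_Ltibia, 1)
  expect_error(normalize_length_force(vals, tibia_mm = 0), "tibia_mm")
})

test_that("invalid length-force points are rejected", {
  expect_error(length_force_points(c(11, 11, 12), 1:3, 1:3), "distinct")
  expect_error(length_force_points(c(-1, 12), c(1, 2), c(0, 0)), "positive")
  expect_error(length_force_points(c(11, 12), c(10, 10), c(100, 0)),
               "passive")
})
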