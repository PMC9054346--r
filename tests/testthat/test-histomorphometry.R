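square_section <- function(pixel_size = 1) {
  lab <- matrix(0L, 20, 20)
  lab[6:15, 6:15] <- 1L   # 10x10 px square
  labeled_section(lab, pixel_size)
}

test_that("fiber areas and perimeters follow pixel geometry", {
  st <- suppressWarnings(fiber_csa_stats(square_section()))
  expect_equal(st$per_fiber$area_um2, 100)
  expect_equal(st$per_fiber$perimeter_um, 40)  # crack-length of a square
  expect_warning(fiber_csa_stats(square_section()), "fewer than 50")

  # areas scale as pixel_size^2, perimeters as pixel_size
  st2 <- suppressWarnings(fiber_csa_stats(square_section(pixel_size = 2)))
  expect_equal(st2$per_fiber$area_um2, 400)
  expect_equal(st2$per_fiber$perimeter_um, 80)

  expect_error(fiber_csa_stats(labeled_section(matrix(0L, 5, 5), 1)),
               "no fibers")
})

test_that("synthetic section areas equal the truth table exactly", {
  sp <- section_spec(n_fibers = 36, mean_fiber_diameter_um = 30,
                     endomysium_thickness_um = 3, pixel_size_um = 1)
  sec <- simulate_section(sp, seed = 4)
  st <- fiber_csa_stats(sec, warn_below = 0)
  expect_identical(st$per_fiber$area_um2, attr(sec, "truth")$area_um2)
})

test_that("fiber typing handles pure, hybrid and unclassified fibers", {
  inten <- rbind(
    c(200, 10, 15, 12),   # pure I
    c(15, 210, 190, 14),  # hybrid IIA/IIX
    c(10, 12, 14, 220),   # pure IIB
    c(10, 11, 12, 13)     # unclassified
  )
  colnames(inten) <- c("MHC-I", "MHC-IIA", "MHC-IIX", "MHC-IIB")
  res <- classify_fiber_types(inten, thresholds = rep(100, 4))
  expect_equal(res$type, c("I", "IIA/IIX", "IIB", "unclassified"))
  expect_equal(sum(res$proportions), 1, tolerance = 1e-12)
  expect_equal(res$n_classified, 3)
  expect_error(classify_fiber_types(inten, thresholds = rep(1e5, 4)),
               "no fiber")
})

test_that("planted fiber-type proportions are recovered with Otsu", {
  sim <- simulate_channel_intensities(200, c(I = 0.6, IIA = 0.4), seed = 21)
  res <- classify_fiber_types(sim$intensities)
  p_hat <- unname(res$proportions["I"])
  ci_half <- 1.96 * sqrt(0.6 * 0.4 / 200)
  expect_lt(abs(p_hat - 0.6), ci_half)
  expect_equal(res$n_classified, 200)
})

test_that("SDH activity follows the Beer-Lambert conversion", {
  expect_equal(sdh_activity(128, 128, incubation_s = 900)$activity, 0)
  a <- sdh_activity(25.5, 255, section_thickness_um = 10,
                    incubation_s = 900)
  expect_equal(a$absorbance, 1, tolerance = 1e-9)
  expect_equal(a$activity, 1 / 9000, tolerance = 1e-9)
  neg <- sdh_activity(200, 100, incubation_s = 900)
  expect_true(neg$negative)
  expect_error(sdh_activity(100, 100), "incubation_s")
})

test_that("per-fiber SDH matches an imposed transmittance field", {
  # forward model: choose per-fiber transmittances, recover activities
  trans <- c(0.8, 0.5, 0.2, 0.05)
  blank <- 255
  act <- vapply(trans, function(tr)
    sdh_activity(blank * tr, blank, 10, 600)$activity, numeric(1))
  expect_equal(act, -log10(trans) / 6000, tolerance = 1e-9)
})

test_that("endomysium thickness from area over perimeter", {
  sec <- square_section()
  sec$connective <- matrix(0L, 20, 20)
  expect_equal(endomysium_Le(sec)$L_e_um, 0)

  # one fiber (perimeter 40), 200 px^2 connective: L_e = 200/40 = 5
  sec$connective[1:10, 1:20] <- 0L
  sec$connective[16:20, 1:20] <- 1L
  le <- endomysium_Le(sec)
  expect_equal(le$L_e_um, (100 * 1) / 1 / 40)
  expect_equal(le$endomysium_area_fraction, 100 / 400)

  # unit scaling: doubling pixel size doubles L_e for identical masks
  sec2 <- sec; sec2$pixel_size_um <- 2
  expect_equal(endomysium_Le(sec2)$L_e_um, 2 * le$L_e_um)
})

test_that("measured L_e tracks the generator's endomysium thickness", {
  le_of <- function(th) {
    sp <- section_spec(n_fibers = 25, mean_fiber_diameter_um = 40,
                       endomysium_thickness_um = th, pixel_size_um = 1)
    endomysium_Le(simulate_section(sp, seed = 6))$L_e_um
  }
  le2 <- le_of(2); le4 <- le_of(4)
  expect_gt(le4, le2)                    # monotone in the true thickness
  expect_lt(abs(le2 - 1) / 1, 0.15)      # ~ half thickness
  expect_lt(abs(le4 - 2) / 2, 0.15)
  b <- endomysium_Le_batch(list(
    simulate_section(section_spec(25, 40, 3, 1), seed = 1),
    simulate_section(section_spec(25, 40, 3, 1), seed = 2)))
  expect_equal(b$L_e_um, mean(b$per_roi_um))
})

test_that("perimysium thickness via midline distance sampling", {
  ct <- matrix(0L, 200, 200)
  ct[, 96:111] <- 1L   # straight band, 16 px = 8 um at 0.5 um/px
  lab <- matrix(0L, 200, 200); lab[, 1:50] <- 1L
  sec <- labeled_section(lab, 0.5, connective = ct)

  path <- data.frame(x_um = c(5, 95), y_um = c(51.75, 51.75),
                     domain = "Lp1")
  pt <- perimysium_thickness(path, sec)
  expect_equal(pt$mean_um, 8, tolerance = 0.1)
  expect_equal(length(pt$thickness_um), 4)  # 90 um path, 25 um spacing
  expect_equal(pt$domain, "Lp1")

  short <- data.frame(x_um = c(5, 15), y_um = c(51.75, 51.75))
  ps <- perimysium_thickness(short, sec)
  expect_equal(length(ps$thickness_um), 1)  # single sample at path start

  outside <- data.frame(x_um = c(5, 95), y_um = c(10, 10))
  expect_error(perimysium_thickness(outside, sec), "outside")

  mixed <- data.frame(x_um = c(5, 95), y_um = c(51.75, 20))
  expect_warning(pm <- perimysium_thickness(mixed, sec), "dropped")
  expect_gt(pm$n_dropped, 0)
})

test_that("a linearly tapering band is measured along its midline", {
  # width grows 8 -> 24 px (4 -> 12 um) along x
  ct <- matrix(0L, 200, 200)
  for (i in 1:200) {
    w <- round(8 + (i - 1) / 199 * 16)
    ct[i, (100 - w %/% 2):(100 + w %/% 2)] <- 1L
  }
  lab <- matrix(0L, 200, 200); lab[, 1:30] <- 1L
  sec <- labeled_section(lab, 0.5, connective = ct)
  path <- data.frame(x_um = c(2, 98), y_um = c(50, 50))
  pt <- perimysium_thickness(path, sec)
  # analytic mean width over the sampled midline: (4 + 12)/2 * ~path coverage
  mid <- mean(c(4 + (seq(2, 98, by = 25) / 100) * 8))
  expect_equal(pt$mean_um, mid, tolerance = 0.15 * mid)
  expect_true(all(diff(pt$thickness_um) > 0))  # monotone taper
})

test_that("labeled_section validates its inputs", {
  expect_error(labeled_section(matrix(-1L, 2, 2), 1), "non-negative")
  expect_error(labeled_section(matrix(0L, 2, 2), 0), "pixel_size_um")
  expect_error(labeled_section(matrix(0L, 2, 2), 1,
                               connective = matrix(0L, 3, 3)), "dimensions")
  expect_error(labeled_section(matrix(0L, 2, 2), 1,
                               connective = matrix(2L, 2, 2)), "binary")
})
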