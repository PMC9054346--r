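#' Ground truth for a simulated muscle
#'
#' Bundles the true contractile parameters of a simulated muscle: the active
#' length-force curve (single-peaked, exactly zero at the active slack length
#' `L_slack` and exactly `F_opt` at the optimum length `L_opt`), the passive
#' exponential curve, tetanic rise kinetics and the fatigue decay. Every
#' simulator in the package draws its signal from one of these records, so
#' downstream estimators can be scored against known values.
#'
#' The active curve is a scaled, shifted power of a cosine,
#' \deqn{F_a(L) = F_{opt} \cos^p\!\left(\frac{\pi}{2}
#'   \frac{L - L_{opt}}{L_{opt} - L_{slack}}\right)}
#' clipped to zero outside the half-wave. It is deliberately *not* a
#' polynomial, so the polynomial fitting stage is exercised under model
#' mismatch. The default exponent `curve_shape = 1` gives a finite, nonzero
#' slope at the slack length, matching the classic sarcomere length-tension
#' curve whose ascending limb meets the length axis transversally.
#'
#' The passive curve is `exp(b0 + b1 * L) + offset` (the same family the
#' passive fitter uses by default, so zero-noise recovery is exact).
#'
#' @param F_opt active force at optimum length (mN).
#' @param L_opt optimum muscle length (mm).
#' @param L_slack active slack length (mm); must be below `L_opt`.
#' @param curve_shape exponent of the cosine active curve (dimensionless).
#' @param passive_b0,passive_b1,passive_offset passive-curve coefficients:
#'   passive force is `exp(passive_b0 + passive_b1 * L) + passive_offset` mN.
#' @param noise_sd standard deviation of iid Gaussian noise added to
#'   measured forces (mN). The study protocol gives no noise magnitude;
#'   the default 3 mN (~1% of the default `F_opt`) is a realistic
#'   transducer-level figure and is fully configurable.
#' @param rise_tau tetanic force rise time constant (ms).
#' @param fatigue_asymptote_frac fraction of initial force retained at the
#'   steady state of a repeated-contraction protocol, in [0, 1].
#' @param fatigue_rate per-contraction exponential decay constant of the
#'   fatigue run.
#'
#' @return An object of class `ground_truth` (a named list).
#' @examples
#' gt <- ground_truth(F_opt = 300, L_opt = 15, L_slack = 11, noise_sd = 0)
#' active_curve(gt, c(11, 15)) # 0 at slack, 300 at optimum
#' @export
ground_truth <- function(F_opt = 294, L_opt = 15.2, L_slack = 11.1,
                         curve_shape = 1,
                         passive_b0 = -12, passive_b1 = 0.9,
                         passive_offset = 1,
                         noise_sd = 3, rise_tau = 20,
                         fatigue_asymptote_frac = 0.84,
                         fatigue_rate = 0.05) {
  check_number(F_opt, "F_opt", lower = 0, allow_equal = FALSE)
  check_number(L_opt, "L_opt", lower = 0, allow_equal = FALSE)
  check_number(L_slack, "L_slack", lower = 0, allow_equal = FALSE)
  if (L_slack >= L_opt)
    stop_myomech("L_slack (%g) must be strictly below L_opt (%g)",
                 L_slack, L_opt)
  check_number(curve_shape, "curve_shape", lower = 0, allow_equal = FALSE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(rise_tau, "rise_tau", lower = 0, allow_equal = FALSE)
  check_number(fatigue_asymptote_frac, "fatigue_asymptote_frac", 0, 1)
  check_number(fatigue_rate, "fatigue_rate", lower = 0)
  structure(list(
    F_opt = F_opt, L_opt = L_opt, L_slack = L_slack,
    curve_shape = curve_shape,
    passive_b0 = passive_b0, passive_b1 = passive_b1,
    passive_offset = passive_offset,
    noise_sd = noise_sd, rise_tau = rise_tau,
    fatigue_asymptote_frac = fatigue_asymptote_frac,
    fatigue_rate = fatigue_rate
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Simulated muscle ground truth\n")
  cat(sprintf("  F_opt %g mN at L_opt %g mm; active slack %g mm (shape %g)\n",
              x$F_opt, x$L_opt, x$L_slack, x$curve_shape))
  cat(sprintf("  passive exp(%g + %g L) + %g mN; noise sd %g mN\n",
              x$passive_b0, x$passive_b1, x$passive_offset, x$noise_sd))
  cat(sprintf("  rise tau %g ms; fatigue asymptote %g, rate %g\n",
              x$rise_tau, x$fatigue_asymptote_frac, x$fatigue_rate))
  invisible(x)
}

#' Analytic active and passive curves of a simulated muscle
#'
#' `active_curve()` evaluates the noise-free active length-force curve of a
#' [ground_truth()] record; `passive_curve()` evaluates the passive curve.
#'
#' @param gt a [ground_truth()] object.
#' @param lengths muscle lengths (mm).
#' @return Forces in mN, one per length.
#' @export
active_curve <- function(gt, lengths) {
  stopifnot(inherits(gt, "ground_truth"))
  z <- (lengths - gt$L_opt) / (gt$L_opt - gt$L_slack)
  base <- cos(pmin(abs(z), 1) * pi / 2)
  gt$F_opt * pmax(base, 0)^gt$curve_shape
}

#' @rdname active_curve
#' @export
passive_curve <- function(gt, lengths) {
  stopifnot(inherits(gt, "ground_truth"))
  exp(gt$passive_b0 + gt$passive_b1 * lengths) + gt$passive_offset
}

#' Simulate a tetanic length-force series
#'
#' Emulates the isometric length-series protocol: tetanic contractions evoked
#' at increasing muscle lengths, each yielding one total-force and one
#' passive-force reading. Total force is `active(L) + passive(L)` plus
#' Gaussian noise; the reported passive force carries its own independent
#' noise draw, as the two are measured in different parts of the record.
#'
#' @param gt a [ground_truth()] record.
#' @param lengths strictly increasing muscle lengths (mm), at least 6 values
#'   (downstream polynomial fits need order + 2 points).
#' @param seed integer RNG seed; the series is bit-reproducible given
#'   `(gt, lengths, seed)`.
#' @param heteroscedastic if `TRUE`, noise sd scales with the square root of
#'   the noise-free force (Poisson-like); default off.
#' @return A `length_series` data frame with columns `muscle_length_mm`,
#'   `total_force_mN`, `passive_force_mN`, and the generating truth in
#'   attribute `"ground_truth"`.
#' @examples
#' gt <- ground_truth(F_opt = 300, L_opt = 15, L_slack = 11, noise_sd = 0)
#' simulate_length_series(gt, seq(11, 16, by = 0.5), seed = 1)
#' @export
simulate_length_series <- function(gt, lengths, seed = 1L,
                                   heteroscedastic = FALSE) {
  stopifnot(inherits(gt, "ground_truth"))
  if (length(lengths) < 6L)
    stop_myomech("need at least 6 lengths, got %d", length(lengths))
  if (any(diff(lengths) <= 0))
    stop_myomech("lengths must be strictly increasing")
  set.seed(as.integer(seed))
  act <- active_curve(gt, lengths)
  pas <- passive_curve(gt, lengths)
  sd_tot <- if (heteroscedastic) gt$noise_sd * sqrt(pmax(act + pas, 0) /
                                                    gt$F_opt) else gt$noise_sd
  sd_pas <- if (heteroscedastic) gt$noise_sd * sqrt(pmax(pas, 0) /
                                                    gt$F_opt) else gt$noise_sd
  out <- data.frame(
    muscle_length_mm = lengths,
    total_force_mN = act + pas + stats::rnorm(length(lengths), 0, sd_tot),
    passive_force_mN = pas + stats::rnorm(length(lengths), 0, sd_pas)
  )
  attr(out, "ground_truth") <- gt
  class(out) <- c("length_series", "data.frame")
  out
}

#' Simulate a high-frequency tetanus force trace
#'
#' Produces a sampled force-time record of a fused tetanus: zero baseline
#' for `baseline_ms`, then a saturating exponential rise
#' `F_opt * (1 - exp(-t / rise_tau))`, plus Gaussian noise. The analytic
#' maximal slope is `F_opt / rise_tau` at stimulation onset, which is the
#' oracle for the rate-of-force-development estimator.
#'
#' @param gt a [ground_truth()] record; `rise_tau` must be positive.
#' @param duration_ms stimulated duration after onset (ms); a duration of at
#'   least `5 * rise_tau` is recommended so the plateau is reached.
#' @param sampling_hz sampling rate (Hz), at least 1000.
#' @param baseline_ms pre-stimulus baseline length (ms).
#' @param seed integer RNG seed.
#' @return A [force_trace()] with a `stim_events` attribute holding the
#'   single `train` event.
#' @export
simulate_tetanus_trace <- function(gt, duration_ms = 150, sampling_hz = 10000,
                                   baseline_ms = 20, seed = 1L) {
  stopifnot(inherits(gt, "ground_truth"))
  check_number(duration_ms, "duration_ms", lower = 0, allow_equal = FALSE)
  if (sampling_hz < 1000)
    stop_myomech("sampling_hz must be >= 1000 for rate-of-rise analysis")
  set.seed(as.integer(seed))
  dt <- 1000 / sampling_hz
  time <- seq(0, baseline_ms + duration_ms, by = dt)
  rel <- time - baseline_ms
  clean <- ifelse(rel <= 0, 0, gt$F_opt * (1 - exp(-rel / gt$rise_tau)))
  tr <- force_trace(time, clean + stats::rnorm(length(time), 0, gt$noise_sd))
  attr(tr, "stim_events") <- stim_events(
    kind = "train", onset_ms = baseline_ms,
    offset_ms = baseline_ms + duration_ms, frequency_hz = 400
  )
  tr
}

#' Simulate a fatigue run of contraction peak forces
#'
#' Peak force of the k-th contraction (k = 0, 1, ...) of a once-per-second
#' stimulation protocol:
#' `F_opt * (a + (1 - a) * exp(-r * k)) + noise`, with `a` the retained
#' asymptotic fraction and `r` the per-contraction decay rate.
#'
#' @param gt a [ground_truth()] record.
#' @param n_contractions number of contractions, at least 2 (default 120,
#'   i.e. a 2-minute 1-Hz protocol).
#' @param seed integer RNG seed.
#' @return Numeric vector of peak forces (mN) with the truth attached as
#'   attribute `"ground_truth"`.
#' @export
simulate_fatigue_series <- function(gt, n_contractions = 120, seed = 1L) {
  stopifnot(inherits(gt, "ground_truth"))
  if (n_contractions < 2) stop_myomech("need at least 2 contractions")
  set.seed(as.integer(seed))
  k <- seq_len(n_contractions) - 1
  a <- gt$fatigue_asymptote_frac
  peaks <- gt$F_opt * (a + (1 - a) * exp(-gt$fatigue_rate * k)) +
    stats::rnorm(n_contractions, 0, gt$noise_sd)
  attr(peaks, "ground_truth") <- gt
  peaks
}

#' Specification of a simulated muscle-fiber cohort
#'
#' Geometry and composition of a cohort of single fibers used to exercise
#' the serial-sarcomere and myonuclear arithmetic: fiber lengths, sarcomere
#' lengths and a linear myonuclear density, together with the two geometric
#' constants of section-corrected nucleus counting (nucleus length, default
#' 12 um, and cryosection thickness, default 10 um).
#'
#' @param n_fibers number of fibers.
#' @param fiber_length_mean,fiber_length_sd fiber length distribution (mm).
#' @param sarcomere_length_mean,sarcomere_length_sd sarcomere length
#'   distribution (um).
#' @param nuclei_per_mm linear myonuclear density (nuclei per mm fiber).
#' @param nucleus_length_um assumed myonucleus length (um).
#' @param section_thickness_um cryosection thickness (um).
#' @return A `fiber_cohort_spec` list.
#' @export
fiber_cohort_spec <- function(n_fibers = 50, fiber_length_mean = 4.4,
                              fiber_length_sd = 0.3,
                              sarcomere_length_mean = 2.2,
                              sarcomere_length_sd = 0.1,
                              nuclei_per_mm = 100,
                              nucleus_length_um = 12,
                              section_thickness_um = 10) {
  check_number(n_fibers, "n_fibers", lower = 1)
  check_number(fiber_length_mean, "fiber_length_mean", lower = 0,
               allow_equal = FALSE)
  check_number(fiber_length_sd, "fiber_length_sd", lower = 0)
  check_number(sarcomere_length_mean, "sarcomere_length_mean", lower = 0,
               allow_equal = FALSE)
  check_number(sarcomere_length_sd, "sarcomere_length_sd", lower = 0)
  check_number(nuclei_per_mm, "nuclei_per_mm", lower = 0)
  check_number(nucleus_length_um, "nucleus_length_um", lower = 0,
               allow_equal = FALSE)
  check_number(section_thickness_um, "section_thickness_um", lower = 0,
               allow_equal = FALSE)
  structure(list(
    n_fibers = as.integer(n_fibers),
    fiber_length_mean = fiber_length_mean,
    fiber_length_sd = fiber_length_sd,
    sarcomere_length_mean = sarcomere_length_mean,
    sarcomere_length_sd = sarcomere_length_sd,
    nuclei_per_mm = nuclei_per_mm,
    nucleus_length_um = nucleus_length_um,
    section_thickness_um = section_thickness_um
  ), class = "fiber_cohort_spec")
}

#' Monte-Carlo myonuclear profile counts in random cryosections
#'
#' Places `n_nuclei` nucleus centres uniformly along a fiber and, for each of
#' `n_slabs` independent random section positions, counts the nuclei whose
#' 1-D extent (length `nucleus_um`) intersects the slab of thickness
#' `section_um`. With the slab interior to the fiber, the hit probability
#' per nucleus is `(nucleus_um + section_um) / fiber_length_um`, so the
#' expected count is `n_nuclei * (L_m + D_s) / L_f` - the quantity the
#' section-correction formula ([myonuclei_per_fiber()]) inverts.
#'
#' @param n_nuclei true number of myonuclei in the fiber.
#' @param fiber_length_um fiber length (um).
#' @param nucleus_um nucleus length (um).
#' @param section_um section thickness (um).
#' @param n_slabs number of independent random sections.
#' @param seed integer RNG seed.
#' @return Integer vector of length `n_slabs` of counted profiles.
#' @export
sample_nucleus_profiles <- function(n_nuclei, fiber_length_um,
                                    nucleus_um = 12, section_um = 10,
                                    n_slabs = 1, seed = 1L) {
  if (nucleus_um + section_um > fiber_length_um)
    stop_myomech(paste("nucleus length + section thickness (%g um) exceeds",
                       "fiber length (%g um)"),
                 nucleus_um + section_um, fiber_length_um)
  set.seed(as.integer(seed))
  if (n_nuclei == 0) return(integer(n_slabs))
  centres <- stats::runif(n_nuclei, 0, fiber_length_um)
  half <- (nucleus_um + section_um) / 2
  # slab centre kept interior so the intersection window never clips
  slab <- stats::runif(n_slabs, half, fiber_length_um - half)
  vapply(slab, function(s) sum(abs(centres - s) < half), integer(1))
}

#' Simulate a fiber cohort with known nuclear content
#'
#' Draws per-fiber lengths and sarcomere lengths from the cohort spec,
#' assigns each fiber a true myonucleus count from its length and the linear
#' density, and "sections" each fiber at `n_slabs` random positions,
#' recording the mean counted profiles per section as a microscopist
#' averaging several cross-sections would.
#'
#' @param spec a [fiber_cohort_spec()].
#' @param seed integer RNG seed.
#' @param n_slabs sections counted per fiber (default 1); the recorded
#'   `counted_profiles` is their mean.
#' @return Data frame with one row per fiber: `fiber_id`, `region`,
#'   `fiber_length_mm`, `mean_sl_um`, `n_sarcomeres` (true serial sarcomere
#'   number), `true_nuclei`, `counted_profiles`. The spec is attached as
#'   attribute `"spec"`.
#' @export
simulate_fiber_cohort <- function(spec, seed = 1L, n_slabs = 1L) {
  stopifnot(inherits(spec, "fiber_cohort_spec"))
  set.seed(as.integer(seed))
  n <- spec$n_fibers
  lf <- pmax(stats::rnorm(n, spec$fiber_length_mean, spec$fiber_length_sd),
             0.2)
  sl <- pmax(stats::rnorm(n, spec$sarcomere_length_mean,
                          spec$sarcomere_length_sd), 0.5)
  true_nuclei <- round(spec$nuclei_per_mm * lf)
  counted <- vapply(seq_len(n), function(i) {
    if (true_nuclei[i] == 0) return(0)
    mean(sample_nucleus_profiles(true_nuclei[i], lf[i] * 1000,
                                 spec$nucleus_length_um,
                                 spec$section_thickness_um,
                                 n_slabs = n_slabs,
                                 seed = (as.integer(seed) %% 1000000L) *
                                   1000L + i))
  }, numeric(1))
  out <- data.frame(
    fiber_id = seq_len(n),
    region = rep(c("proximal", "distal"), length.out = n),
    fiber_length_mm = lf,
    mean_sl_um = sl,
    n_sarcomeres = lf * 1000 / sl,
    true_nuclei = true_nuclei,
    counted_profiles = counted
  )
  attr(out, "spec") <- spec
  out
}

#' Specification of a synthetic muscle cross-section
#'
#' Geometry for a Voronoi-tessellated synthetic cross-section: roughly
#' `n_fibers` polygonal fibers of the requested mean diameter separated by
#' an endomysial connective-tissue network of known thickness.
#'
#' @param n_fibers target number of fibers.
#' @param mean_fiber_diameter_um mean fiber diameter (um).
#' @param endomysium_thickness_um thickness of the connective-tissue seam
#'   between adjacent fibers (um); must be below the fiber diameter.
#' @param pixel_size_um pixel size (um/px).
#' @param image_size_px image side length (px); the image must be large
#'   enough to hold `n_fibers` at the requested diameter.
#' @return A `section_spec` list.
#' @export
section_spec <- function(n_fibers = 100, mean_fiber_diameter_um = 40,
                         endomysium_thickness_um = 3, pixel_size_um = 0.5,
                         image_size_px = NULL) {
  check_number(n_fibers, "n_fibers", lower = 4)
  check_number(mean_fiber_diameter_um, "mean_fiber_diameter_um", lower = 0,
               allow_equal = FALSE)
  check_number(endomysium_thickness_um, "endomysium_thickness_um", lower = 0)
  if (endomysium_thickness_um >= mean_fiber_diameter_um)
    stop_myomech("endomysium thickness must be below the fiber diameter")
  check_number(pixel_size_um, "pixel_size_um", lower = 0, allow_equal = FALSE)
  side_um <- ceiling(sqrt(n_fibers)) * mean_fiber_diameter_um
  if (is.null(image_size_px))
    image_size_px <- ceiling(side_um / pixel_size_um)
  if (image_size_px * pixel_size_um <
      sqrt(n_fibers) * mean_fiber_diameter_um * 0.9)
    stop_myomech("image of %d px at %g um/px too small for %d fibers of %g um",
                 image_size_px, pixel_size_um, n_fibers,
                 mean_fiber_diameter_um)
  structure(list(
    n_fibers = as.integer(n_fibers),
    mean_fiber_diameter_um = mean_fiber_diameter_um,
    endomysium_thickness_um = endomysium_thickness_um,
    pixel_size_um = pixel_size_um,
    image_size_px = as.integer(image_size_px)
  ), class = "section_spec")
}

#' Simulate a labeled cross-section with a connective-tissue mask
#'
#' Builds a Voronoi tessellation from jittered-grid seed points, then carves
#' an endomysial seam of the requested thickness along every inter-fiber
#' boundary: a pixel belongs to connective tissue when its distance to the
#' Voronoi boundary (half the difference between the distances to the two
#' nearest seeds) is below half the endomysium thickness. Fibers touching
#' the image border are kept, so the truth table is computed from the same
#' masks the measurement operations see.
#'
#' @param spec a [section_spec()].
#' @param seed integer RNG seed.
#' @return A `labeled_section` (see [labeled_section()]) whose
#'   `connective` slot is the binary endomysium mask and whose
#'   `truth` slot tabulates per-fiber area (um^2) and perimeter (um).
#' @export
simulate_section <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "section_spec"))
  set.seed(as.integer(seed))
  n_side <- ceiling(sqrt(spec$n_fibers))
  px <- spec$image_size_px
  sz_um <- px * spec$pixel_size_um
  pitch <- sz_um / n_side
  centres <- expand.grid(
    x = (seq_len(n_side) - 0.5) * pitch,
    y = (seq_len(n_side) - 0.5) * pitch
  )
  centres <- centres[seq_len(min(nrow(centres), spec$n_fibers)), ]
  jit <- pitch * 0.25
  centres$x <- centres$x + stats::runif(nrow(centres), -jit, jit)
  centres$y <- centres$y + stats::runif(nrow(centres), -jit, jit)

  xs <- (seq_len(px) - 0.5) * spec$pixel_size_um
  # distance from every pixel to every seed, row-blocked to bound memory
  lab <- matrix(0L, px, px)
  gap <- matrix(FALSE, px, px)
  half_t <- spec$endomysium_thickness_um / 2
  dy2 <- outer(xs, centres$y, function(a, b) (a - b)^2)  # px x n_seeds
  for (i in seq_len(px)) {
    dd2 <- dy2 + matrix((xs[i] - centres$x)^2, px, nrow(centres),
                        byrow = TRUE)
    ord1 <- max.col(-dd2)
    d1sq <- dd2[cbind(seq_len(px), ord1)]
    dd2[cbind(seq_len(px), ord1)] <- Inf
    ord2 <- max.col(-dd2)
    d2sq <- dd2[cbind(seq_len(px), ord2)]
    lab[i, ] <- ord1
    if (half_t > 0) {
      # exact perpendicular distance to the bisector of the two nearest
      # seeds: (d2^2 - d1^2) / (2 |s2 - s1|), so the seam has true width
      seed_gap <- sqrt((centres$x[ord1] - centres$x[ord2])^2 +
                       (centres$y[ord1] - centres$y[ord2])^2)
      gap[i, ] <- (d2sq - d1sq) / (2 * seed_gap) < half_t
    }
  }
  lab[gap] <- 0L
  section <- labeled_section(lab, spec$pixel_size_um,
                             connective = matrix(as.integer(gap), px, px))
  stats <- fiber_csa_stats(section, warn_below = 0)
  attr(section, "truth") <- stats$per_fiber
  attr(section, "spec") <- spec
  section
}

#' Simulate per-fiber immunofluorescence channel intensities
#'
#' Plants a known fiber-type composition: each fiber is assigned a type by
#' the given proportions; its positive channel(s) get intensities well above
#' threshold and negative channels stay near background. Used to validate
#' threshold-based fiber-type classification.
#'
#' @param n_fibers number of fibers.
#' @param proportions named numeric vector of planted type proportions;
#'   names from `c("I", "IIA", "IIX", "IIB")`, or hybrid names such as
#'   `"IIA/IIX"` (both channels positive). Must sum to 1.
#' @param positive_mean,negative_mean mean intensity of positive and
#'   negative channels (arbitrary units).
#' @param intensity_sd Gaussian spread of intensities.
#' @param seed integer RNG seed.
#' @return List with `intensities` (n x 4 matrix, columns MHC-I, MHC-IIA,
#'   MHC-IIX, MHC-IIB) and `true_type` (character vector).
#' @export
simulate_channel_intensities <- function(n_fibers = 200,
                                         proportions = c(I = 0.6, IIA = 0.4),
                                         positive_mean = 200,
                                         negative_mean = 20,
                                         intensity_sd = 15, seed = 1L) {
  if (abs(sum(proportions) - 1) > 1e-8)
    stop_myomech("proportions must sum to 1")
  set.seed(as.integer(seed))
  channels <- c("I", "IIA", "IIX", "IIB")
  types <- sample(names(proportions), n_fibers, replace = TRUE,
                  prob = proportions)
  inten <- matrix(stats::rnorm(n_fibers * 4, negative_mean, intensity_sd),
                  n_fibers, 4, dimnames = list(NULL, paste0("MHC-", channels)))
  for (i in seq_len(n_fibers)) {
    pos <- strsplit(types[i], "/", fixed = TRUE)[[1]]
    idx <- match(pos, channels)
    inten[i, idx] <- stats::rnorm(length(idx), positive_mean, intensity_sd)
  }
  inten[inten < 0] <- 0
  list(intensities = inten, true_type = types)
}
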