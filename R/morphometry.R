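#' Muscle and fiber morphometry
#'
#' Closed-form morphometric derivations from specimen and single-fiber
#' measurements: serial sarcomere number, optimum fiber length, muscle
#' volume from mass and density, physiological cross-sectional area (PCSA),
#' tendon length, section-corrected myonuclear number and the myonuclear
#' domain. All quantities carry explicit units in their argument names and
#' the constants (optimum sarcomere length 2.2 um, muscle density
#' 1.0597 g/cm^3, nucleus length 12 um, section thickness 10 um) are named
#' defaults, not buried literals.
#'
#' @name morphometry
NULL

# guard against um/mm confusion: physiological sarcomere lengths are a few um
check_sarcomere_um <- function(x) {
  if (any(x <= 0)) stop_myomech("sarcomere length must be positive")
  if (any(x < 0.5 | x > 10))
    stop_myomech(paste("mean sarcomere length %g um outside the physiological",
                       "0.5-10 um band; check units (um expected)"),
                 x[which(x < 0.5 | x > 10)[1]])
  invisible(x)
}

#' Serial sarcomere number
#'
#' Number of sarcomeres arranged in series along a fiber: measured fiber
#' length divided by the fiber's mean sarcomere length.
#'
#' @param fiber_length_mm fiber length (mm).
#' @param mean_sarcomere_um mean sarcomere length (um). Values outside the
#'   physiological 0.5-10 um band are rejected so a um/mm mix-up cannot
#'   pass silently.
#' @return Serial sarcomere number (unrounded; round at report time).
#' @examples
#' serial_sarcomere_number(4.4, 2.2) # 2000
#' @export
serial_sarcomere_number <- function(fiber_length_mm, mean_sarcomere_um) {
  if (any(fiber_length_mm <= 0))
    stop_myomech("fiber length must be positive")
  check_sarcomere_um(mean_sarcomere_um)
  fiber_length_mm * 1000 / mean_sarcomere_um
}

#' Optimum fiber length
#'
#' Serial sarcomere number times the optimum sarcomere length (2.2 um, the
#' sarcomere length at the plateau of the length-tension curve).
#'
#' @param n_sarcomeres serial sarcomere number (>= 0).
#' @param optimum_sarcomere_um optimum sarcomere length (um).
#' @return Optimum fiber length (mm).
#' @examples
#' optimum_fiber_length(2000) # 4.4
#' @export
optimum_fiber_length <- function(n_sarcomeres, optimum_sarcomere_um = 2.2) {
  if (any(n_sarcomeres < 0)) stop_myomech("sarcomere number must be >= 0")
  check_sarcomere_um(optimum_sarcomere_um)
  n_sarcomeres * optimum_sarcomere_um / 1000
}

#' Muscle volume from mass
#'
#' Muscle mass divided by muscle tissue density (1.0597 g/cm^3).
#'
#' @param muscle_mass_mg muscle mass (mg).
#' @param density_g_per_cm3 muscle density (g/cm^3).
#' @return Muscle volume (mm^3).
#' @examples
#' muscle_volume(1059.7) # 1000
#' @export
muscle_volume <- function(muscle_mass_mg, density_g_per_cm3 = 1.0597) {
  if (any(muscle_mass_mg <= 0)) stop_myomech("muscle mass must be positive")
  check_number(density_g_per_cm3, "density_g_per_cm3", lower = 0,
               allow_equal = FALSE)
  # mg / (g/cm^3) = mm^3 (1 g/cm^3 == 1 mg/mm^3)
  muscle_mass_mg / density_g_per_cm3
}

#' Physiological cross-sectional area
#'
#' Muscle volume divided by fiber length. By convention the optimum fiber
#' length from [optimum_fiber_length()] is used as the denominator; the raw
#' measured mean fiber length may be supplied instead.
#'
#' @param volume_mm3 muscle volume (mm^3).
#' @param fiber_length_mm (optimum) fiber length (mm).
#' @return PCSA (mm^2). Satisfies `pcsa * fiber_length == volume` exactly.
#' @examples
#' pcsa(10, 4.4)
#' @export
pcsa <- function(volume_mm3, fiber_length_mm) {
  if (any(volume_mm3 <= 0)) stop_myomech("volume must be positive")
  if (any(fiber_length_mm <= 0))
    stop_myomech("fiber length must be positive")
  volume_mm3 / fiber_length_mm
}

#' Tendon length at optimum length
#'
#' Muscle-tendon-complex length minus muscle belly length, both measured at
#' the optimum length; optionally normalized by tibia length.
#'
#' @param mtc_opt_mm muscle-tendon complex length at optimum (mm).
#' @param belly_opt_mm muscle belly length at optimum (mm), not above
#'   `mtc_opt_mm`.
#' @param tibia_mm optional tibia length (mm) for normalization.
#' @return Tendon length (mm), or a list with `tendon_mm` and
#'   `tendon_over_Ltibia` when `tibia_mm` is given.
#' @examples
#' tendon_length(20, 12) # 8
#' @export
tendon_length <- function(mtc_opt_mm, belly_opt_mm, tibia_mm = NULL) {
  if (any(mtc_opt_mm < belly_opt_mm))
    stop_myomech("muscle-tendon complex length below belly length")
  len <- mtc_opt_mm - belly_opt_mm
  if (is.null(tibia_mm)) return(len)
  check_number(tibia_mm, "tibia_mm", lower = 0, allow_equal = FALSE)
  list(tendon_mm = len, tendon_over_Ltibia = len / tibia_mm)
}

#' Myonuclei per fiber, corrected for section sampling
#'
#' A cryosection of thickness D_s "sees" a nucleus of length L_m whenever
#' their 1-D extents overlap, i.e. with probability (L_m + D_s) / L_f per
#' nucleus of a fiber of length L_f. Inverting this sampling gives the true
#' number of myonuclei per fiber from the mean counted profiles per
#' cross-section:
#' \deqn{M_{n,f} = N_{n,s} \frac{L_f}{L_m + D_s}.}
#'
#' @param counted_profiles mean counted myonuclear profiles per fiber
#'   cross-section (N_n,s).
#' @param fiber_length_um fiber length L_f (um). Must be much larger than
#'   `nucleus_um + section_um` for the correction to be meaningful.
#' @param nucleus_um assumed myonucleus length L_m (um), default 12.
#' @param section_um section thickness D_s (um), default 10.
#' @return Myonuclei per fiber.
#' @examples
#' myonuclei_per_fiber(2.2, 4400) # 440
#' @export
myonuclei_per_fiber <- function(counted_profiles, fiber_length_um,
                                nucleus_um = 12, section_um = 10) {
  if (any(counted_profiles < 0)) stop_myomech("counts must be >= 0")
  if (nucleus_um + section_um <= 0)
    stop_myomech("nucleus length + section thickness must be positive")
  if (any(fiber_length_um <= nucleus_um + section_um))
    stop_myomech(paste("fiber length (%g um) must exceed nucleus length +",
                       "section thickness (%g um); check units (um expected)"),
                 min(fiber_length_um), nucleus_um + section_um)
  counted_profiles * fiber_length_um / (nucleus_um + section_um)
}

#' Myonuclear domain
#'
#' Fiber cross-sectional area divided by the number of myonuclei per 1 mm
#' of fiber length. Note the unit oddity of this conventional definition:
#' an area divided by a linear density, i.e. um^2 per (nuclei/mm); it is
#' implemented as defined.
#'
#' @param fiber_csa_um2 fiber cross-sectional area (um^2).
#' @param nuclei_per_mm myonuclei per mm of fiber length, positive.
#' @return Myonuclear domain, um^2 / (nuclei/mm).
#' @examples
#' myonuclear_domain(1500, 30) # 50
#' @export
myonuclear_domain <- function(fiber_csa_um2, nuclei_per_mm) {
  if (any(fiber_csa_um2 < 0)) stop_myomech("fiber CSA must be >= 0")
  if (any(nuclei_per_mm <= 0))
    stop_myomech("nuclear density must be positive")
  fiber_csa_um2 / nuclei_per_mm
}

#' Morphometry summary for one specimen
#'
#' Composes the closed-form morphometry chain for one muscle: per-region
#' mean serial sarcomere number, optimum fiber length, volume, PCSA and
#' tendon length.
#'
#' @param specimen named list or one-row data frame with `muscle_mass_mg`,
#'   `tibia_mm`, and optionally `mtc_opt_mm`, `belly_opt_mm`.
#' @param fibers data frame with `fiber_length_mm` and either
#'   `mean_sl_um` or `n_sarcomeres`, plus optionally `region`.
#' @param pooling `"region_mean"` (mean of per-region means, default) or
#'   `"grand_mean"` over all fibers.
#' @param optimum_sarcomere_um,density_g_per_cm3 constants, see
#'   [optimum_fiber_length()] and [muscle_volume()].
#' @return List with `ssn` (per-region means), `ssn_pooled`, `Lfo_mm`,
#'   `volume_mm3`, `PCSA_mm2` and, when lengths are available, `tendon_mm`
#'   and `tendon_over_Ltibia`.
#' @export
morphometry_summary <- function(specimen, fibers,
                                pooling = c("region_mean", "grand_mean"),
                                optimum_sarcomere_um = 2.2,
                                density_g_per_cm3 = 1.0597) {
  pooling <- match.arg(pooling)
  specimen <- as.list(specimen)
  require_columns(fibers, "fiber_length_mm", "fibers table")
  if (!"n_sarcomeres" %in% names(fibers)) {
    require_columns(fibers, "mean_sl_um", "fibers table")
    fibers$n_sarcomeres <- serial_sarcomere_number(fibers$fiber_length_mm,
                                                   fibers$mean_sl_um)
  }
  region <- if ("region" %in% names(fibers)) fibers$region
            else rep("all", nrow(fibers))
  ssn <- tapply(fibers$n_sarcomeres, region, mean)
  ssn_pooled <- switch(pooling,
                       region_mean = mean(ssn),
                       grand_mean = mean(fibers$n_sarcomeres))
  Lfo <- optimum_fiber_length(ssn_pooled, optimum_sarcomere_um)
  vol <- muscle_volume(specimen$muscle_mass_mg, density_g_per_cm3)
  out <- list(ssn = ssn, ssn_pooled = ssn_pooled, Lfo_mm = Lfo,
              volume_mm3 = vol, PCSA_mm2 = pcsa(vol, Lfo))
  if (!is.null(specimen$mtc_opt_mm) && !is.null(specimen$belly_opt_mm) &&
      !is.na(specimen$mtc_opt_mm) && !is.na(specimen$belly_opt_mm)) {
    td <- tendon_length(specimen$mtc_opt_mm, specimen$belly_opt_mm,
                        tibia_mm = specimen$tibia_mm)
    out$tendon_mm <- td$tendon_mm
    out$tendon_over_Ltibia <- td$tendon_over_Ltibia
  }
  out
}
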