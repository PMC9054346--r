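#' Study configuration
#'
#' Assembles and validates the configuration of an end-to-end run: input
#' paths per stage, the morphometric constants, and the analysis flags whose
#' defaults encode the package's documented conventions. Unknown keys are
#' rejected so a typo cannot silently disable a stage.
#'
#' @param lf_manifest path to a length-series manifest CSV (optional).
#' @param tibia_mm,body_mass_g tibia length and body mass for
#'   normalization (optional).
#' @param mrfd_trace,mrfd_events paths to a high-frequency train trace and
#'   its events CSV (optional; events may be embedded via attribute when
#'   simulating).
#' @param ffreq_csv path to a per-frequency CSV with `frequency_hz`,
#'   `total_force_mN`, `passive_force_mN` (optional).
#' @param fatigue_peaks_csv path to a peaks CSV with `contraction_idx`,
#'   `peak_force_mN` (optional).
#' @param specimens_csv,fibers_csv,nuclei_csv morphometry inputs
#'   (optional).
#' @param qpcr_csv qPCR Ct table (optional).
#' @param constants named list of constants; defaults
#'   `optimum_sarcomere_um = 2.2`, `density_g_per_cm3 = 1.0597`,
#'   `nucleus_um = 12`, `section_um = 10`, `alpha = 0.05`.
#' @param flags named list of analysis flags; defaults
#'   `passive_form = "exp-linear-plus-offset"`, `subtract = "measured"`,
#'   `f_end_rule = "last"`, `dct_orientation = "target_minus_reference"`,
#'   `ffreq_mode = "active"`.
#' @param seed integer seed recorded in provenance.
#' @param out_dir output directory (created if missing).
#' @return A `study_config` list.
#' @export
study_config <- function(lf_manifest = NULL, tibia_mm = NULL,
                         body_mass_g = NULL,
                         mrfd_trace = NULL, mrfd_events = NULL,
                         ffreq_csv = NULL, fatigue_peaks_csv = NULL,
                         specimens_csv = NULL, fibers_csv = NULL,
                         nuclei_csv = NULL, qpcr_csv = NULL,
                         constants = list(), flags = list(),
                         seed = 1L, out_dir = tempfile("myomech_run_")) {
  def_const <- list(optimum_sarcomere_um = 2.2, density_g_per_cm3 = 1.0597,
                    nucleus_um = 12, section_um = 10, alpha = 0.05)
  def_flags <- list(passive_form = "exp-linear-plus-offset",
                    subtract = "measured", f_end_rule = "last",
                    dct_orientation = "target_minus_reference",
                    ffreq_mode = "active")
  unknown <- setdiff(names(constants), names(def_const))
  if (length(unknown))
    stop_myomech("unknown constants: %s", paste(unknown, collapse = ", "))
  unknown <- setdiff(names(flags), names(def_flags))
  if (length(unknown))
    stop_myomech("unknown flags: %s", paste(unknown, collapse = ", "))
  structure(list(
    lf_manifest = lf_manifest, tibia_mm = tibia_mm,
    body_mass_g = body_mass_g,
    mrfd_trace = mrfd_trace, mrfd_events = mrfd_events,
    ffreq_csv = ffreq_csv, fatigue_peaks_csv = fatigue_peaks_csv,
    specimens_csv = specimens_csv, fibers_csv = fibers_csv,
    nuclei_csv = nuclei_csv, qpcr_csv = qpcr_csv,
    constants = utils::modifyList(def_const, constants),
    flags = utils::modifyList(def_flags, flags),
    seed = as.integer(seed), out_dir = out_dir
  ), class = "study_config")
}

run_stage <- function(name, bundle, expr) {
  res <- tryCatch(expr, error = function(e) {
    bundle$errors[[name]] <<- conditionMessage(e)
    message(sprintf("[myomech] stage '%s' failed: %s", name,
                    conditionMessage(e)))
    NULL
  })
  res
}

#' Run the full analysis pipeline
#'
#' Executes every stage for which the configuration provides inputs -
#' length-force fitting, trace dynamics (rate of force development,
#' force-frequency, fatigue), morphometry, and qPCR quantification -
#' writing study-style result CSVs, a JSON fit record and a provenance
#' record (config hash, seed, package version) to the output directory.
#' Stages without inputs are skipped with a notice; a failing stage is
#' reported and does not abort the others. Reruns with identical inputs,
#' config and seed produce byte-identical outputs.
#'
#' @param config a [study_config()].
#' @return A `result_bundle` list: per-stage results (`lf`, `dynamics`,
#'   `ffreq`, `fatigue`, `morphometry`, `qpcr`), collected `warnings` and
#'   `errors`, `provenance`, and `out_dir`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- new.env()
  bundle$errors <- list()
  out <- list()
  warns <- character()
  const <- config$constants
  flags <- config$flags

  if (!is.null(config$lf_manifest)) {
    out$lf <- run_stage("length_force", bundle, {
      pts <- read_manifest(config$lf_manifest)
      fit <- fit_length_force(pts, passive_form = flags$passive_form,
                              subtract = flags$subtract,
                              alpha = const$alpha)
      warns <- c(warns, fit$warnings)
      row <- data.frame(F_mao_mN = fit$F_mao, L_mao_mm = fit$L_mao,
                        L_mas_mm = fit$L_mas,
                        range_mm = fit$length_range_mm,
                        F_mao_measured_mN = fit$F_mao_measured,
                        poly_order = fit$order,
                        boundary_optimum = fit$boundary_optimum)
      if (!is.null(config$tibia_mm)) {
        nrm <- normalize_length_force(fit, config$tibia_mm,
                                      body_mass_g = config$body_mass_g)
        row$L_mao_over_Ltibia <- round(nrm$L_mao_over_Ltibia, 2)
        row$L_mas_over_Ltibia <- round(nrm$L_mas_over_Ltibia, 2)
        row$range_over_Ltibia <- round(nrm$range_over_Ltibia, 2)
        if (!is.null(config$body_mass_g))
          row$F_mao_over_BM_mN_per_g <- round(nrm$F_mao_over_BM_mN_per_g, 1)
      }
      utils::write.csv(row, file.path(config$out_dir, "lf_results.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(coefficients = fit$coefficients, order = fit$order,
             selection_table = fit$selection_table,
             passive = if (is.null(fit$passive_fit)) NULL else
               list(form = fit$passive_fit$form,
                    coefficients = fit$passive_fit$coefficients,
                    rss = fit$passive_fit$rss,
                    degenerate = fit$passive_fit$degenerate),
             boundary_optimum = fit$boundary_optimum,
             warnings = fit$warnings),
        file.path(config$out_dir, "lf_fit.json"),
        auto_unbox = TRUE, digits = NA)
      fit
    })
  } else message("[myomech] no length-force manifest; stage skipped")

  dyn_row <- list()
  if (!is.null(config$mrfd_trace)) {
    out$dynamics <- run_stage("mrfd", bundle, {
      tr <- read_trace(config$mrfd_trace)
      ev <- if (!is.null(config$mrfd_events)) read_events(config$mrfd_events)
            else attr(tr, "stim_events")
      m <- mrfd(tr, ev)
      dyn_row$MRFD_mN_per_ms <- m$mrfd_mN_per_ms
      dyn_row$MRFD_over_Fmax <- m$mrfd_over_fmax
      m
    })
  }
  if (!is.null(config$ffreq_csv)) {
    out$ffreq <- run_stage("force_frequency", bundle, {
      df <- read_csv_checked(config$ffreq_csv,
                             c("frequency_hz", "total_force_mN",
                               "passive_force_mN"))
      curve <- force_frequency_curve(df$frequency_hz, df$total_force_mN,
                                     df$passive_force_mN,
                                     mode = flags$ffreq_mode)
      utils::write.csv(curve, file.path(config$out_dir, "ffreq_curve.csv"),
                       row.names = FALSE)
      curve
    })
  }
  if (!is.null(config$fatigue_peaks_csv)) {
    out$fatigue <- run_stage("fatigue", bundle, {
      df <- read_csv_checked(config$fatigue_peaks_csv, "peak_force_mN")
      fr <- fatigue_index(df$peak_force_mN, f_end_rule = flags$f_end_rule)
      dyn_row$fatigue_index_pct <- fr$fatigue_index_pct
      fr
    })
  }
  if (length(dyn_row))
    utils::write.csv(as.data.frame(dyn_row),
                     file.path(config$out_dir, "dynamics_results.csv"),
                     row.names = FALSE)

  if (!is.null(config$specimens_csv) && !is.null(config$fibers_csv)) {
    out$morphometry <- run_stage("morphometry", bundle, {
      spec <- read_specimens(config$specimens_csv)
      fib <- read_fibers(config$fibers_csv)
      m <- morphometry_summary(spec[1, ], fib,
                               optimum_sarcomere_um =
                                 const$optimum_sarcomere_um,
                               density_g_per_cm3 = const$density_g_per_cm3)
      row <- data.frame(Ssn = m$ssn_pooled, Lfo_mm = m$Lfo_mm,
                        volume_mm3 = m$volume_mm3, PCSA_mm2 = m$PCSA_mm2)
      if (!is.null(m$tendon_mm)) {
        row$tendon_mm <- m$tendon_mm
        row$tendon_over_Ltibia <- m$tendon_over_Ltibia
      }
      if (!is.null(config$nuclei_csv)) {
        nuc <- read_nuclei(config$nuclei_csv)
        lf_um <- mean(fib$fiber_length_mm) * 1000
        mnf <- myonuclei_per_fiber(mean(nuc$counted_profiles), lf_um,
                                   const$nucleus_um, const$section_um)
        row$Mn_f <- mnf
        row$myonuclear_domain <- myonuclear_domain(
          mean(nuc$fiber_csa_um2), mnf / (lf_um / 1000))
      }
      utils::write.csv(row,
                       file.path(config$out_dir, "morphometry_results.csv"),
                       row.names = FALSE)
      m
    })
  }

  if (!is.null(config$qpcr_csv)) {
    out$qpcr <- run_stage("qpcr", bundle, {
      df <- read_csv_checked(config$qpcr_csv,
                             c("ct_rep1", "ct_rep2", "ct_18s_mean"))
      res <- qpcr_table(df, orientation = flags$dct_orientation)
      utils::write.csv(res, file.path(config$out_dir, "qpcr_results.csv"),
                       row.names = FALSE)
      res
    })
  }

  provenance <- list(
    package = "myomech",
    version = as.character(utils::packageVersion("myomech")),
    seed = config$seed,
    config_hash = config_hash(config[setdiff(names(config), "out_dir")])
  )
  jsonlite::write_json(provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(lf = out$lf, dynamics = out$dynamics, ffreq = out$ffreq,
                 fatigue = out$fatigue, morphometry = out$morphometry,
                 qpcr = out$qpcr,
                 warnings = warns, errors = bundle$errors,
                 provenance = provenance, out_dir = config$out_dir),
            class = "result_bundle")
}

#' @export
print.result_bundle <- function(x, ...) {
  ran <- names(Filter(Negate(is.null),
                      x[c("lf", "dynamics", "ffreq", "fatigue",
                          "morphometry", "qpcr")]))
  cat("myomech result bundle\n")
  cat("  stages run:", if (length(ran)) paste(ran, collapse = ", ")
                       else "none", "\n")
  if (length(x$errors))
    cat("  stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  cat("  outputs in:", x$out_dir, "\n")
  invisible(x)
}
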