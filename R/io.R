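#' File formats
#'
#' All tabular inputs and outputs are plain CSV with unit-suffixed headers
#' (`time_ms`, `force_mN`, `muscle_length_mm`, ...), UTF-8, '.' decimal
#' separator. Fits and provenance are JSON; masks are single-channel TIFF
#' (16-bit labels, 8-bit binary) with pixel size in a JSON sidecar. Readers
#' validate strictly and report the offending column or cell.
#'
#' @name myomech-io
NULL

read_csv_checked <- function(file, cols, what = basename(file)) {
  if (!file.exists(file)) stop_myomech("file not found: %s", file)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  require_columns(df, cols, what)
  for (cl in cols) {
    v <- df[[cl]]
    if (is.character(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "")
      if (length(bad))
        stop_myomech("%s: non-numeric value '%s' in column %s, line %d",
                     what, v[bad[1]], cl, bad[1] + 1L)
      df[[cl]] <- num
    }
  }
  df
}

#' Read and write force traces
#'
#' A trace CSV has columns `time_ms`, `force_mN`; sampling uniformity is
#' validated on read (see [force_trace()]).
#'
#' @param file path to a CSV file.
#' @return `read_trace()`: a [force_trace()].
#' @export
read_trace <- function(file) {
  df <- read_csv_checked(file, c("time_ms", "force_mN"))
  force_trace(df$time_ms, df$force_mN)
}

#' @rdname read_trace
#' @param trace a [force_trace()].
#' @export
write_trace <- function(trace, file) {
  utils::write.csv(as.data.frame(trace)[, c("time_ms", "force_mN")], file,
                   row.names = FALSE)
  invisible(file)
}

#' Read and write stimulation-event tables
#'
#' Events CSV: `kind`, `onset_ms`, `offset_ms`, optional `frequency_hz`,
#' `muscle_length_mm`.
#'
#' @param file path to a CSV file.
#' @return `read_events()`: a [stim_events()] table.
#' @export
read_events <- function(file) {
  df <- read_csv_checked(file, c("onset_ms", "offset_ms"))
  require_columns(df, "kind", basename(file))
  stim_events(df$kind, df$onset_ms, df$offset_ms,
              frequency_hz = if ("frequency_hz" %in% names(df))
                df$frequency_hz else NA_real_,
              muscle_length_mm = if ("muscle_length_mm" %in% names(df))
                df$muscle_length_mm else NA_real_)
}

#' @rdname read_events
#' @param events a [stim_events()] table.
#' @export
write_events <- function(events, file) {
  utils::write.csv(as.data.frame(events), file, row.names = FALSE)
  invisible(file)
}

#' Read a length-series manifest
#'
#' Manifest CSV: `contraction_id`, `muscle_length_mm`, `total_force_mN`,
#' `passive_force_mN`.
#'
#' @param file path to a CSV file.
#' @param length_type `"muscle"` or `"mtc"`, see [length_force_points()].
#' @return A [length_force_points()] table.
#' @export
read_manifest <- function(file, length_type = "muscle") {
  df <- read_csv_checked(file, c("muscle_length_mm", "total_force_mN",
                                 "passive_force_mN"))
  length_force_points(df$muscle_length_mm, df$total_force_mN,
                      df$passive_force_mN, length_type = length_type)
}

#' Read morphometry input tables
#'
#' `read_specimens()`: `specimens.csv` with `muscle_mass_mg`, `tibia_mm`
#' and optionally `mtc_opt_mm`, `belly_opt_mm`, `body_mass_g`.
#' `read_fibers()`: `fibers.csv` with `fiber_id`, `fiber_length_mm` and
#' `mean_sl_um` or `n_sarcomeres` (plus optional `region`).
#' `read_nuclei()`: `nuclei.csv` with `fiber_id`, `counted_profiles`,
#' `fiber_csa_um2`.
#'
#' @param file path to a CSV file.
#' @return A validated data frame.
#' @export
read_specimens <- function(file) {
  read_csv_checked(file, c("muscle_mass_mg", "tibia_mm"))
}

#' @rdname read_specimens
#' @export
read_fibers <- function(file) {
  df <- read_csv_checked(file, "fiber_length_mm")
  if (!any(c("mean_sl_um", "n_sarcomeres") %in% names(df)))
    stop_myomech("%s needs a mean_sl_um or n_sarcomeres column",
                 basename(file))
  df
}

#' @rdname read_specimens
#' @export
read_nuclei <- function(file) {
  read_csv_checked(file, c("counted_profiles", "fiber_csa_um2"))
}

#' Write and read ground-truth JSON
#'
#' Serializes a [ground_truth()] record to `truth.json` alongside a
#' simulated dataset, and reads it back.
#'
#' @param gt a [ground_truth()] record.
#' @param file path to a JSON file.
#' @export
write_truth_json <- function(gt, file) {
  stopifnot(inherits(gt, "ground_truth"))
  jsonlite::write_json(unclass(gt), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(file) {
  do.call(ground_truth, jsonlite::read_json(file, simplifyVector = TRUE))
}

#' Write and read section masks as TIFF
#'
#' Label masks are written as 16-bit single-channel TIFF, binary masks as
#' 8-bit; the pixel size travels in a JSON sidecar (`<file>.json`).
#'
#' @param section a [labeled_section()].
#' @param file path to the label TIFF; the connective mask (if present)
#'   goes to `<stem>_connective.tif`.
#' @export
write_section_tiff <- function(section, file) {
  stopifnot(inherits(section, "labeled_section"))
  tiff::writeTIFF(section$labels / 65535, file, bits.per.sample = 16L)
  jsonlite::write_json(list(pixel_size_um = section$pixel_size_um,
                            region = section$region),
                       paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(section$connective)) {
    ct_file <- sub("\\.tiff?$", "_connective.tif", file)
    tiff::writeTIFF(section$connective / 255, ct_file, bits.per.sample = 8L)
  }
  invisible(file)
}

#' @rdname write_section_tiff
#' @param file path to the label TIFF written by [write_section_tiff()].
#' @export
read_section_tiff <- function(file) {
  labels <- round(tiff::readTIFF(file) * 65535)
  side <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  ct_file <- sub("\\.tiff?$", "_connective.tif", file)
  connective <- if (file.exists(ct_file))
    round(tiff::readTIFF(ct_file) * 255) else NULL
  labeled_section(labels, side$pixel_size_um, connective = connective,
                  region = side$region)
}
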