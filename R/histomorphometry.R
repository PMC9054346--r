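#' Labeled muscle cross-section
#'
#' A label image of a muscle cross-section (integer matrix; 0 = background
#' or connective tissue, positive integers = fibers) with its pixel size
#' and, optionally, a binary connective-tissue mask of identical geometry.
#'
#' @param labels integer matrix of fiber labels.
#' @param pixel_size_um pixel size (um/px), positive.
#' @param connective optional binary (0/1) matrix of connective tissue,
#'   same dimensions as `labels`.
#' @param region region tag: `"whole"`, `"high_oxidative"` or
#'   `"low_oxidative"`.
#' @return A `labeled_section` list.
#' @export
labeled_section <- function(labels, pixel_size_um, connective = NULL,
                            region = c("whole", "high_oxidative",
                                       "low_oxidative")) {
  region <- match.arg(region)
  if (!is.matrix(labels)) stop_myomech("labels must be a matrix")
  if (any(labels < 0) || any(labels != round(labels)))
    stop_myomech("labels must be non-negative integers")
  check_number(pixel_size_um, "pixel_size_um", lower = 0,
               allow_equal = FALSE)
  if (!is.null(connective)) {
    if (!identical(dim(connective), dim(labels)))
      stop_myomech("connective mask and labels must share dimensions")
    if (!all(connective %in% c(0, 1)))
      stop_myomech("connective mask must be binary (0/1)")
  }
  structure(list(labels = labels, pixel_size_um = pixel_size_um,
                 connective = connective, region = region),
            class = "labeled_section")
}

#' @export
print.labeled_section <- function(x, ...) {
  cat(sprintf("Labeled section: %dx%d px at %g um/px, %d fibers (%s)%s\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size_um,
              length(setdiff(unique(as.vector(x$labels)), 0L)), x$region,
              if (is.null(x$connective)) "" else ", connective mask"))
  invisible(x)
}

# per-label crack-length perimeter: count 4-neighbour edges between a fiber
# pixel and a pixel of any other value, times the pixel size. Edges on the
# image border are NOT counted: a fiber clipped by the ROI is treated as
# continuing beyond it, so ROI cropping does not inflate perimeters (and
# hence does not deflate area-over-perimeter thickness measures).
label_perimeters <- function(labels, pixel_size_um) {
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  n <- max(ids)
  counts <- numeric(n)
  nr <- nrow(labels); nc <- ncol(labels)
  pad <- function(shift_r, shift_c) {
    nb <- matrix(NA_integer_, nr, nc)  # NA outside: border edges ignored
    rs <- seq_len(nr) + shift_r
    cs <- seq_len(nc) + shift_c
    ok_r <- rs >= 1 & rs <= nr
    ok_c <- cs >= 1 & cs <= nc
    nb[ok_r, ok_c] <- labels[rs[ok_r], cs[ok_c]]
    nb
  }
  for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- pad(sh[1], sh[2])
    edge <- labels > 0L & !is.na(nb) & nb != labels
    counts <- counts + tabulate(labels[edge], nbins = n)
  }
  data.frame(fiber = ids, perimeter_um = counts[ids] * pixel_size_um)
}

#' Per-fiber cross-sectional areas and perimeters
#'
#' Area per fiber is its pixel count times the squared pixel size; the
#' perimeter (needed for endomysium thickness) is the 4-neighbour
#' crack-length boundary estimate. The conventional protocol averages at
#' least 50 fibers; fewer produce a warning, not an error.
#'
#' @param section a [labeled_section()].
#' @param subset optional vector of fiber labels to include.
#' @param warn_below warn when fewer than this many fibers are measured
#'   (default 50; set 0 to silence).
#' @return List: `per_fiber` (data frame `fiber`, `area_um2`,
#'   `perimeter_um`), `mean_area_um2`, `sd_area_um2`, `n`.
#' @export
fiber_csa_stats <- function(section, subset = NULL, warn_below = 50) {
  stopifnot(inherits(section, "labeled_section"))
  labels <- section$labels
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (!length(ids)) stop_myomech("label image contains no fibers")
  if (!is.null(subset)) ids <- intersect(ids, subset)
  if (!length(ids)) stop_myomech("subset matches no fibers")
  px2 <- section$pixel_size_um^2
  counts <- tabulate(labels, nbins = max(ids))
  per <- label_perimeters(labels, section$pixel_size_um)
  per_fiber <- data.frame(fiber = ids, area_um2 = counts[ids] * px2)
  per_fiber <- merge(per_fiber, per, by = "fiber")
  if (length(ids) < warn_below)
    warning(sprintf("fewer than %d fibers measured (n = %d)", warn_below,
                    length(ids)), call. = FALSE)
  list(per_fiber = per_fiber,
       mean_area_um2 = mean(per_fiber$area_um2),
       sd_area_um2 = stats::sd(per_fiber$area_um2),
       n = length(ids))
}

# Otsu threshold of a numeric vector (maximal between-class variance over a
# 256-bin histogram)
otsu_threshold <- function(x, bins = 256L) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- hist(x, breaks = seq(r[1], r[2], length.out = bins + 1L),
            plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# Otsu with a bimodality guard: the split must explain most of the channel
# variance (between-class variance fraction eta^2 >= 0.8), otherwise the
# channel carries no positive fibers - an all-negative antibody channel
# would otherwise be split down the middle of its background noise.
channel_threshold <- function(x, min_eta2 = 0.8) {
  th <- otsu_threshold(x)
  lo <- x[x <= th]
  hi <- x[x > th]
  if (length(lo) < 2L || length(hi) < 2L) return(Inf)
  p <- length(hi) / length(x)
  between <- p * (1 - p) * (mean(hi) - mean(lo))^2
  total <- stats::var(x) * (length(x) - 1) / length(x)
  if (total <= 0 || between / total < min_eta2) Inf else th
}

#' Classify fiber types from per-fiber channel intensities
#'
#' Threshold-based myosin heavy chain typing with hybrid fibers: a fiber is
#' positive for every channel whose intensity exceeds that channel's
#' threshold. Single positives become pure types; multi-positives become
#' hybrids labeled with the sorted combination (e.g. `"IIA/IIX"`); fibers
#' positive on no channel are `"unclassified"`. Thresholds default to a
#' per-channel Otsu split of the intensity distribution, with a bimodality
#' guard: a channel whose split does not separate two clearly distinct
#' intensity classes is treated as having no positive fibers.
#'
#' The antibody-to-isoform mapping is a configurable table. The default
#' follows the staining panel order BAD5 -> I, SC-71 -> IIA, 6H1 -> IIB,
#' BF-F3 -> IIX; note that the common convention swaps the last two
#' (BF-F3 -> IIB), selectable via `channel_types`.
#'
#' @param intensities numeric matrix, fibers in rows, one column per
#'   antibody channel.
#' @param thresholds named numeric vector of per-channel thresholds, or
#'   `NULL` for Otsu.
#' @param channel_types character vector mapping columns to isoform names,
#'   by default `c("I", "IIA", "IIX", "IIB")` in column order.
#' @return List: `type` (character per fiber), `proportions` (over
#'   classified fibers; sums to 1), `n_classified`, `thresholds`.
#' @export
classify_fiber_types <- function(intensities, thresholds = NULL,
                                 channel_types = c("I", "IIA", "IIX",
                                                   "IIB")) {
  intensities <- as.matrix(intensities)
  if (any(intensities < 0)) stop_myomech("intensities must be >= 0")
  nc <- ncol(intensities)
  if (length(channel_types) != nc)
    stop_myomech("channel_types must name every intensity column")
  if (is.null(thresholds))
    thresholds <- apply(intensities, 2, channel_threshold)
  if (length(thresholds) != nc)
    stop_myomech("one threshold per channel required")
  pos <- sweep(intensities, 2, thresholds, `>`)
  type <- apply(pos, 1, function(p) {
    hit <- channel_types[p]
    if (!length(hit)) return("unclassified")
    paste(hit[order(match(hit, channel_types))], collapse = "/")
  })
  classified <- type != "unclassified"
  if (!any(classified))
    stop_myomech("no fiber exceeded any channel threshold")
  tab <- table(type[classified])
  list(type = type,
       proportions = stats::setNames(as.numeric(tab) / sum(tab), names(tab)),
       n_classified = sum(classified),
       thresholds = thresholds)
}

#' Succinate dehydrogenase activity from stain gray values
#'
#' Converts mean fiber and blank gray values to absorbance,
#' `A = -log10(gray_fiber / gray_blank)`, and expresses SDH activity as
#' absorbance per um section thickness per second of incubation
#' (delta A660 / um / s). A fiber brighter than the blank yields a negative
#' activity and a flag.
#'
#' @param mean_gray_fiber mean fiber gray value (same scale as blank).
#' @param mean_gray_blank mean gray value of an unstained blank region,
#'   positive.
#' @param section_thickness_um section thickness (um), default 10.
#' @param incubation_s incubation time (s); no default - it is a protocol
#'   parameter that must be supplied.
#' @return List: `absorbance`, `activity` (delta A660 / um / s),
#'   `negative` flag.
#' @examples
#' sdh_activity(25.5, 255, incubation_s = 900)
#' @export
sdh_activity <- function(mean_gray_fiber, mean_gray_blank,
                         section_thickness_um = 10, incubation_s) {
  if (missing(incubation_s))
    stop_myomech("incubation_s is required (protocol parameter, no default)")
  if (any(mean_gray_blank <= 0)) stop_myomech("blank gray must be positive")
  if (any(mean_gray_fiber <= 0)) stop_myomech("fiber gray must be positive")
  check_number(section_thickness_um, "section_thickness_um", lower = 0,
               allow_equal = FALSE)
  check_number(incubation_s, "incubation_s", lower = 0, allow_equal = FALSE)
  A <- -log10(mean_gray_fiber / mean_gray_blank)
  act <- A / (section_thickness_um * incubation_s)
  list(absorbance = A, activity = act, negative = any(act < 0))
}

#' Mean endomysium thickness per fiber
#'
#' For a region of interest containing only muscle fibers and endomysium:
#' the endomysial area per fiber divided by the mean fiber perimeter,
#' \deqn{L_e = \frac{A_{endo} / n_{fibers}}{\bar{P}_{fiber}},}
#' plus the endomysium area fraction of the ROI. The standard protocol
#' averages ten such ROIs; [endomysium_Le_batch()] does that.
#'
#' @param section a [labeled_section()] whose `connective` mask is the
#'   endomysium.
#' @return List: `L_e_um`, `endomysium_area_fraction`, `n_fibers`,
#'   `mean_perimeter_um`.
#' @export
endomysium_Le <- function(section) {
  stopifnot(inherits(section, "labeled_section"))
  if (is.null(section$connective))
    stop_myomech("section has no connective-tissue mask")
  stats <- fiber_csa_stats(section, warn_below = 0)
  mean_per <- mean(stats$per_fiber$perimeter_um)
  if (mean_per <= 0) stop_myomech("mean fiber perimeter is zero")
  px2 <- section$pixel_size_um^2
  area_ct <- sum(section$connective) * px2
  list(L_e_um = (area_ct / stats$n) / mean_per,
       endomysium_area_fraction = sum(section$connective) /
         length(section$connective),
       n_fibers = stats$n,
       mean_perimeter_um = mean_per)
}

#' @rdname endomysium_Le
#' @param sections list of [labeled_section()] ROIs.
#' @return For the batch version: list with the mean `L_e_um` over ROIs and
#'   the per-ROI values.
#' @export
endomysium_Le_batch <- function(sections) {
  per_roi <- vapply(sections, function(s) endomysium_Le(s)$L_e_um,
                    numeric(1))
  list(L_e_um = mean(per_roi), per_roi_um = per_roi)
}

# distance (um) from points to the nearest non-connective pixel centre
dist_to_background <- function(x_um, y_um, connective, pixel_size_um) {
  bg <- which(connective == 0, arr.ind = TRUE)
  bx <- (bg[, 1] - 0.5) * pixel_size_um
  by <- (bg[, 2] - 0.5) * pixel_size_um
  vapply(seq_along(x_um), function(i) {
    sqrt(min((bx - x_um[i])^2 + (by - y_um[i])^2))
  }, numeric(1))
}

#' Perimysium thickness along an annotation path
#'
#' Samples points every `spacing_um` of arc length along a polyline drawn
#' through a perimysial band and measures the local band thickness as twice
#' the distance from the sample point to the nearest non-connective pixel
#' (the medial-axis reading of thickness for a path running along the band
#' midline). Sample points falling outside the connective mask are dropped
#' with a warning; a path shorter than the spacing yields a single sample
#' at its start. The perimysial domain (smallest fascicles L_p1, compound
#' fascicles L_p2, or section-traversing bands L_p3) is a tag carried with
#' the path.
#'
#' @param path data frame with `x_um`, `y_um` vertex coordinates and
#'   optionally a `domain` column (`"Lp1"`, `"Lp2"` or `"Lp3"`).
#' @param section a [labeled_section()] with a connective mask.
#' @param spacing_um sampling interval along the path (um), default 25.
#' @return List: `thickness_um` (per-sample), `mean_um`, `n_dropped`,
#'   `domain`.
#' @export
perimysium_thickness <- function(path, section, spacing_um = 25) {
  stopifnot(inherits(section, "labeled_section"))
  if (is.null(section$connective))
    stop_myomech("section has no connective-tissue mask")
  require_columns(path, c("x_um", "y_um"), "annotation path")
  if (nrow(path) < 2L) stop_myomech("path needs at least 2 vertices")
  seg <- sqrt(diff(path$x_um)^2 + diff(path$y_um)^2)
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  s <- if (total < spacing_um) 0 else seq(0, total, by = spacing_um)
  xs <- stats::approx(arc, path$x_um, xout = s)$y
  ys <- stats::approx(arc, path$y_um, xout = s)$y

  px <- section$pixel_size_um
  i <- pmin(pmax(ceiling(xs / px), 1L), nrow(section$connective))
  j <- pmin(pmax(ceiling(ys / px), 1L), ncol(section$connective))
  inside <- section$connective[cbind(i, j)] == 1
  if (!any(inside))
    stop_myomech("every sample point lies outside the connective tissue")
  if (any(!inside))
    warning(sprintf("%d of %d perimysium samples outside connective %s",
                    sum(!inside), length(inside), "tissue; dropped"),
            call. = FALSE)
  d <- dist_to_background(xs[inside], ys[inside], section$connective, px)
  domain <- if ("domain" %in% names(path)) as.character(path$domain[1])
            else NA_character_
  list(thickness_um = 2 * d, mean_um = mean(2 * d),
       n_dropped = sum(!inside), domain = domain)
}
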