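#' Force-time trace
#'
#' A uniformly sampled force record. Sampling uniformity is enforced on
#' construction (relative step jitter above 1e-6 is rejected), so every
#' downstream derivative and windowing operation can assume a constant step.
#'
#' @param time_ms sample times (ms), strictly increasing and uniform.
#' @param force_mN forces (mN), same length.
#' @param meta optional named list (muscle id, protocol tag, ...).
#' @return A `force_trace` data frame with attributes `sampling_rate_hz`
#'   and `meta`.
#' @export
force_trace <- function(time_ms, force_mN, meta = list()) {
  if (length(time_ms) != length(force_mN))
    stop_myomech("time and force must have equal length")
  if (length(time_ms) < 2L) stop_myomech("a trace needs at least 2 samples")
  dt <- diff(time_ms)
  if (any(dt <= 0)) stop_myomech("time must be strictly increasing")
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop_myomech("non-uniform sampling: time steps vary by more than 1e-6")
  out <- data.frame(time_ms = time_ms, force_mN = force_mN)
  attr(out, "sampling_rate_hz") <- 1000 / dt[1]
  attr(out, "meta") <- meta
  class(out) <- c("force_trace", "data.frame")
  out
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("Force trace: %d samples at %.6g Hz, %.6g-%.6g ms\n",
              nrow(x), attr(x, "sampling_rate_hz"),
              x$time_ms[1], x$time_ms[nrow(x)]))
  invisible(x)
}

#' Stimulation events
#'
#' A table of stimulation events annotating a force trace: twitches, tetani
#' and high-frequency trains, with onset/offset times and, for tetani and
#' trains, the stimulation frequency.
#'
#' @param kind event kinds, each one of `"twitch"`, `"tetanus"`, `"train"`.
#' @param onset_ms,offset_ms event window (ms), onset strictly before offset.
#' @param frequency_hz stimulation frequency (Hz); required positive for
#'   tetanus/train events, `NA` allowed for twitches.
#' @param muscle_length_mm optional muscle length during the event.
#' @return A `stim_events` data frame.
#' @export
stim_events <- function(kind, onset_ms, offset_ms, frequency_hz = NA_real_,
                        muscle_length_mm = NA_real_) {
  kind <- match.arg(kind, c("twitch", "tetanus", "train"),
                    several.ok = TRUE)
  df <- data.frame(kind = kind, onset_ms = onset_ms, offset_ms = offset_ms,
                   frequency_hz = frequency_hz,
                   muscle_length_mm = muscle_length_mm)
  if (any(df$onset_ms >= df$offset_ms))
    stop_myomech("every event must have onset < offset")
  need_f <- df$kind %in% c("tetanus", "train")
  if (any(need_f & (is.na(df$frequency_hz) | df$frequency_hz <= 0)))
    stop_myomech("tetanus/train events need a positive frequency")
  class(df) <- c("stim_events", "data.frame")
  df
}

# Local-polynomial (Savitzky-Golay type) derivative of a uniformly sampled
# signal. Interior samples use a centered quadratic fit of the requested
# width. Samples too close to a segment boundary for a centered window -
# including the first sample, where the maximal slope of a saturating rise
# lives - use a one-sided cubic fit over a three-fold window: the higher
# order removes the boundary bias and the wider support keeps the variance
# of the off-centre derivative in check.
local_quadratic_deriv <- function(y, dt_ms, window_ms) {
  n <- length(y)
  half <- max(2L, round(window_ms / (2 * dt_ms)))
  d <- numeric(n)
  for (i in seq_len(n)) {
    if (i > half && i + half <= n) {
      tt <- (seq(i - half, i + half) - i) * dt_ms
      d[i] <- stats::lm.fit(cbind(1, tt, tt^2),
                            y[(i - half):(i + half)])$coefficients[2]
    } else {
      w3 <- min(6L * half, n - 1L)
      lo <- if (i <= half) 1L else n - w3
      hi <- lo + w3
      tt <- (seq(lo, hi) - i) * dt_ms
      d[i] <- stats::lm.fit(cbind(1, tt, tt^2, tt^3),
                            y[lo:hi])$coefficients[2]
    }
  }
  d
}

moving_average <- function(y, width) {
  if (width <= 1L) return(y)
  k <- rep(1 / width, width)
  pad <- floor(width / 2)
  ypad <- c(rep(y[1], pad), y, rep(y[length(y)], width - 1 - pad))
  stats::filter(ypad, k, sides = 1)[(width):(length(y) + width - 1)]
}

#' Maximal rate of force development
#'
#' Estimates the maximal slope of the force rise during a high-frequency
#' pulse train. The trace is baseline-corrected (mean force over
#' `baseline_window`), the derivative on the rising phase (onset to the
#' first plateau sample, i.e. the smoothed maximum) is estimated by a
#' centered local-quadratic fit of width `smooth_ms`, and the maximum of
#' that derivative is returned together with the maximal smoothed active
#' force and their ratio. The local-polynomial estimator performs smoothing
#' and differentiation in one step; near the onset the fit window is shifted
#' inside the record and evaluated off-centre, which avoids the downward
#' bias a plain moving-average-plus-difference scheme suffers exactly where
#' the rise is steepest.
#'
#' @param trace a [force_trace()].
#' @param event a single-row train event from [stim_events()]; defaults to
#'   the `stim_events` attribute of the trace.
#' @param baseline_window length-2 vector (ms) of the baseline interval;
#'   defaults to everything before the event onset. Must precede the onset.
#' @param smooth_ms width of the local-fit window (ms). The rise must be
#'   longer than the window.
#' @return List with `mrfd_mN_per_ms`, `f_max_mN`, `mrfd_over_fmax` and the
#'   rising-phase derivative trace (`deriv`).
#' @examples
#' gt <- ground_truth(F_opt = 200, rise_tau = 20, noise_sd = 0)
#' tr <- simulate_tetanus_trace(gt, duration_ms = 150, sampling_hz = 10000)
#' mrfd(tr)$mrfd_mN_per_ms # ~ F_opt / rise_tau = 10
#' @export
mrfd <- function(trace, event = NULL, baseline_window = NULL, smooth_ms = 5) {
  stopifnot(inherits(trace, "force_trace"))
  if (is.null(event)) event <- attr(trace, "stim_events")
  if (is.null(event)) stop_myomech("no stimulation event supplied or attached")
  event <- as.data.frame(event)
  if (nrow(event) != 1L || event$kind != "train")
    stop_myomech("mrfd needs exactly one 'train' event")
  t <- trace$time_ms
  dt <- 1000 / attr(trace, "sampling_rate_hz")
  if (is.null(baseline_window)) baseline_window <- c(t[1], event$onset_ms)
  if (baseline_window[2] > event$onset_ms + dt / 2)
    stop_myomech("baseline window must precede the train onset")
  bl <- t >= baseline_window[1] & t <= baseline_window[2]
  if (!any(bl)) stop_myomech("baseline window contains no samples")
  f <- trace$force_mN - mean(trace$force_mN[bl])

  on_idx <- which(t >= event$onset_ms)[1]
  seg <- f[on_idx:length(f)]
  width <- max(3L, round(smooth_ms / dt))
  smooth <- moving_average(seg, width)
  plateau <- which.max(smooth)
  if ((plateau - 1) * dt <= smooth_ms)
    stop_myomech(paste("rising phase (%g ms) is shorter than the smoothing",
                       "window (%g ms); reduce smooth_ms"),
                 (plateau - 1) * dt, smooth_ms)
  rise <- seg[1:plateau]
  dforce <- local_quadratic_deriv(rise, dt, smooth_ms)
  f_max <- max(smooth)
  list(mrfd_mN_per_ms = max(dforce),
       f_max_mN = f_max,
       mrfd_over_fmax = max(dforce) / f_max,
       deriv = dforce)
}

#' Normalized force-frequency curve
#'
#' Subtracts the passive force from the per-frequency total peak forces and
#' divides by the maximal active force over frequencies, so the curve's
#' maximum is exactly 1. Set `mode = "total"` to divide the raw total force
#' by the maximal total instead (no passive subtraction).
#'
#' @param frequency_hz stimulation frequencies (at least 3).
#' @param total_force_mN peak total force at each frequency.
#' @param passive_force_mN passive force (scalar, or one per frequency).
#' @param mode `"active"` (default) or `"total"`.
#' @return Data frame `frequency_hz`, `relative_force`.
#' @export
force_frequency_curve <- function(frequency_hz, total_force_mN,
                                  passive_force_mN = 0,
                                  mode = c("active", "total")) {
  mode <- match.arg(mode)
  if (length(frequency_hz) < 3L)
    stop_myomech("need at least 3 frequencies, got %d", length(frequency_hz))
  if (length(total_force_mN) != length(frequency_hz))
    stop_myomech("one total force per frequency required")
  num <- if (mode == "active") total_force_mN - passive_force_mN
         else total_force_mN
  if (max(num) <= 0)
    stop_myomech("maximal %s force is not positive; cannot normalize", mode)
  data.frame(frequency_hz = frequency_hz, relative_force = num / max(num))
}

#' Peak force of each contraction in a repeated-stimulation run
#'
#' Splits a trace into per-contraction windows - either the events table or
#' a fixed stimulation period - and returns the maximal force in each.
#'
#' @param trace a [force_trace()].
#' @param events optional [stim_events()]; if absent, windows are inferred
#'   from `period_ms`.
#' @param period_ms stimulation period for inferred windows (default 1000 ms,
#'   the once-per-second fatigue protocol).
#' @return Numeric vector of peak forces (mN).
#' @export
extract_contraction_peaks <- function(trace, events = NULL, period_ms = 1000) {
  stopifnot(inherits(trace, "force_trace"))
  t <- trace$time_ms
  if (!is.null(events)) {
    vapply(seq_len(nrow(events)), function(i) {
      w <- t >= events$onset_ms[i] & t <= events$offset_ms[i]
      if (!any(w)) stop_myomech("event %d covers no samples", i)
      max(trace$force_mN[w])
    }, numeric(1))
  } else {
    idx <- floor((t - t[1]) / period_ms)
    as.numeric(tapply(trace$force_mN, idx, max))
  }
}

#' Fatigue index of a repeated-contraction protocol
#'
#' Percentage decrease of active force at the end of a series of
#' contractions relative to the maximal force obtained during the protocol:
#' `100 * (1 - F_end / F_max)`. `F_end` is the final contraction's peak by
#' default, or the mean of the last `k` peaks.
#'
#' @param peaks per-contraction peak forces (mN), at least 2.
#' @param f_end_rule `"last"` (default) or `"mean_last_k"`.
#' @param k number of final contractions averaged under `"mean_last_k"`.
#' @return A `fatigue_result` list: `per_contraction_peaks`,
#'   `F_max_protocol`, `F_end`, `fatigue_index_pct`.
#' @examples
#' fatigue_index(c(100, 90, 75, 62, 60))$fatigue_index_pct # 40
#' @export
fatigue_index <- function(peaks, f_end_rule = c("last", "mean_last_k"),
                          k = 3L) {
  f_end_rule <- match.arg(f_end_rule)
  peaks <- as.numeric(peaks)
  if (length(peaks) < 2L) stop_myomech("need at least 2 contractions")
  f_max <- max(peaks)
  if (f_max <= 0) stop_myomech("maximal protocol force must be positive")
  f_end <- if (f_end_rule == "last") peaks[length(peaks)]
           else mean(utils::tail(peaks, k))
  structure(list(per_contraction_peaks = peaks,
                 F_max_protocol = f_max,
                 F_end = f_end,
                 fatigue_index_pct = 100 * (1 - f_end / f_max)),
            class = "fatigue_result")
}

#' @export
print.fatigue_result <- function(x, ...) {
  cat(sprintf(
    "Fatigue: %d contractions, F_max %.4g mN, F_end %.4g mN, index %.2f%%\n",
    length(x$per_contraction_peaks), x$F_max_protocol, x$F_end,
    x$fatigue_index_pct))
  invisible(x)
}
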