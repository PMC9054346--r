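#' Length-force data points
#'
#' One row per tetanic contraction of an isometric length series: the
#' imposed length, the peak total force, and the passive force measured just
#' before the tetanus. Whether lengths refer to the muscle belly or to the
#' whole muscle-tendon complex is an explicit flag that is carried through
#' to the results.
#'
#' @param muscle_length_mm lengths (mm), strictly positive and distinct.
#' @param total_force_mN peak tetanic forces (mN).
#' @param passive_force_mN passive forces (mN).
#' @param length_type `"muscle"` or `"mtc"` (muscle-tendon complex).
#' @param tol allowance (mN) by which passive force may exceed total force
#'   before the row is rejected. The check exists to catch unit mix-ups and
#'   gross recording errors, not measurement noise, so the default scales
#'   with the force range: `max(25, 0.15 * range(total force))`.
#' @return A `length_force_points` data frame.
#' @export
length_force_points <- function(muscle_length_mm, total_force_mN,
                                passive_force_mN,
                                length_type = c("muscle", "mtc"),
                                tol = NULL) {
  length_type <- match.arg(length_type)
  if (is.null(tol))
    tol <- max(25, 0.15 * diff(range(total_force_mN)))
  n <- length(muscle_length_mm)
  if (length(total_force_mN) != n || length(passive_force_mN) != n)
    stop_myomech("length, total force and passive force must align")
  if (any(muscle_length_mm <= 0))
    stop_myomech("muscle lengths must be positive")
  if (anyDuplicated(muscle_length_mm))
    stop_myomech("muscle lengths must be distinct")
  bad <- passive_force_mN > total_force_mN + tol
  if (any(bad))
    stop_myomech("passive force exceeds total force beyond tolerance at %s mm",
                 paste(muscle_length_mm[bad], collapse = ", "))
  out <- data.frame(muscle_length_mm = muscle_length_mm,
                    total_force_mN = total_force_mN,
                    passive_force_mN = passive_force_mN)
  attr(out, "length_type") <- length_type
  class(out) <- c("length_force_points", "data.frame")
  out
}

#' Passive force from a contraction trace
#'
#' The passive force at a given length is the mean force in the quiet
#' interval between the second conditioning twitch and the tetanus, after a
#' settle margin following the twitch.
#'
#' @param trace a [force_trace()].
#' @param events a [stim_events()] table containing at least two twitches
#'   followed by a tetanus.
#' @param settle_ms margin (ms) after the second twitch's offset excluded
#'   from the averaging window.
#' @return Mean passive force (mN).
#' @export
extract_passive_force <- function(trace, events, settle_ms = 50) {
  stopifnot(inherits(trace, "force_trace"))
  tw <- events[events$kind == "twitch", , drop = FALSE]
  if (nrow(tw) < 2L)
    stop_myomech("events contain %d twitch(es); two conditioning twitches %s",
                 nrow(tw), "are required")
  tw <- tw[order(tw$onset_ms), ]
  tet <- events[events$kind %in% c("tetanus", "train") &
                events$onset_ms > tw$offset_ms[2], , drop = FALSE]
  if (nrow(tet) == 0L)
    stop_myomech("no tetanus event found after the second twitch")
  lo <- tw$offset_ms[2] + settle_ms
  hi <- min(tet$onset_ms)
  if (hi <= lo)
    stop_myomech("window between second twitch (+%g ms settle) and tetanus %s",
                 settle_ms, "is empty; reduce settle_ms")
  w <- trace$time_ms > lo & trace$time_ms < hi
  if (!any(w))
    stop_myomech("no samples between second twitch and tetanus")
  mean(trace$force_mN[w])
}

#' Fit the passive length-force curve
#'
#' Nonlinear least squares in a second-order-exponential family. The default
#' form is `passive(L) = exp(b0 + b1 L) + b2` (exponential with a force
#' offset); `form = "exp-quadratic"` selects
#' `passive(L) = exp(b0 + b1 L + b2 L^2)` instead. Fitting uses
#' Levenberg-Marquardt with a deterministic multi-start grid on the rate
#' coefficient (a log-linearized start plus five fixed rates), keeping the
#' converged fit with the lowest residual sum of squares. A series whose
#' passive forces are all numerically zero
#' returns a degenerate, flagged fit that predicts zero everywhere.
#'
#' @param lengths muscle lengths (mm), at least 4 distinct values.
#' @param passive_mN measured passive forces (mN).
#' @param form functional form, `"exp-linear-plus-offset"` (default) or
#'   `"exp-quadratic"`.
#' @return A `passive_fit` list: `coefficients` (b0, b1, b2), `form`,
#'   `rss`, `degenerate`, `fitted`, plus the data range.
#' @examples
#' L <- seq(11, 16, by = 0.5)
#' y <- exp(-12 + 0.9 * L) + 1
#' fit_passive(L, y)$coefficients
#' @export
fit_passive <- function(lengths, passive_mN,
                        form = c("exp-linear-plus-offset", "exp-quadratic")) {
  form <- match.arg(form)
  if (length(lengths) < 4L)
    stop_myomech("passive fit needs at least 4 points, got %d",
                 length(lengths))
  if (anyDuplicated(lengths)) stop_myomech("lengths must be distinct")
  if (length(passive_mN) != length(lengths))
    stop_myomech("one passive force per length required")

  scale <- max(abs(passive_mN))
  if (scale < 1e-9) {
    return(structure(list(
      coefficients = c(b0 = NA_real_, b1 = NA_real_, b2 = 0),
      form = form, rss = 0, degenerate = TRUE,
      fitted = rep(0, length(lengths)),
      length_range = range(lengths)
    ), class = "passive_fit"))
  }

  span <- diff(range(lengths))
  # linearized start: log(y - offset) ~ L with offset just below min(y)
  off <- min(passive_mN) - 0.05 * scale
  z <- pmax(passive_mN - off, 1e-6 * scale)
  lf <- stats::lm(log(z) ~ lengths)
  b1_grid <- c(unname(stats::coef(lf)[2]),            # log-linear slope
               c(0.2, 0.5, 1, 2, 4) / span * 4)       # gentle to steep
  best <- NULL
  for (b1s in b1_grid) {
    start <- switch(form,
      "exp-linear-plus-offset" = list(b0 = unname(stats::coef(lf)[1]),
                                      b1 = b1s, b2 = off),
      "exp-quadratic" = list(b0 = unname(stats::coef(lf)[1]),
                             b1 = b1s, b2 = 0))
    fml <- switch(form,
      "exp-linear-plus-offset" = passive_mN ~ exp(b0 + b1 * lengths) + b2,
      "exp-quadratic" = passive_mN ~ exp(b0 + b1 * lengths + b2 * lengths^2))
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, start = start,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-10, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop_myomech("passive fit did not converge from any of %d starts",
                 length(b1_grid))
  cf <- stats::coef(best$fit)
  structure(list(
    coefficients = c(b0 = unname(cf["b0"]), b1 = unname(cf["b1"]),
                     b2 = unname(cf["b2"])),
    form = form, rss = best$rss, degenerate = FALSE,
    fitted = stats::fitted(best$fit),
    length_range = range(lengths)
  ), class = "passive_fit")
}

#' Evaluate a fitted passive curve
#'
#' @param object a [fit_passive()] result.
#' @param lengths muscle lengths (mm).
#' @param ... ignored.
#' @return Predicted passive forces (mN).
#' @export
predict.passive_fit <- function(object, lengths, ...) {
  if (object$degenerate) return(rep(object$coefficients[["b2"]],
                                    length(lengths)))
  b <- object$coefficients
  switch(object$form,
    "exp-linear-plus-offset" = exp(b[["b0"]] + b[["b1"]] * lengths) +
                               b[["b2"]],
    "exp-quadratic" = exp(b[["b0"]] + b[["b1"]] * lengths +
                          b[["b2"]] * lengths^2))
}

#' @export
print.passive_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Passive fit: degenerate (all-zero passive force)\n")
  } else {
    cat(sprintf("Passive fit (%s): b0 %.4g, b1 %.4g, b2 %.4g, rss %.4g\n",
                x$form, x$coefficients[1], x$coefficients[2],
                x$coefficients[3], x$rss))
  }
  invisible(x)
}

#' Active force per length
#'
#' Active force is total force minus passive force at each length. By
#' default the *measured* per-length passive value is subtracted; the fitted
#' passive curve (which describes the passive relation but smooths the
#' measurement) can be subtracted instead. Values near or below zero close
#' to the slack length are retained - clipping them would bias the slack
#' estimate.
#'
#' @param points a [length_force_points()] table.
#' @param passive `"measured"` (default) or `"fitted"`.
#' @param passive_fit required [fit_passive()] result when
#'   `passive = "fitted"`.
#' @return Data frame `muscle_length_mm`, `active_force_mN`.
#' @export
active_forces <- function(points, passive = c("measured", "fitted"),
                          passive_fit = NULL) {
  passive <- match.arg(passive)
  p <- if (passive == "measured") points$passive_force_mN
       else {
         if (is.null(passive_fit))
           stop_myomech("passive = 'fitted' needs a passive_fit")
         predict(passive_fit, points$muscle_length_mm)
       }
  data.frame(muscle_length_mm = points$muscle_length_mm,
             active_force_mN = points$total_force_mN - p)
}

# least-squares polynomial fit of given order; returns coefficients
# (ascending powers), rss and residual df, or NULL if rank deficient
fit_poly_order <- function(x, y, order) {
  X <- outer(x, 0:order, `^`)
  qrx <- qr(X)
  if (qrx$rank < order + 1L) return(NULL)
  cf <- qr.coef(qrx, y)
  res <- y - drop(X %*% cf)
  list(coefficients = unname(cf), rss = sum(res^2),
       df = length(y) - (order + 1L))
}

#' Select the polynomial order of the active length-force fit
#'
#' Fits nested polynomials of order 2 through `max_order` and compares
#' successive orders by the extra-sum-of-squares F-test,
#' \deqn{F = \frac{(RSS_k - RSS_{k+1})/1}{RSS_{k+1}/df_{k+1}},}
#' the nested-model reading of an ANOVA between fits. The selected order is
#' the lowest order k for which the step to k+1 no longer yields a
#' significant improvement at level `alpha`; if every step improves
#' significantly the highest order is kept. Exact fits are handled by a
#' relative tolerance on the residual sum of squares (so the procedure is
#' invariant to rescaling the forces). With fewer than `max_order + 2`
#' points the search is capped at the highest estimable order, with a
#' warning.
#'
#' @param lengths muscle lengths (mm).
#' @param active_mN active forces (mN).
#' @param alpha significance level of each F-step (default 0.05).
#' @param max_order highest order considered (default 5).
#' @return List with `order`, `coefficients` (b0..bk, ascending powers),
#'   `rss`, and `selection_table` (one row per tested step: rss of both
#'   orders, residual df, F, p).
#' @export
select_polynomial_order <- function(lengths, active_mN, alpha = 0.05,
                                    max_order = 5L) {
  n <- length(lengths)
  if (n != length(active_mN))
    stop_myomech("one active force per length required")
  if (n < 4L)
    stop_myomech("order selection needs at least 4 points (order 2 + 1 df)")
  cap <- min(max_order, n - 2L)
  if (cap < max_order)
    warning(sprintf(
      "only %d points: polynomial search capped at order %d", n, cap),
      call. = FALSE)

  fits <- vector("list", cap)
  for (k in 2:cap) {
    fits[[k]] <- fit_poly_order(lengths, active_mN, k)
    if (is.null(fits[[k]]))
      warning(sprintf("order-%d fit is rank deficient; skipped", k),
              call. = FALSE)
  }
  tss <- sum((active_mN - mean(active_mN))^2)
  tol0 <- 1e-12 * max(tss, .Machine$double.eps)

  tab <- NULL
  selected <- NULL
  k <- 2L
  while (k < cap) {
    k2 <- k + 1L
    while (k2 <= cap && is.null(fits[[k2]])) k2 <- k2 + 1L
    if (is.null(fits[[k]]) || k2 > cap) break
    r1 <- fits[[k]]$rss; r2 <- fits[[k2]]$rss
    extra_df <- k2 - k
    if (r2 < tol0) {
      # (near-)exact higher fit: significant only if the lower one is worse
      Fv <- if (r1 - r2 > tol0) Inf else 0
      p <- if (is.infinite(Fv)) 0 else 1
    } else {
      Fv <- ((r1 - r2) / extra_df) / (r2 / fits[[k2]]$df)
      p <- stats::pf(Fv, extra_df, fits[[k2]]$df, lower.tail = FALSE)
    }
    tab <- rbind(tab, data.frame(order_low = k, order_high = k2,
                                 rss_low = r1, rss_high = r2,
                                 df_high = fits[[k2]]$df, F = Fv, p = p))
    if (p >= alpha) { selected <- k; break }
    k <- k2
  }
  if (is.null(selected)) selected <- k  # every step significant, or capped
  if (is.null(fits[[selected]]))
    stop_myomech("no estimable polynomial fit at order %d", selected)
  list(order = selected,
       coefficients = fits[[selected]]$coefficients,
       rss = fits[[selected]]$rss,
       selection_table = tab)
}

#' Optimum of the fitted active curve
#'
#' The optimum length is the argmax of the fitted polynomial restricted to
#' the measured length range, located from the real stationary points of
#' the polynomial (roots of its derivative) compared against the range
#' endpoints, with a dense 1e-3 mm grid as a safety net. A maximum attained
#' at a range boundary is flagged: the true optimum may lie outside the
#' measured range.
#'
#' @param coefs polynomial coefficients b0..bn, ascending powers.
#' @param length_range length-2 vector, the measured length range (mm).
#' @return List `L_mao` (mm), `F_mao` (mN), `boundary` (logical flag).
#' @examples
#' extract_optimum(c(300 - 225, 30, -1), c(11, 16)) # 300 - (L - 15)^2
#' @export
extract_optimum <- function(coefs, length_range) {
  lo <- length_range[1]; hi <- length_range[2]
  dcf <- poly_deriv_coefs(coefs)
  cand <- c(lo, hi)
  if (any(dcf != 0)) {
    rts <- polyroot(dcf)
    re <- Re(rts)[abs(Im(rts)) < 1e-8 * (1 + abs(Re(rts)))]
    cand <- c(cand, re[re > lo & re < hi])
  }
  vals <- poly_eval(coefs, cand)
  if (!all(is.finite(vals))) {  # fallback: dense grid
    cand <- seq(lo, hi, by = 1e-3)
    vals <- poly_eval(coefs, cand)
  }
  i <- which.max(vals)
  L_mao <- cand[i]
  boundary <- abs(L_mao - lo) < 1e-9 || abs(L_mao - hi) < 1e-9
  list(L_mao = L_mao, F_mao = vals[i], boundary = boundary)
}

#' Active slack length from the fitted curve
#'
#' The active slack length is the x-intercept of the fitted active
#' polynomial: the largest real root strictly below the optimum length. The
#' search window extends below the lowest measured length by
#' `extrapolate_frac` of the measured span (uncontrolled polynomial
#' extrapolation further down produces spurious roots). Roots are isolated
#' from the polynomial's real roots and sign changes on a 1e-3 mm grid and
#' polished by bisection to 1e-6 mm.
#'
#' @param coefs polynomial coefficients b0..bn, ascending powers.
#' @param L_mao optimum length (mm) from [extract_optimum()].
#' @param length_range measured length range (mm).
#' @param extrapolate_frac fraction of the measured span the search may
#'   extend below the lowest measured length (default 0.25).
#' @return Slack length `L_mas` (mm).
#' @export
extract_active_slack <- function(coefs, L_mao, length_range,
                                 extrapolate_frac = 0.25) {
  span <- diff(range(length_range))
  lo <- length_range[1] - extrapolate_frac * span
  hi <- L_mao
  f <- function(x) poly_eval(coefs, x)

  rts <- polyroot(coefs)
  re <- Re(rts)[abs(Im(rts)) < 1e-6 * (1 + abs(Re(rts)))]
  re <- re[re >= lo & re < hi - 1e-9]
  grid <- seq(lo, hi, length.out = max(64L, ceiling(span / 1e-3)))
  sgn <- sign(f(grid))
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(cross)) {
    i <- max(cross)
    re <- c(re, stats::uniroot(f, c(grid[i], grid[i + 1]),
                               tol = 1e-6)$root)
  }
  if (!length(re)) {
    stop_myomech(paste("slack not bracketed: fitted active force stays",
                       "positive down to %.3f mm (lowest value %.3g mN)"),
                 lo, min(f(grid)))
  }
  L_mas <- max(re)
  # polish polynomial roots by bisection where a bracket exists
  eps <- 1e-3 * span
  a <- max(lo, L_mas - eps); b <- min(hi, L_mas + eps)
  if (f(a) * f(b) < 0)
    L_mas <- stats::uniroot(f, c(a, b), tol = 1e-6)$root
  L_mas
}

#' Fit a complete active/passive length-force relationship
#'
#' Runs the full decomposition on one length series: passive-curve fit,
#' per-length active forces, F-test polynomial order selection, optimum
#' extraction, and active slack extraction. This is the one-call interface
#' the pipeline uses; the individual stages are exported separately.
#'
#' @param points a [length_force_points()] table (at least 6 lengths
#'   recommended; 4 minimum).
#' @param passive_form passed to [fit_passive()].
#' @param subtract `"measured"` or `"fitted"` passive, see
#'   [active_forces()].
#' @param alpha F-test level for order selection.
#' @param max_order highest polynomial order considered.
#' @param extrapolate_frac slack search extension, see
#'   [extract_active_slack()].
#' @return A `length_force_fit` list: `passive_fit`, `active` (per-length
#'   table), `order`, `coefficients`, `selection_table`, `L_mao`, `F_mao`,
#'   `boundary_optimum`, `L_mas`, `length_range_mm` (L_mao - L_mas),
#'   `F_mao_measured` (largest measured active force), `length_type`,
#'   and collected `warnings`.
#' @examples
#' gt <- ground_truth(noise_sd = 0)
#' s <- simulate_length_series(gt, seq(11, 16, 0.5), seed = 1)
#' pts <- length_force_points(s$muscle_length_mm, s$total_force_mN,
#'                            s$passive_force_mN)
#' fit <- fit_length_force(pts)
#' c(fit$L_mao, fit$F_mao, fit$L_mas)
#' @export
fit_length_force <- function(points,
                             passive_form = c("exp-linear-plus-offset",
                                              "exp-quadratic"),
                             subtract = c("measured", "fitted"),
                             alpha = 0.05, max_order = 5L,
                             extrapolate_frac = 0.25) {
  passive_form <- match.arg(passive_form)
  subtract <- match.arg(subtract)
  warn <- character()
  withCallingHandlers({
    pfit <- if (subtract == "measured") {
      # the active decomposition does not depend on the passive curve here,
      # so a failed descriptive fit degrades to a warning, not an error
      tryCatch(fit_passive(points$muscle_length_mm,
                           points$passive_force_mN, form = passive_form),
               error = function(e) {
                 warning(conditionMessage(e), call. = FALSE)
                 NULL
               })
    } else {
      fit_passive(points$muscle_length_mm, points$passive_force_mN,
                  form = passive_form)
    }
    act <- active_forces(points, passive = subtract, passive_fit = pfit)
    sel <- select_polynomial_order(act$muscle_length_mm, act$active_force_mN,
                                   alpha = alpha, max_order = max_order)
    rng <- range(points$muscle_length_mm)
    opt <- extract_optimum(sel$coefficients, rng)
    if (opt$boundary)
      warning("boundary optimum: maximum at edge of measured range",
              call. = FALSE)
    L_mas <- extract_active_slack(sel$coefficients, opt$L_mao, rng,
                                  extrapolate_frac = extrapolate_frac)
  }, warning = function(w) {
    warn <<- c(warn, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  structure(list(
    passive_fit = pfit,
    active = act,
    order = sel$order,
    coefficients = sel$coefficients,
    selection_table = sel$selection_table,
    L_mao = opt$L_mao, F_mao = opt$F_mao,
    boundary_optimum = opt$boundary,
    L_mas = L_mas,
    length_range_mm = opt$L_mao - L_mas,
    F_mao_measured = max(act$active_force_mN),
    length_type = attr(points, "length_type"),
    warnings = warn
  ), class = "length_force_fit")
}

#' @export
print.length_force_fit <- function(x, ...) {
  cat(sprintf("Length-force fit (order %d polynomial)\n", x$order))
  cat(sprintf("  L_mao %.3f mm, F_mao %.1f mN%s\n", x$L_mao, x$F_mao,
              if (x$boundary_optimum) " [boundary optimum]" else ""))
  cat(sprintf("  L_mas %.3f mm, active range %.3f mm\n", x$L_mas,
              x$length_range_mm))
  invisible(x)
}

#' Normalized length-force variables
#'
#' Dimensionless and mass/area-normalized versions of the fitted
#' length-force variables: optimum and slack length over tibia length,
#' active length range over tibia length, optimum force per body mass and
#' per physiological cross-sectional area (specific force). Values are
#' returned at full precision; rounding belongs to report writing.
#'
#' @param fit a [fit_length_force()] result, or a named list with `L_mao`,
#'   `L_mas`, `F_mao`.
#' @param tibia_mm tibia length (mm), required and positive.
#' @param body_mass_g body mass (g), optional.
#' @param pcsa_mm2 physiological cross-sectional area (mm^2), optional.
#' @return List: `L_mao_over_Ltibia`, `L_mas_over_Ltibia`,
#'   `range_over_Ltibia`, and (when the denominators are given)
#'   `F_mao_over_BM_mN_per_g`, `F_mao_over_PCSA_mN_per_mm2`.
#' @examples
#' normalize_length_force(list(L_mao = 15.2, L_mas = 11.1, F_mao = 294),
#'                        tibia_mm = 18.89)
#' @export
normalize_length_force <- function(fit, tibia_mm, body_mass_g = NULL,
                                   pcsa_mm2 = NULL) {
  check_number(tibia_mm, "tibia_mm", lower = 0, allow_equal = FALSE)
  out <- list(
    L_mao_over_Ltibia = fit$L_mao / tibia_mm,
    L_mas_over_Ltibia = fit$L_mas / tibia_mm,
    range_over_Ltibia = (fit$L_mao - fit$L_mas) / tibia_mm
  )
  if (!is.null(body_mass_g)) {
    check_number(body_mass_g, "body_mass_g", lower = 0, allow_equal = FALSE)
    out$F_mao_over_BM_mN_per_g <- fit$F_mao / body_mass_g
  }
  if (!is.null(pcsa_mm2)) {
    check_number(pcsa_mm2, "pcsa_mm2", lower = 0, allow_equal = FALSE)
    out$F_mao_over_PCSA_mN_per_mm2 <- fit$F_mao / pcsa_mm2
  }
  out
}
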