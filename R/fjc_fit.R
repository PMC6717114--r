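#' Fit the FJC model to a stretch segment of a force curve
#'
#' Fits tether extension (piezo displacement minus cantilever deflection,
#' `x = z - F/kc`) against force with the FJC force-extension relation,
#' estimating the contour length `Lc` and Kuhn length `Lk` by
#' Levenberg-Marquardt least squares. The residual is reported as a
#' force-equivalent RMS: extension residuals divided by the local slope of
#' the total series compliance `dz/dF = 1/kc + dL/dF`, which maps them
#' back onto the force axis where the measurement noise lives.
#'
#' @param curve a `force_curve`.
#' @param segment integer indices of the stretch segment (>= 20 points
#'   with force above the noise floor).
#' @param start optional list with starting values `Lc`, `Lk`.
#' @return list with `fjc` (an [fjc_params]), `residual` (pN RMS) and
#'   `n_points`; or `NULL` (fit-rejected) when the optimiser fails or
#'   returns unphysical parameters (Lk > 5 nm or Lc > 500 nm).
#' @export
fit_fjc <- function(curve, segment, start = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  segment <- segment[curve$force[segment] > 0]
  if (length(segment) < 20) return(NULL)
  F <- curve$force[segment]
  x <- curve$piezo[segment] - F / curve$kc
  kT <- kBT(curve$temperature)
  if (is.null(start)) {
    start <- list(Lc = max(max(x) * 1.05, 1), Lk = 0.7)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      x ~ Lc * (1 / tanh(F * Lk / kT) - kT / (F * Lk)),
      data = list(x = x, F = F, kT = kT),
      start = start,
      lower = c(Lc = 0.5, Lk = 0.05),
      upper = c(Lc = 1000, Lk = 10),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  co <- stats::coef(fit)
  if (!all(is.finite(co)) || co["Lk"] > 5 || co["Lc"] > 500) return(NULL)
  p <- fjc_params(unname(co["Lc"]), unname(co["Lk"]))
  xr <- x - fjc_extension(F, p, curve$temperature)
  dzdF <- 1 / curve$kc + fjc_extension_deriv(F, p, curve$temperature)
  list(fjc = p, residual = sqrt(mean((xr / dzdF)^2)), n_points = length(F))
}

#' Default criteria for specific-event classification
#'
#' The signature of a specific single-molecule event is the stretching of
#' the PEG tether: an FJC fit that converges with a force-equivalent
#' residual below `max_residual`, a fitted contour length inside
#' `lc_window` (default 55 +/- 18 nm, i.e. +/- 3 sigma of the measured
#' 55 +/- 6 nm tether distribution), followed by a rupture back to
#' baseline.
#'
#' @param lc_window numeric length-2, accepted contour-length window (nm).
#' @param max_residual maximum force-equivalent fit residual (pN); `NULL`
#'   adapts to 4x the estimated per-sample force noise (floor 8 pN).
#' @param min_peak_force minimum peak force (pN) for a rupture candidate.
#' @param min_points minimum points in the stretch segment.
#' @param smooth_width running-median width for peak detection (odd).
#' @return list of criteria, class `classify_criteria`.
#' @export
classify_criteria <- function(lc_window = c(37, 73),
                              max_residual = NULL,
                              min_peak_force = 30,
                              min_points = 20,
                              smooth_width = 5) {
  stopifnot(length(lc_window) == 2, lc_window[1] < lc_window[2],
            min_peak_force > 0, min_points >= 3,
            smooth_width %% 2 == 1)
  structure(list(lc_window = lc_window, max_residual = max_residual,
                 min_peak_force = min_peak_force, min_points = min_points,
                 smooth_width = smooth_width),
            class = "classify_criteria")
}

# Locate the last rupture candidate: the smoothed force peak that is
# followed by a return to baseline. Returns NULL when no peak qualifies.
.find_rupture <- function(curve, criteria) {
  f <- curve$force
  n <- length(f)
  if (n < criteria$min_points + 5) return(NULL)
  fs <- stats::runmed(f, criteria$smooth_width)
  noise <- stats::mad(diff(f)) / sqrt(2)
  floor_f <- max(3 * noise, 10)
  peak_min <- max(criteria$min_peak_force, 5 * noise)
  p <- which.max(fs)
  if (fs[p] < peak_min) return(NULL)
  after <- fs[p:n]
  if (min(after) > floor_f) return(NULL)        # never returns to baseline
  # drop must be sharp: reach half the peak within 10 samples
  drop_win <- after[seq_len(min(10, length(after)))]
  if (min(drop_win) > 0.5 * fs[p]) return(NULL)
  # extend the segment end to the last raw pre-drop sample (the smoothed
  # peak sits a couple of samples early because its window straddles the
  # drop)
  post <- which(f[(p + 1):n] < 0.5 * fs[p])
  p_end <- if (length(post) > 0) p + post[1] - 1 else p
  # contiguous stretch segment ending at the rupture
  below <- which(fs[1:p] < floor_f)
  seg_start <- if (length(below) == 0) 1 else max(below) + 1
  if (seg_start >= p_end) return(NULL)
  list(peak = p_end, segment = seg_start:p_end, noise = noise)
}

#' Classify a force curve as specific, nonspecific, or no-event
#'
#' A curve is `specific` iff a rupture candidate exists, the FJC fit of
#' the stretch segment converges with residual below threshold, and the
#' fitted contour length falls inside the expected tether window;
#' `nonspecific` when a rupture exists but the tether signature fails;
#' `none` when no rupture is found.
#'
#' @param curve a `force_curve`.
#' @param criteria a [classify_criteria] object.
#' @return label character: `"specific"`, `"nonspecific"` or `"none"`.
#'   The full analysis (fit, rupture event) is available from
#'   [analyze_curve].
#' @export
classify_curve <- function(curve, criteria = classify_criteria()) {
  analyze_curve(curve, criteria)$label
}

#' Full per-curve analysis: classification, FJC fit, rupture event
#'
#' @inheritParams classify_curve
#' @return list with `label`, `fjc` (fit or NULL), `residual`,
#'   `event` (from [extract_rupture], or NULL).
#' @export
analyze_curve <- function(curve, criteria = classify_criteria()) {
  stopifnot(inherits(curve, "force_curve"),
            inherits(criteria, "classify_criteria"))
  cand <- .find_rupture(curve, criteria)
  if (is.null(cand)) {
    return(list(label = "none", fjc = NULL, residual = NA_real_,
                event = NULL))
  }
  if (length(cand$segment) < criteria$min_points) {
    return(list(label = "nonspecific", fjc = NULL, residual = NA_real_,
                event = NULL))
  }
  fit <- fit_fjc(curve, cand$segment)
  if (is.null(fit)) {
    return(list(label = "nonspecific", fjc = NULL, residual = NA_real_,
                event = NULL))
  }
  max_res <- criteria$max_residual
  if (is.null(max_res)) max_res <- max(4 * cand$noise, 8)
  ok_lc <- fit$fjc$Lc >= criteria$lc_window[1] &&
    fit$fjc$Lc <= criteria$lc_window[2]
  if (!ok_lc || fit$residual > max_res) {
    return(list(label = "nonspecific", fjc = fit$fjc,
                residual = fit$residual, event = NULL))
  }
  ev <- extract_rupture(curve, fit$fjc, segment = cand$segment,
                        smooth_width = criteria$smooth_width)
  if (is.null(ev)) {
    return(list(label = "nonspecific", fjc = fit$fjc,
                residual = fit$residual, event = NULL))
  }
  ev$fit_residual <- fit$residual
  list(label = "specific", fjc = fit$fjc, residual = fit$residual,
       event = ev)
}

#' Extract the rupture event from a specific force curve
#'
#' The unbinding force `F_ub` is the maximum of the median-filtered force
#' within the fitted stretch segment immediately preceding the detachment
#' drop; the per-event loading rate is the tether-corrected rate
#' ([loading_rate]) evaluated at `F_ub`.
#'
#' @param curve a `force_curve`.
#' @param fjc the fitted [fjc_params] of the stretch.
#' @param segment indices of the stretch segment; `NULL` re-detects it.
#' @param smooth_width running-median width (odd).
#' @return list (class `rupture_event`) with `F_ub` (pN), `vF` (pN/s),
#'   `fjc`, `velocity`, `rupture_index`; or `NULL` when no drop is found.
#' @export
extract_rupture <- function(curve, fjc, segment = NULL, smooth_width = 5) {
  stopifnot(inherits(curve, "force_curve"), inherits(fjc, "fjc_params"))
  if (is.null(segment)) {
    cand <- .find_rupture(curve, classify_criteria(smooth_width = smooth_width))
    if (is.null(cand)) return(NULL)
    segment <- cand$segment
  }
  # filter restricted to the stretch segment so post-rupture baseline
  # samples cannot drag the peak estimate down; runmed's shrinking end
  # windows keep the last pre-drop point nearly raw
  k <- min(smooth_width, length(segment) - (1 - length(segment) %% 2))
  fs <- stats::runmed(curve$force[segment], max(k, 1))
  F_ub <- max(fs)
  if (!is.finite(F_ub) || F_ub <= 0) return(NULL)
  structure(list(F_ub = F_ub,
                 vF = loading_rate(F_ub, fjc, curve$kc, curve$velocity,
                                   curve$temperature),
                 fjc = fjc, velocity = curve$velocity,
                 rupture_index = segment[which.max(fs)],
                 fit_residual = NA_real_),
            class = "rupture_event")
}

#' Analyze every curve in a set
#'
#' Runs [analyze_curve] over a `force_curve_set` and tabulates the result.
#'
#' @param curves a `force_curve_set` (or list of `force_curve`).
#' @param criteria a [classify_criteria].
#' @return data.frame with one row per curve: `curve_id`, `label`,
#'   `velocity`, `Lc`, `Lk`, `residual`, `F_ub`, `vF`, and (when the set
#'   carries ground truth) `true_label`.
#' @export
analyze_curves <- function(curves, criteria = classify_criteria()) {
  res <- lapply(curves, function(ci) {
    a <- analyze_curve(ci, criteria)
    data.frame(
      curve_id = ci$id,
      label = a$label,
      velocity = ci$velocity,
      Lc = if (!is.null(a$fjc)) a$fjc$Lc else NA_real_,
      Lk = if (!is.null(a$fjc)) a$fjc$Lk else NA_real_,
      residual = a$residual,
      F_ub = if (!is.null(a$event)) a$event$F_ub else NA_real_,
      vF = if (!is.null(a$event)) a$event$vF else NA_real_,
      true_label = if (!is.null(ci$truth)) ci$truth$label else NA_character_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
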