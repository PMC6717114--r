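#' Most-probable force and loading rate for one velocity
#'
#' Fits a single Gaussian to the histogram of unbinding forces and takes
#' its mean as the most probable force `F_mp`; the most probable loading
#' rate `LR_mp` is the Gaussian peak of the log loading-rate histogram
#' (loading rates are log-normally spread because force enters the
#' compliance correction exponentially).
#'
#' @param F_ub numeric vector of per-event unbinding forces (pN).
#' @param vF numeric vector of per-event loading rates (pN/s).
#' @param velocity retraction velocity of this group (nm/s), metadata.
#' @param bin_width histogram bin width for forces; `NULL` for
#'   Freedman-Diaconis.
#' @param min_events minimum events required (default 20).
#' @return An object of class `dfs_point`: list with `velocity`, `F_mp`,
#'   `F_sigma`, `LR_mp`, `n_events`, `method`.
#' @export
most_probable_force <- function(F_ub, vF, velocity = NA_real_,
                                bin_width = NULL, min_events = 20) {
  ok <- is.finite(F_ub) & is.finite(vF) & F_ub > 0 & vF > 0
  F_ub <- F_ub[ok]; vF <- vF[ok]
  if (length(F_ub) < min_events) {
    stop(sprintf("most_probable_force: %d events < required %d",
                 length(F_ub), min_events))
  }
  # rupture-force distributions are left-skewed; a local Gaussian fit
  # (finer-than-FD bins, window of +/-0.75 SD about the mode bin) tracks
  # the analytic most-probable force where a full-range fit is dragged
  # toward the skewed tail
  if (is.null(bin_width)) {
    bin_width <- 0.6 * 2 * stats::IQR(F_ub) / length(F_ub)^(1 / 3)
  }
  pf <- gauss_peak(F_ub, bin_width = bin_width,
                   window = 0.75 * stats::sd(F_ub))
  pl <- gauss_peak(log(vF), window = stats::sd(log(vF)))
  structure(list(velocity = velocity,
                 F_mp = pf$mu, F_sigma = pf$sigma,
                 LR_mp = exp(pl$mu), n_events = length(F_ub),
                 method = pf$method),
            class = "dfs_point")
}

#' Aggregate rupture events into per-velocity DFS points
#'
#' @param events data.frame from [analyze_curves] (uses rows with
#'   `label == "specific"`).
#' @param bin_width force histogram bin width; `NULL` for
#'   Freedman-Diaconis.
#' @param min_events minimum events per velocity; velocities with fewer
#'   are dropped with a warning.
#' @return data.frame with columns `velocity`, `F_mp`, `F_sigma`,
#'   `LR_mp`, `n_events`.
#' @export
dfs_points <- function(events, bin_width = NULL, min_events = 20) {
  ev <- events[events$label == "specific" & is.finite(events$F_ub), ]
  out <- lapply(split(ev, ev$velocity), function(g) {
    if (nrow(g) < min_events) {
      warning(sprintf("velocity %g nm/s: only %d events, skipped",
                      g$velocity[1], nrow(g)))
      return(NULL)
    }
    p <- most_probable_force(g$F_ub, g$vF, g$velocity[1],
                             bin_width = bin_width,
                             min_events = min_events)
    data.frame(velocity = p$velocity, F_mp = p$F_mp, F_sigma = p$F_sigma,
               LR_mp = p$LR_mp, n_events = p$n_events)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out[order(out$velocity), , drop = FALSE]
}

#' Bell-Evans regression of most-probable force on log loading rate
#'
#' Fits `F_mp = (kBT/x_beta) * ln(LR_mp * x_beta / (koff0 * kBT))`, which
#' is linear in `ln(LR_mp)`: the slope `a = kBT/x_beta` gives the distance
#' to the transition state and the intercept `b = a*ln(x_beta/(koff0*kBT))`
#' gives the intrinsic off-rate `koff0 = (x_beta/kBT) * exp(-b/a)`.
#' Standard errors propagate from the regression covariance by the delta
#' method.
#'
#' @param points data.frame from [dfs_points] (needs >= 3 rows spanning
#'   at least one decade of `LR_mp`).
#' @param T temperature in kelvin.
#' @param weighted logical; if TRUE, weight points by `1/F_sigma^2`.
#' @return A [bell_evans_params] object with extra fields `se` (list with
#'   `koff0`, `x_beta`), `fit` (the `lm`), `r_squared`.
#' @export
fit_bell_evans <- function(points, T = 298, weighted = FALSE) {
  stopifnot(is.data.frame(points), nrow(points) >= 3)
  if (diff(range(log10(points$LR_mp))) < 1) {
    stop("fit_bell_evans: loading rates must span at least one decade")
  }
  kT <- kBT(T)
  w <- if (weighted) 1 / points$F_sigma^2 else NULL
  fit <- stats::lm(F_mp ~ log(LR_mp), data = points, weights = w)
  a <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  if (a <= 0) {
    stop("fit_bell_evans: non-positive slope; Bell-Evans model violated")
  }
  x_beta <- kT / a
  koff0 <- (x_beta / kT) * exp(-b / a)
  # vcov warns through summary.lm on numerically perfect fits
  V <- suppressWarnings(stats::vcov(fit))
  se_a <- sqrt(V[2, 2]); se_b <- sqrt(V[1, 1]); cov_ab <- V[1, 2]
  # delta method: x_beta = kT/a; koff0 = exp(-b/a)/a
  dxb_da <- -kT / a^2
  se_xb <- abs(dxb_da) * se_a
  dk_da <- koff0 * (b / a^2 - 1 / a)
  dk_db <- koff0 * (-1 / a)
  se_k <- sqrt(dk_da^2 * se_a^2 + dk_db^2 * se_b^2 +
                 2 * dk_da * dk_db * cov_ab)
  out <- bell_evans_params(koff0, x_beta)
  out$se <- list(koff0 = se_k, x_beta = se_xb)
  out$fit <- fit
  # summary.lm warns on numerically perfect fits; the R^2 is still valid
  out$r_squared <- suppressWarnings(summary(fit)$r.squared)
  out
}

#' Full dynamic force spectroscopy pipeline
#'
#' Classify curves, extract specific rupture events with FJC fits and
#' per-event loading rates, aggregate per-velocity most-probable forces,
#' and regress against log loading rate with the Bell-Evans model.
#'
#' @param curves a `force_curve_set`.
#' @param criteria a [classify_criteria].
#' @param T temperature in kelvin (defaults to the curves' temperature).
#' @param min_events minimum events per velocity.
#' @param weighted logical, passed to [fit_bell_evans].
#' @return list with `events` (per-curve table), `points` (per-velocity
#'   table), `bell` (the fitted [bell_evans_params]), and
#'   `specific_fraction` (classified prevalence).
#' @export
dfs_analysis <- function(curves, criteria = classify_criteria(), T = NULL,
                         min_events = 20, weighted = FALSE) {
  if (is.null(T)) T <- curves[[1]]$temperature
  events <- analyze_curves(curves, criteria)
  points <- dfs_points(events, min_events = min_events)
  bell <- fit_bell_evans(points, T = T, weighted = weighted)
  list(events = events, points = points, bell = bell,
       specific_fraction = mean(events$label == "specific"))
}
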