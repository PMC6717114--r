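# Shared numeric helpers.

# Freedman-Diaconis bin width with sane fallbacks
.fd_binwidth <- function(x) {
  iqr <- stats::IQR(x)
  if (iqr <= 0) iqr <- stats::sd(x)
  if (!is.finite(iqr) || iqr <= 0) return(NULL)
  2 * iqr / length(x)^(1 / 3)
}

#' Gaussian peak of a histogram
#'
#' Histograms a sample at a given bin width (Freedman-Diaconis by default)
#' and fits a single Gaussian `A*exp(-(x-mu)^2/(2*sigma^2))` to the bin
#' counts by least squares. This is the "peak-maxima" estimator used for
#' rupture-force, loading-rate and FRET-efficiency distributions. On fit
#' failure it falls back to the mode bin centre with a warning.
#'
#' @param x numeric sample (length >= 5).
#' @param bin_width histogram bin width; `NULL` for Freedman-Diaconis.
#' @param window if non-NULL, half-width around the mode bin outside of
#'   which bins are excluded from the fit (robustifies against secondary
#'   modes).
#' @return list with `mu`, `sigma`, `method` ("gaussian" or "mode"),
#'   `n`, `bin_width`, and the histogram (`mids`, `counts`).
#' @export
gauss_peak <- function(x, bin_width = NULL, window = NULL) {
  x <- x[is.finite(x)]
  if (length(x) < 5) stop("gauss_peak needs at least 5 finite values")
  if (is.null(bin_width)) bin_width <- .fd_binwidth(x)
  if (is.null(bin_width) || bin_width <= 0 ||
      diff(range(x)) < .Machine$double.eps) {
    # degenerate (all-identical) sample: the peak is the common value
    return(list(mu = x[1], sigma = 0, method = "degenerate", n = length(x),
                bin_width = bin_width, mids = x[1], counts = length(x)))
  }
  breaks <- seq(min(x) - bin_width, max(x) + bin_width, by = bin_width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  mids <- h$mids
  counts <- h$counts
  mu0 <- mids[which.max(counts)]
  keep <- rep(TRUE, length(mids))
  if (!is.null(window)) keep <- abs(mids - mu0) <= window
  s0 <- max(stats::sd(x[abs(x - mu0) <= 3 * stats::sd(x)]), bin_width / 2)
  try_fit <- function(sel) tryCatch(
    stats::nls(counts ~ A * exp(-(mids - mu)^2 / (2 * s^2)),
               data = list(counts = counts[sel], mids = mids[sel]),
               start = list(A = max(counts), mu = mu0, s = s0),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  fit <- try_fit(keep)
  if (is.null(fit) && !all(keep)) fit <- try_fit(rep(TRUE, length(mids)))
  if (is.null(fit) || !is.finite(stats::coef(fit)[["mu"]])) {
    warning("Gaussian peak fit failed; falling back to histogram mode")
    return(list(mu = mu0, sigma = stats::sd(x), method = "mode",
                n = length(x), bin_width = bin_width,
                mids = mids, counts = counts))
  }
  co <- stats::coef(fit)
  list(mu = unname(co["mu"]), sigma = abs(unname(co["s"])),
       method = "gaussian", n = length(x), bin_width = bin_width,
       mids = mids, counts = counts)
}

# Local maxima of a (lightly smoothed) count vector: positions where the
# count exceeds both neighbours and a fraction of the global maximum.
.histogram_modes <- function(counts, min_frac = 0.5) {
  if (length(counts) < 3) return(which.max(counts))
  sm <- as.numeric(stats::filter(counts, rep(1 / 3, 3), sides = 2))
  sm[is.na(sm)] <- counts[is.na(sm)]
  idx <- which(diff(sign(diff(sm))) == -2) + 1
  idx <- idx[sm[idx] >= min_frac * max(sm)]
  if (length(idx) == 0) idx <- which.max(counts)
  idx
}
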