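#' Background and leakage correction of an smFRET trace
#'
#' Subtracts channel backgrounds and removes donor-to-acceptor spectral
#' leakage: `I_D' = I_D - bg_D`; `I_A' = I_A - bg_A - alpha * I_D'`.
#'
#' @param t a [fret_trace].
#' @param background_donor,background_acceptor channel backgrounds
#'   (counts/frame).
#' @param leakage_alpha leakage fraction in \[0,1).
#' @return the corrected [fret_trace].
#' @export
correct_trace <- function(t, background_donor = 0, background_acceptor = 0,
                          leakage_alpha = 0) {
  stopifnot(inherits(t, "fret_trace"),
            leakage_alpha >= 0, leakage_alpha < 1)
  I_D <- t$I_D - background_donor
  I_A <- t$I_A - background_acceptor - leakage_alpha * I_D
  out <- fret_trace(I_D, I_A, t$trace_id, t$truth)
  out$corrected <- TRUE
  out
}

#' Per-frame FRET efficiency of a corrected trace
#'
#' `E = I_A / (I_D + I_A)` per frame. Frames whose total corrected
#' intensity is not positive are returned as `NA` (flagged invalid).
#'
#' @param t a corrected [fret_trace].
#' @return numeric vector of per-frame efficiencies (NA where invalid).
#'   Raises a condition of class `fret_empty_trace` when every frame is
#'   invalid.
#' @export
efficiency_trace <- function(t) {
  stopifnot(inherits(t, "fret_trace"))
  tot <- t$I_D + t$I_A
  E <- ifelse(tot > 0, t$I_A / tot, NA_real_)
  if (all(is.na(E))) {
    stop(structure(class = c("fret_empty_trace", "error", "condition"),
                   list(message = paste0("trace ", t$trace_id,
                                         ": no valid frames"),
                        call = sys.call())))
  }
  E
}

# First sustained acceptor-bleach frame: >= `run` consecutive frames with
# acceptor below `frac` of the median acceptor intensity over all earlier
# frames. Returns NA when no bleach is found.
.detect_bleach <- function(I_A, frac = 0.3, run = 3) {
  n <- length(I_A)
  if (n < run + 2) return(NA_integer_)
  sm <- stats::runmed(I_A, min(run, n - (1 - n %% 2)))
  for (i in 3:(n - run + 1)) {
    med_pre <- stats::median(I_A[1:(i - 1)])
    if (med_pre <= 0) next
    if (all(sm[i:(i + run - 1)] < frac * med_pre)) return(i)
  }
  NA_integer_
}

#' Per-trace mean efficiency with acceptor-bleach detection
#'
#' Detects the first acceptor bleach as a sustained (>= 3 frames) drop of
#' the acceptor intensity below 30% of its pre-drop median, then averages
#' the per-frame efficiency over the valid frames before the bleach.
#' Traces with fewer than `min_frames` valid pre-bleach frames are
#' rejected (returned as `NA` with `rejected = TRUE`).
#'
#' @param t a corrected [fret_trace].
#' @param min_frames minimum valid pre-bleach frames (default 5).
#' @param bleach_frac,bleach_run bleach-detection threshold fraction and
#'   run length.
#' @return list with `E_mean`, `bleach_frame` (NA if none), `n_frames`
#'   (valid frames used), `rejected`.
#' @export
trace_efficiency <- function(t, min_frames = 5, bleach_frac = 0.3,
                             bleach_run = 3) {
  stopifnot(inherits(t, "fret_trace"))
  bleach <- .detect_bleach(t$I_A, bleach_frac, bleach_run)
  last <- if (is.na(bleach)) length(t$I_A) else bleach - 1
  if (last < 1) {
    return(list(E_mean = NA_real_, bleach_frame = bleach, n_frames = 0L,
                rejected = TRUE))
  }
  tot <- t$I_D[1:last] + t$I_A[1:last]
  valid <- which(tot > 0)
  if (length(valid) < min_frames) {
    return(list(E_mean = NA_real_, bleach_frame = bleach,
                n_frames = length(valid), rejected = TRUE))
  }
  E <- t$I_A[valid] / tot[valid]
  list(E_mean = mean(E), bleach_frame = bleach,
       n_frames = length(valid), rejected = FALSE)
}

#' Most-probable efficiency from a set of per-trace efficiencies
#'
#' Histograms the per-trace efficiencies and fits a single Gaussian; the
#' fitted mean is the most-probable efficiency `E_mp`. When the histogram
#' has more than one substantial mode a warning is raised and the fit is
#' restricted to a window around the dominant mode.
#'
#' @param efficiencies numeric vector of per-trace efficiencies (>= 30).
#' @param bin_width histogram bin width; `NULL` (default) uses the
#'   Freedman-Diaconis width capped at 0.05 so that narrow synthetic
#'   distributions remain resolvable.
#' @return list with `E_mp`, `E_sigma`, `n`, `bin_width`, `method`,
#'   `multimodal` flag.
#' @export
fit_efficiency_peak <- function(efficiencies, bin_width = NULL) {
  E <- efficiencies[is.finite(efficiencies)]
  if (length(E) < 30) {
    stop("fit_efficiency_peak: need at least 30 trace efficiencies")
  }
  if (any(E < -0.2 | E > 1.2)) {
    warning("efficiencies outside [-0.2, 1.2] dropped")
    E <- E[E >= -0.2 & E <= 1.2]
  }
  if (is.null(bin_width)) {
    fd <- .fd_binwidth(E)
    bin_width <- if (is.null(fd) || fd <= 0) 0.05 else min(fd, 0.05)
  }
  # multimodality screen on the raw histogram
  breaks <- seq(min(E) - bin_width, max(E) + bin_width, by = bin_width)
  h <- graphics::hist(E, breaks = breaks, plot = FALSE)
  modes <- .histogram_modes(h$counts)
  multimodal <- length(modes) > 1 &&
    max(diff(sort(h$mids[modes]))) > 2 * bin_width
  window <- NULL
  if (multimodal) {
    warning("efficiency distribution is multimodal; reporting dominant mode")
    window <- 0.15
  }
  pk <- gauss_peak(E, bin_width = bin_width, window = window)
  E_mp <- min(max(pk$mu, 0), 1)
  list(E_mp = E_mp, E_sigma = pk$sigma, n = pk$n,
       bin_width = bin_width, method = pk$method, multimodal = multimodal)
}

#' Calibrate the Forster radius from a reference efficiency-distance pair
#'
#' Inverse Forster relation: `R0 = d_ref * (E_ref/(1-E_ref))^(1/6)`. The
#' package default calibration uses the wild-type tip-link pair
#' (E = 0.68 at 4.62 nm), giving R0 of about 5.24 nm for the Cy3/Cy5
#' labelling used on the complex.
#'
#' @param E_ref reference efficiency, strictly inside (0,1).
#' @param d_ref donor-acceptor distance at `E_ref`, in nm.
#' @return object of class `fret_calibration` with field `R0` (nm).
#' @export
calibrate_R0 <- function(E_ref = 0.68, d_ref = 4.62) {
  if (!(E_ref > 0 && E_ref < 1)) {
    stop("calibrate_R0: E_ref must be strictly inside (0,1)")
  }
  stopifnot(d_ref > 0)
  structure(list(R0 = d_ref * (E_ref / (1 - E_ref))^(1 / 6),
                 E_ref = E_ref, d_ref = d_ref),
            class = "fret_calibration")
}

#' @export
print.fret_calibration <- function(x, ...) {
  cat(sprintf("Forster calibration: R0 = %.4g nm (from E = %.3g at %.4g nm)\n",
              x$R0, x$E_ref, x$d_ref))
  invisible(x)
}

#' Convert a FRET efficiency to a donor-acceptor distance
#'
#' `d = R0 * ((1-E)/E)^(1/6)`.
#'
#' @param E efficiency, strictly inside (0,1) (vectorised).
#' @param cal a [calibrate_R0] calibration.
#' @return distance in nm.
#' @export
efficiency_to_distance <- function(E, cal = calibrate_R0()) {
  stopifnot(inherits(cal, "fret_calibration"))
  if (any(E <= 0 | E >= 1)) {
    stop("efficiency_to_distance: E must be strictly inside (0,1)")
  }
  cal$R0 * ((1 - E) / E)^(1 / 6)
}

#' Full smFRET pipeline: correct, summarise, fit peak, convert to distance
#'
#' @param traces a `fret_trace_set` (or list of [fret_trace]).
#' @param background_donor,background_acceptor,leakage_alpha correction
#'   parameters (defaults taken from the generating config when the set
#'   carries one).
#' @param cal a [calibrate_R0] calibration for the distance conversion.
#' @param bin_width passed to [fit_efficiency_peak].
#' @return list with `efficiencies` (per-trace table), `peak` (from
#'   [fit_efficiency_peak]), `d_nm` (distance at `E_mp`), `n_rejected`.
#' @export
analyze_fret_traces <- function(traces, background_donor = NULL,
                                background_acceptor = NULL,
                                leakage_alpha = NULL,
                                cal = calibrate_R0(), bin_width = NULL) {
  cfg <- attr(traces, "config")
  if (is.null(background_donor))
    background_donor <- if (!is.null(cfg)) cfg$background_donor else 0
  if (is.null(background_acceptor))
    background_acceptor <- if (!is.null(cfg)) cfg$background_acceptor else 0
  if (is.null(leakage_alpha))
    leakage_alpha <- if (!is.null(cfg)) cfg$leakage_alpha else 0
  rows <- lapply(traces, function(tr) {
    ct <- correct_trace(tr, background_donor, background_acceptor,
                        leakage_alpha)
    s <- trace_efficiency(ct)
    data.frame(trace_id = tr$trace_id, E_mean = s$E_mean,
               bleach_frame = if (is.na(s$bleach_frame)) NA_integer_
                              else s$bleach_frame,
               n_frames = s$n_frames, rejected = s$rejected,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  keep <- !tab$rejected
  peak <- fit_efficiency_peak(tab$E_mean[keep], bin_width = bin_width)
  list(efficiencies = tab, peak = peak,
       d_nm = efficiency_to_distance(peak$E_mp, cal),
       n_rejected = sum(tab$rejected))
}
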