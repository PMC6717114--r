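#' Configuration for the smFRET trace generator
#'
#' Emulates donor/acceptor intensity time traces from a TIRF experiment on
#' surface-immobilised complexes: an ideal split of the total photon
#' budget by the FRET efficiency, donor-to-acceptor spectral leakage,
#' channel backgrounds, Gaussian shot/readout noise, and single-step
#' acceptor photobleaching with a geometric waiting time. A per-trace
#' spread of the true efficiency (`efficiency_sd`) emulates the
#' molecule-to-molecule width of measured efficiency histograms
#' (Gaussian widths of roughly 0.03-0.05).
#'
#' @param n_traces number of traces.
#' @param true_efficiency mean true FRET efficiency in (0,1).
#' @param efficiency_sd per-trace SD of the true efficiency (>= 0);
#'   sampled values are clamped to (0.01, 0.99).
#' @param total_intensity total donor+acceptor counts per frame.
#' @param noise_sd Gaussian noise SD per channel (counts).
#' @param leakage_alpha donor-to-acceptor leakage fraction in \[0,1).
#' @param background_donor,background_acceptor channel backgrounds
#'   (counts/frame).
#' @param bleach_rate per-frame acceptor bleaching probability in \[0,1\].
#' @param n_frames frames per trace.
#' @param seed integer RNG seed.
#' @return An object of class `trace_gen_config`.
#' @export
trace_gen_config <- function(n_traces = 500,
                             true_efficiency = 0.68,
                             efficiency_sd = 0.04,
                             total_intensity = 1000,
                             noise_sd = 50,
                             leakage_alpha = 0.05,
                             background_donor = 100,
                             background_acceptor = 100,
                             bleach_rate = 0.005,
                             n_frames = 200,
                             seed = 1) {
  stopifnot(n_traces >= 0,
            true_efficiency > 0, true_efficiency < 1,
            efficiency_sd >= 0,
            total_intensity > 0, noise_sd >= 0,
            leakage_alpha >= 0, leakage_alpha < 1,
            background_donor >= 0, background_acceptor >= 0,
            bleach_rate >= 0, bleach_rate <= 1,
            n_frames >= 2)
  structure(list(n_traces = n_traces, true_efficiency = true_efficiency,
                 efficiency_sd = efficiency_sd,
                 total_intensity = total_intensity, noise_sd = noise_sd,
                 leakage_alpha = leakage_alpha,
                 background_donor = background_donor,
                 background_acceptor = background_acceptor,
                 bleach_rate = bleach_rate, n_frames = n_frames,
                 seed = as.integer(seed)),
            class = "trace_gen_config")
}

#' Construct an smFRET intensity trace
#'
#' @param I_D donor intensity series (counts).
#' @param I_A acceptor intensity series, same length (>= 2 frames).
#' @param trace_id identifier.
#' @param truth optional ground-truth list.
#' @return object of class `fret_trace`.
#' @export
fret_trace <- function(I_D, I_A, trace_id = "trace", truth = NULL) {
  stopifnot(length(I_D) == length(I_A), length(I_D) >= 2)
  structure(list(trace_id = trace_id, I_D = as.numeric(I_D),
                 I_A = as.numeric(I_A), truth = truth),
            class = "fret_trace")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("FRET trace %s: %d frames\n", x$trace_id, length(x$I_D)))
  invisible(x)
}

#' Generate synthetic smFRET traces with known ground truth
#'
#' Per frame the ideal intensities are
#' `(I_D, I_A) = total_intensity * (1 - E, E)`; leakage adds
#' `alpha * I_D` to the acceptor channel; channel backgrounds and Gaussian
#' noise are added. An acceptor bleach event at a geometric waiting time
#' sends the acceptor to background and the donor to the full photon
#' budget for the remaining frames.
#'
#' @param cfg a [trace_gen_config].
#' @return list (class `fret_trace_set`) of [fret_trace] objects; each
#'   trace's `truth` records its true efficiency and bleach frame, and the
#'   generating config is attached as an attribute.
#' @export
gen_fret_traces <- function(cfg) {
  stopifnot(inherits(cfg, "trace_gen_config"))
  set.seed(cfg$seed)
  traces <- vector("list", cfg$n_traces)
  for (i in seq_len(cfg$n_traces)) {
    E <- cfg$true_efficiency
    if (cfg$efficiency_sd > 0) {
      E <- min(max(stats::rnorm(1, E, cfg$efficiency_sd), 0.01), 0.99)
    }
    nf <- cfg$n_frames
    bleach <- if (cfg$bleach_rate > 0) {
      b <- stats::rgeom(1, cfg$bleach_rate) + 1   # frame index of bleach
      if (b > nf) NA_integer_ else b
    } else NA_integer_
    I_D <- rep(cfg$total_intensity * (1 - E), nf)
    I_A <- rep(cfg$total_intensity * E, nf)
    if (!is.na(bleach)) {
      I_A[bleach:nf] <- 0
      I_D[bleach:nf] <- cfg$total_intensity
    }
    I_A <- I_A + cfg$leakage_alpha * I_D
    I_D <- I_D + cfg$background_donor
    I_A <- I_A + cfg$background_acceptor
    if (cfg$noise_sd > 0) {
      I_D <- I_D + stats::rnorm(nf, 0, cfg$noise_sd)
      I_A <- I_A + stats::rnorm(nf, 0, cfg$noise_sd)
    }
    traces[[i]] <- fret_trace(I_D, I_A, sprintf("trace_%04d", i),
                              truth = list(E = E, bleach_frame = bleach))
  }
  structure(traces, class = "fret_trace_set", config = cfg)
}
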