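#' Configuration for the AFM force-curve generator
#'
#' Describes a synthetic dynamic force spectroscopy experiment: a cantilever
#' of stiffness `kc` retracting at each velocity in `velocities`, pulling a
#' receptor-ligand bond through an FJC tether, with Bell rupture kinetics.
#' Defaults follow the tip-link AFM protocol: six retraction velocities
#' 200-5000 nm/s, kc = 25 pN/nm (instrument range 20-30), two 5 kDa PEG
#' spacers in series (Lc = 55 nm, Lk = 0.7 nm), about 5% of curves showing
#' a specific single-tether stretching event.
#'
#' @param n_curves total number of curves, distributed evenly over
#'   `velocities`.
#' @param specific_fraction probability in \[0,1\] that a curve contains a
#'   specific tether-stretch + rupture event.
#' @param velocities retraction velocities in nm/s (all > 0).
#' @param kc cantilever stiffness in pN/nm.
#' @param tether an [fjc_params] object for the PEG tether.
#' @param bell a [bell_evans_params] object for the bond kinetics.
#' @param temperature kelvin.
#' @param force_noise_sd Gaussian force noise in pN added per sample.
#' @param dt sampling interval in s, or `NULL` to sample each velocity's
#'   ramp at `n_samples` points.
#' @param n_samples samples per curve when `dt` is `NULL`.
#' @param seed integer RNG seed.
#' @return An object of class `curve_gen_config`.
#' @export
curve_gen_config <- function(n_curves = 5625,
                             specific_fraction = 0.05,
                             velocities = c(200, 500, 1000, 2000, 3000, 5000),
                             kc = 25,
                             tether = fjc_params(55, 0.7),
                             bell = bell_evans_params(4.5e-3, 0.18),
                             temperature = 298,
                             force_noise_sd = 5,
                             dt = NULL,
                             n_samples = 2048,
                             seed = 1) {
  stopifnot(n_curves >= 0,
            specific_fraction >= 0, specific_fraction <= 1,
            all(velocities > 0), kc > 0, temperature > 0,
            force_noise_sd >= 0,
            inherits(tether, "fjc_params"),
            inherits(bell, "bell_evans_params"))
  if (!is.null(dt) && dt <= 0) stop("dt must be > 0")
  if (specific_fraction > 0 && length(velocities) == 0) {
    stop("specific_fraction > 0 requires at least one retraction velocity")
  }
  structure(list(n_curves = n_curves, specific_fraction = specific_fraction,
                 velocities = velocities, kc = kc, tether = tether,
                 bell = bell, temperature = temperature,
                 force_noise_sd = force_noise_sd, dt = dt,
                 n_samples = n_samples, seed = as.integer(seed)),
            class = "curve_gen_config")
}

# Force-vs-displacement and cumulative-hazard tables for one velocity.
# z(F) is explicit (tether extension + cantilever deflection in series);
# the rupture hazard along the ramp is koff(F) dt = koff(F) (dz/dF)/v dF,
# accumulated by trapezoid on a fine force grid.
.ramp_tables <- function(cfg, v, n_grid = 4000) {
  kT <- kBT(cfg$temperature)
  # expand force range until survival is negligible (cum hazard > 50)
  Fmax <- 50
  repeat {
    Fg <- seq(1e-3, Fmax, length.out = 512)
    dzdF <- fjc_extension_deriv(Fg, cfg$tether, cfg$temperature) + 1 / cfg$kc
    haz <- bell_off_rate(Fg, cfg$bell, cfg$temperature) * dzdF / v
    H <- cumsum(c(0, diff(Fg) * (haz[-1] + haz[-length(haz)]) / 2))
    if (max(H) > 50 || Fmax > 1e6) break
    Fmax <- Fmax * 2
  }
  Fg <- seq(1e-3, Fmax, length.out = n_grid)
  zg <- fjc_extension(Fg, cfg$tether, cfg$temperature) + Fg / cfg$kc
  dzdF <- fjc_extension_deriv(Fg, cfg$tether, cfg$temperature) + 1 / cfg$kc
  haz <- bell_off_rate(Fg, cfg$bell, cfg$temperature) * dzdF / v
  H <- cumsum(c(0, diff(Fg) * (haz[-1] + haz[-length(haz)]) / 2))
  list(F = Fg, z = zg, H = H)
}

.new_force_curve <- function(time, piezo, force, kc, velocity, temperature,
                             id, truth) {
  structure(list(time = time, piezo = piezo, force = force, kc = kc,
                 velocity = velocity, temperature = temperature,
                 id = id, truth = truth),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("Force curve %s: %d samples, v = %g nm/s, kc = %g pN/nm",
              x$id, length(x$time), x$velocity, x$kc))
  if (!is.null(x$truth)) cat(sprintf(" [truth: %s]", x$truth$label))
  cat("\n")
  invisible(x)
}

#' Convert a force curve to a data frame
#'
#' @param x a `force_curve`.
#' @param ... unused.
#' @return data.frame with columns `time_s`, `piezo_nm`, `force_pN`.
#' @export
as.data.frame.force_curve <- function(x, ...) {
  data.frame(time_s = x$time, piezo_nm = x$piezo, force_pN = x$force)
}

#' Generate synthetic AFM force curves with known ground truth
#'
#' For each specific curve the rupture displacement is drawn from the exact
#' first-passage distribution of the force ramp: with cumulative hazard
#' `H(z) = integral of koff(F(z'))/v dz'`, rupture occurs where `H` first
#' exceeds `-log(u)`, `u` uniform on (0,1). Before rupture the force
#' follows the cantilever-tether force balance ([solve_tether_force]);
#' after rupture it drops to baseline. Non-specific curves are an equal
#' mixture of no-event (baseline noise) and short-range adhesion shapes
#' whose apparent contour lengths (8-30 nm) fall outside the specific
#' tether window. Gaussian force noise is added throughout.
#'
#' @param cfg a [curve_gen_config].
#' @return An object of class `force_curve_set`: a list of `force_curve`
#'   objects with ground-truth labels (`specific`, `nonspecific`, `none`),
#'   true rupture forces, and the generating configuration attached as an
#'   attribute.
#' @export
gen_force_curves <- function(cfg) {
  stopifnot(inherits(cfg, "curve_gen_config"))
  set.seed(cfg$seed)
  n <- cfg$n_curves
  if (n == 0) {
    return(structure(list(), class = "force_curve_set", config = cfg))
  }
  vel <- rep_len(cfg$velocities, n)
  u_lab <- stats::runif(n)
  label <- ifelse(u_lab < cfg$specific_fraction, "specific",
                  ifelse(stats::runif(n) < 0.5, "nonspecific", "none"))

  curves <- vector("list", n)
  for (v in unique(vel)) {
    tab <- .ramp_tables(cfg, v)
    idx <- which(vel == v)
    # common ramp length for this velocity: 99.9% of specific events
    # rupture inside, plus a post-rupture baseline margin
    z999 <- stats::approx(tab$H, tab$z, xout = -log(1e-3), rule = 2, ties = "ordered")$y
    z_total <- z999 + 15
    dt <- if (is.null(cfg$dt)) (z_total / v) / cfg$n_samples else cfg$dt
    tgrid <- seq(0, z_total / v, by = dt)
    zgrid <- v * tgrid
    # baseline force for z below the grid start is effectively 0
    f_of_z <- function(z) {
      f <- stats::approx(tab$z, tab$F, xout = z, rule = 2)$y
      f[z <= min(tab$z)] <- 0
      f
    }
    for (i in idx) {
      lab <- label[i]
      force <- numeric(length(zgrid))
      truth <- list(label = lab, rupture_force = NA_real_,
                    rupture_time = NA_real_, velocity = v)
      if (lab == "specific") {
        Hstar <- stats::rexp(1)
        if (Hstar >= max(tab$H)) Hstar <- max(tab$H) * 0.999
        z_rup <- stats::approx(tab$H, tab$z, xout = Hstar, ties = "ordered")$y
        F_rup <- stats::approx(tab$H, tab$F, xout = Hstar, ties = "ordered")$y
        pre <- zgrid < z_rup
        force[pre] <- f_of_z(zgrid[pre])
        truth$rupture_force <- F_rup
        truth$rupture_time <- z_rup / v
        truth$Lc <- cfg$tether$Lc
        truth$Lk <- cfg$tether$Lk
      } else if (lab == "nonspecific") {
        adh <- fjc_params(stats::runif(1, 8, 30), cfg$tether$Lk)
        F_rup <- stats::runif(1, 30, 150)
        z_rup <- fjc_extension(F_rup, adh, cfg$temperature) + F_rup / cfg$kc
        pre <- zgrid < z_rup
        if (any(pre)) {
          Fa <- seq(1e-3, F_rup + 5, length.out = 400)
          za <- fjc_extension(Fa, adh, cfg$temperature) + Fa / cfg$kc
          fi <- stats::approx(za, Fa, xout = zgrid[pre], rule = 2)$y
          fi[zgrid[pre] <= min(za)] <- 0
          force[pre] <- fi
        }
        truth$rupture_force <- F_rup
        truth$rupture_time <- z_rup / v
        truth$Lc <- adh$Lc
      }
      if (cfg$force_noise_sd > 0) {
        force <- force + stats::rnorm(length(force), 0, cfg$force_noise_sd)
      }
      curves[[i]] <- .new_force_curve(tgrid, zgrid, force, cfg$kc, v,
                                      cfg$temperature,
                                      sprintf("curve_%05d", i), truth)
    }
  }
  structure(curves, class = "force_curve_set", config = cfg)
}

#' @export
print.force_curve_set <- function(x, ...) {
  labs <- vapply(x, function(ci) ci$truth$label, character(1))
  cat(sprintf("Force-curve set: %d curves (%d specific, %d nonspecific, %d none)\n",
              length(x), sum(labs == "specific"), sum(labs == "nonspecific"),
              sum(labs == "none")))
  invisible(x)
}
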