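#' Bell-Evans escape-landscape parameters
#'
#' Intrinsic off-rate `koff0` (s^-1), distance from the bound state to the
#' transition state along the pulling coordinate `x_beta` (nm), and the
#' pulling angle `theta` (rad, default 0: force collinear with the
#' reaction coordinate).
#'
#' @param koff0 intrinsic off-rate in s^-1 (> 0).
#' @param x_beta distance to the transition state in nm (> 0).
#' @param theta pulling angle in radians.
#' @return An object of class `bell_evans_params`.
#' @export
bell_evans_params <- function(koff0, x_beta, theta = 0) {
  stopifnot(koff0 > 0, x_beta > 0, is.numeric(theta))
  structure(list(koff0 = koff0, x_beta = x_beta, theta = theta),
            class = "bell_evans_params")
}

#' @export
print.bell_evans_params <- function(x, ...) {
  cat(sprintf("Bell-Evans: koff0 = %.3g /s, x_beta = %.3g nm, theta = %.3g rad\n",
              x$koff0, x$x_beta, x$theta))
  if (!is.null(x$se)) {
    cat(sprintf("  SE: koff0 %.2g, x_beta %.2g\n", x$se$koff0, x$se$x_beta))
  }
  invisible(x)
}

#' Force-accelerated off-rate (Bell model)
#'
#' `koff(F) = koff0 * exp(F * x_beta * cos(theta) / kBT)`: an external
#' force tilts the escape barrier and accelerates unbinding exponentially.
#'
#' @param F force in pN (vectorised).
#' @param p a [bell_evans_params] object.
#' @param T temperature in kelvin.
#' @return off-rate in s^-1.
#' @export
bell_off_rate <- function(F, p, T = 298) {
  stopifnot(inherits(p, "bell_evans_params"))
  p$koff0 * exp(F * p$x_beta * cos(p$theta) / kBT(T))
}

#' External tilt energy of the escape barrier
#'
#' `E_ext = F * x_beta * cos(theta)` in pN nm: the work done by the applied
#' force over the distance to the transition state. A larger `x_beta`
#' converts the same force into a larger barrier tilt, which is why
#' complexes with longer transition distances dissociate faster under load.
#'
#' @param F force in pN.
#' @param x_beta distance to the transition state in nm.
#' @param theta pulling angle in radians.
#' @return energy in pN nm.
#' @export
tilt_energy <- function(F, x_beta, theta = 0) {
  F * x_beta * cos(theta)
}

#' Most probable rupture force at a given loading rate (Bell-Evans)
#'
#' `F_mp(vF) = (kBT/x_beta) * ln(vF * x_beta / (koff0 * kBT))`, the peak of
#' the rupture-force distribution under a constant force ramp.
#'
#' @param vF loading rate in pN/s (vectorised).
#' @param p a [bell_evans_params] object (theta enters through the
#'   effective transition distance `x_beta*cos(theta)`).
#' @param T temperature in kelvin.
#' @return most probable rupture force in pN.
#' @export
bell_evans_force <- function(vF, p, T = 298) {
  stopifnot(inherits(p, "bell_evans_params"))
  xb <- p$x_beta * cos(p$theta)
  (kBT(T) / xb) * log(vF * xb / (p$koff0 * kBT(T)))
}

#' Self-consistent most probable rupture force through a compliant tether
#'
#' With an FJC tether in series the loading rate itself depends on force,
#' so the most probable force solves the fixed point
#' `F = (kBT/x_beta) * ln(vF(F) * x_beta / (koff0*kBT))` with `vF(F)` from
#' [loading_rate]. Solved by damped fixed-point iteration.
#'
#' @param bell a [bell_evans_params] object.
#' @param fjc an [fjc_params] object.
#' @param kc cantilever stiffness in pN/nm.
#' @param v retraction velocity in nm/s.
#' @param T temperature in kelvin.
#' @param tol convergence tolerance in pN.
#' @return list with `F_mp` (pN) and `vF` (pN/s) at the fixed point.
#' @export
most_probable_force_theory <- function(bell, fjc, kc, v, T = 298, tol = 1e-8) {
  F <- max(10, bell_evans_force(kc * v, bell, T))
  for (i in 1:200) {
    vF <- loading_rate(F, fjc, kc, v, T)
    Fn <- bell_evans_force(vF, bell, T)
    if (abs(Fn - F) < tol) {
      return(list(F_mp = Fn, vF = loading_rate(Fn, fjc, kc, v, T)))
    }
    F <- 0.5 * F + 0.5 * Fn
  }
  stop("most_probable_force_theory: fixed-point iteration did not converge")
}
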