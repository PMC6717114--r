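#' Freely-jointed-chain parameters
#'
#' Container for the two FJC parameters of a polymer tether: the contour
#' length `Lc` and the Kuhn length `Lk`. The default values describe two
#' 5 kDa PEG spacers in series as used on AFM cantilever and substrate
#' (contour length about 55 nm, Kuhn length 0.7 nm).
#'
#' @param Lc contour length in nm (> 0).
#' @param Lk Kuhn length in nm (> 0, much smaller than `Lc`).
#' @return An object of class `fjc_params`.
#' @export
fjc_params <- function(Lc = 55, Lk = 0.7) {
  stopifnot(is.numeric(Lc), is.numeric(Lk), length(Lc) == 1, length(Lk) == 1,
            Lc >= 0, Lk > 0)
  structure(list(Lc = Lc, Lk = Lk), class = "fjc_params")
}

#' @export
print.fjc_params <- function(x, ...) {
  cat(sprintf("FJC tether: Lc = %.3g nm, Lk = %.3g nm\n", x$Lc, x$Lk))
  invisible(x)
}

# coth(x) - 1/x (the Langevin function of x), series-protected near 0
.langevin <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  out[small] <- x[small] / 3 - x[small]^3 / 45
  xb <- x[!small]
  out[!small] <- 1 / tanh(xb) - 1 / xb
  out
}

# csch^2(x), overflow-protected for large x
.csch2 <- function(x) {
  out <- numeric(length(x))
  big <- x > 350
  out[!big] <- 1 / sinh(x[!big])^2
  out
}

#' FJC force-extension relation
#'
#' Extension of a freely-jointed chain at tension `F`:
#' `L(F) = Lc * (coth(F*Lk/kBT) - kBT/(F*Lk))`.
#' Monotone increasing in F, saturating at the contour length.
#'
#' @param F force in pN (vectorised; must be > 0 — callers handle the F = 0
#'   limit, where the extension is 0).
#' @param p an [fjc_params] object.
#' @param T temperature in kelvin.
#' @return extension in nm.
#' @export
fjc_extension <- function(F, p, T = 298) {
  stopifnot(inherits(p, "fjc_params"))
  if (any(F <= 0)) stop("fjc_extension requires F > 0; F = 0 gives extension 0")
  x <- F * p$Lk / kBT(T)
  p$Lc * .langevin(x)
}

#' Derivative of FJC extension with respect to force
#'
#' `dL/dF = (Lc/F_k) * ((F_k/F)^2 - csch^2(F/F_k))` with the characteristic
#' force `F_k = kBT/Lk`. Used in the tether-corrected loading rate and in
#' residual scaling of FJC fits.
#'
#' @inheritParams fjc_extension
#' @return dL/dF in nm/pN.
#' @export
fjc_extension_deriv <- function(F, p, T = 298) {
  stopifnot(inherits(p, "fjc_params"))
  if (any(F <= 0)) stop("F must be > 0")
  Fk <- kBT(T) / p$Lk
  x <- F / Fk
  # series for small x: d/dx [coth x - 1/x] = 1/x^2 - csch^2 x -> 1/3 - x^2/15
  out <- numeric(length(x))
  small <- x < 1e-4
  out[small] <- (p$Lc / Fk) * (1 / 3 - x[small]^2 / 15)
  xb <- x[!small]
  out[!small] <- (p$Lc / Fk) * (1 / xb^2 - .csch2(xb))
  out
}

#' Force on a tether-cantilever series at a given piezo displacement
#'
#' The cantilever (stiffness `kc`) and the FJC tether are mechanically in
#' series, so the piezo displacement partitions as
#' `z = L_FJC(F) + F/kc`. The left side is monotone in F, so the force is
#' the unique root of this displacement constraint, found by bisection.
#'
#' @param z piezo displacement in nm (>= 0; vectorised).
#' @param kc cantilever spring constant in pN/nm.
#' @param tether an [fjc_params] object; `Lc = 0` degenerates to a rigid
#'   link, giving `F = kc*z`.
#' @param T temperature in kelvin.
#' @param tol relative tolerance of the root (default 1e-9).
#' @return force in pN, same length as `z`.
#' @export
solve_tether_force <- function(z, kc, tether, T = 298, tol = 1e-9) {
  stopifnot(kc > 0, inherits(tether, "fjc_params"))
  if (any(z < 0)) stop("piezo displacement must be >= 0")
  if (tether$Lc == 0) return(kc * z)
  vapply(z, function(zi) {
    if (zi == 0) return(0)
    # displacement residual g(F) = L(F) + F/kc - z, increasing in F
    g <- function(F) fjc_extension(F, tether, T) + F / kc - zi
    hi <- max(1, kc * zi)                      # rigid-link force bounds above
    lo <- 1e-12
    it <- 0
    while (g(hi) < 0 && it < 200) { hi <- hi * 2; it <- it + 1 }
    if (it >= 200) stop("solve_tether_force: failed to bracket root at z = ", zi)
    r <- stats::uniroot(g, c(lo, hi), tol = tol * max(1, hi))
    r$root
  }, numeric(1))
}

#' Tether-corrected loading rate at force F
#'
#' The instantaneous loading rate of a cantilever retracting at velocity
#' `v` through a compliant FJC tether:
#' `1/vF = (1/(kc*v)) * (1 + kc * dL/dF)`, i.e. the series-compliance
#' correction of the nominal rate `kc*v`. Equivalent closed form:
#' `1/vF = (1/(kc*v)) * (1 + kc*(Lc/F_k)*((F_k/F)^2 - csch^2(F/F_k)))`
#' with `F_k = kBT/Lk`. Evaluated at the rupture force it gives the
#' per-event loading rate used in dynamic force spectroscopy.
#'
#' @param F force in pN (> 0; vectorised).
#' @param fjc an [fjc_params] object (`Lc = 0` recovers `kc*v`).
#' @param kc cantilever stiffness in pN/nm.
#' @param v retraction velocity in nm/s.
#' @param T temperature in kelvin.
#' @return loading rate in pN/s.
#' @export
loading_rate <- function(F, fjc, kc, v, T = 298) {
  stopifnot(kc > 0, v > 0, inherits(fjc, "fjc_params"))
  if (any(F <= 0)) stop("F must be > 0")
  if (fjc$Lc == 0) return(rep(kc * v, length(F)))
  kc * v / (1 + kc * fjc_extension_deriv(F, fjc, T))
}
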