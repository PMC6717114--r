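#' Boltzmann constant in piconewton-nanometre per kelvin
#'
#' All mechanics in this package are expressed in pN, nm, s and K, the
#' natural units of AFM force spectroscopy. `kB * T` at 298 K is
#' approximately 4.114 pN nm.
#'
#' @format A length-one numeric, 0.0138065 pN nm / K.
#' @export
kB <- 0.0138065

#' Thermal energy at temperature T
#'
#' @param T temperature in kelvin.
#' @return kB*T in pN nm.
#' @export
kBT <- function(T = 298) {
  stopifnot(is.numeric(T), T > 0)
  kB * T
}
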