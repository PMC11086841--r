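#' Boltzmann constant in kcal/(mol K)
#'
#' All energies in the package are in kcal/mol, lengths in Angstrom,
#' temperatures in K and times in ps.
#'
#' @export
KB_KCAL <- 0.0019872

#' Thermal energy kT in kcal/mol
#'
#' @param temperature temperature in K
#' @return kT in kcal/mol
#' @export
kT <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  KB_KCAL * temperature
}

#' Deterministic sub-seed derived from a master seed and a stream name
#'
#' Fans one master seed out to named noise streams (integrator noise,
#' ensemble noise, rigid motions, per-window runs) so that composite
#' computations are bit-reproducible from a single seed. The result stays
#' below 2^31.
#'
#' @param seed integer master seed
#' @param name character stream name
#' @return integer sub-seed
#' @export
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 97561L
  as.integer((as.numeric(seed) * 2654435.0 + h * 40503.0) %% 2147483629) + 1L
}
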