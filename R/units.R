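# Particle-count / concentration conversions for a well-mixed compartment.

#' Avogadro constant (mol^-1)
#' @export
AVOGADRO <- 6.02214076e23

#' Default simulation volume in liters (0.0328 fL cube, 0.32 um edge)
#' @export
DEFAULT_VOLUME <- 0.0328e-15

#' Per-pair stochastic propensity of a bimolecular reaction
#'
#' Converts a macroscopic association constant (M^-1 s^-1) into the
#' per-pair hazard (s^-1) used by the stochastic engines:
#' `k_on / (N_A * V)`.
#'
#' @param k_on association rate constant, M^-1 s^-1 (>= 0)
#' @param volume compartment volume in liters (> 0)
#' @return per-pair rate in s^-1
#' @examples
#' bimolecular_propensity(1e8, 0.0328e-15)  # ~5.06 s^-1 per CaM-subunit pair
#' @export
bimolecular_propensity <- function(k_on, volume = DEFAULT_VOLUME) {
  if (any(k_on < 0)) stop("k_on must be non-negative")
  if (any(volume <= 0)) stop("volume must be positive")
  k_on / (AVOGADRO * volume)
}

#' Convert a molar concentration to a discrete particle count
#'
#' @param conc concentration in mol/L (>= 0)
#' @param volume compartment volume in liters (> 0)
#' @return integer count, `round(conc * N_A * volume)`
#' @examples
#' concentration_to_count(22.8e-6)  # 450 CaM in the 0.0328 fL compartment
#' concentration_to_count(0.86e-6)  # 17 PP1
#' @export
concentration_to_count <- function(conc, volume = DEFAULT_VOLUME) {
  if (any(conc < 0)) stop("concentration must be non-negative")
  if (any(volume <= 0)) stop("volume must be positive")
  as.integer(round(conc * AVOGADRO * volume))
}

#' Convert a particle count to a molar concentration
#'
#' @param count particle count (>= 0)
#' @param volume compartment volume in liters (> 0)
#' @return concentration in mol/L
#' @export
count_to_concentration <- function(count, volume = DEFAULT_VOLUME) {
  if (any(count < 0)) stop("count must be non-negative")
  if (any(volume <= 0)) stop("volume must be positive")
  count / (AVOGADRO * volume)
}
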