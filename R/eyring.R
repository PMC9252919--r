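#' Intrinsic rate constant from an activation free energy (Eyring equation)
#'
#' Converts an activation free energy \eqn{\Delta G^\ddagger} into a
#' first-order rate constant via transition-state theory,
#' \deqn{k = \kappa \frac{k_B T}{h} \exp\!\left(-\frac{\Delta G^\ddagger}{RT}\right).}
#'
#' At 310.15 K (37 degrees C) the prefactor \eqn{k_B T / h} is about
#' 6.46e12 s\eqn{^{-1}}; barriers of 11.8, 6.5 and 0.1 kcal mol\eqn{^{-1}}
#' map to 3.13e4, 1.70e8 and 5.49e12 s\eqn{^{-1}} respectively.
#'
#' @param delta_g Activation free energy in kcal mol\eqn{^{-1}}. Vectorized.
#'   May be zero or (formally) negative; a value quoted as an upper bound,
#'   e.g. "<= 0.1", should be passed as the bound itself.
#' @param temperature Absolute temperature in K; must be positive.
#' @param constants A [physical_constants()] object.
#'
#' @return Rate constant(s) in s\eqn{^{-1}}.
#' @seealso [eyring_barrier()] for the inverse transform.
#' @examples
#' eyring_rate(6.5, 310.15)   # ~1.70e8 s^-1
#' eyring_rate(0, 310.15)     # prefactor kB*T/h
#' @export
eyring_rate <- function(delta_g, temperature = body_temperature,
                        constants = physical_constants()) {
  stopifnot(is.numeric(delta_g), is.numeric(temperature))
  if (length(temperature) != 1L || !is.finite(temperature) || temperature <= 0) {
    stop("temperature must be a single positive finite value (K)", call. = FALSE)
  }
  if (any(!is.finite(delta_g))) {
    stop("delta_g must be finite (kcal/mol)", call. = FALSE)
  }
  prefactor <- constants$transmission_coefficient *
    constants$boltzmann * temperature / constants$planck
  prefactor * exp(-delta_g / (constants$gas_constant * temperature))
}

#' Activation free energy from a rate constant
#'
#' Exact algebraic inverse of [eyring_rate()]:
#' \eqn{\Delta G^\ddagger = -RT \log(k h / (\kappa k_B T))}.
#'
#' @param rate First-order rate constant(s) in s\eqn{^{-1}}; must be positive.
#' @inheritParams eyring_rate
#' @return Activation free energy in kcal mol\eqn{^{-1}}.
#' @examples
#' eyring_barrier(3.13e4, 310.15)  # ~11.8 kcal/mol
#' @export
eyring_barrier <- function(rate, temperature = body_temperature,
                           constants = physical_constants()) {
  stopifnot(is.numeric(rate), is.numeric(temperature))
  if (length(temperature) != 1L || !is.finite(temperature) || temperature <= 0) {
    stop("temperature must be a single positive finite value (K)", call. = FALSE)
  }
  if (any(!is.finite(rate)) || any(rate <= 0)) {
    stop("rate must be positive and finite (s^-1)", call. = FALSE)
  }
  prefactor <- constants$transmission_coefficient *
    constants$boltzmann * temperature / constants$planck
  -constants$gas_constant * temperature * log(rate / prefactor)
}
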