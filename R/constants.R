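#' Physical constants for transition-state-theory rate calculations
#'
#' Returns the constants entering the Eyring expression
#' \eqn{k = \kappa (k_B T / h) \exp(-\Delta G^\ddagger / RT)}.
#' Defaults are the exact CODATA 2018 SI values for the Boltzmann and
#' Planck constants, the molar gas constant expressed in
#' kcal mol\eqn{^{-1}} K\eqn{^{-1}}, and a transmission coefficient of 1.
#'
#' @param boltzmann Boltzmann constant, J K\eqn{^{-1}}.
#' @param planck Planck constant, J s.
#' @param gas_constant Molar gas constant, kcal mol\eqn{^{-1}} K\eqn{^{-1}}.
#' @param transmission_coefficient Dimensionless transmission coefficient
#'   \eqn{\kappa}; 1 unless there is a reason to believe barrier recrossing
#'   or tunnelling matters.
#'
#' @return A list of class `physical_constants`.
#' @examples
#' physical_constants()
#' @export
physical_constants <- function(boltzmann = 1.380649e-23,
                               planck = 6.62607015e-34,
                               gas_constant = 1.98720425e-3,
                               transmission_coefficient = 1) {
  vals <- c(boltzmann, planck, gas_constant, transmission_coefficient)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all physical constants must be positive and finite", call. = FALSE)
  }
  structure(
    list(boltzmann = boltzmann, planck = planck,
         gas_constant = gas_constant,
         transmission_coefficient = transmission_coefficient),
    class = "physical_constants"
  )
}

# 37 degrees C. The assay temperature of the study conditions; also the
# temperature at which the reference activation barriers were converted to
# intrinsic rate constants.
#' Body temperature in kelvin (37 degrees C)
#'
#' Default temperature for networks, profiles and Eyring conversions.
#' @export
body_temperature <- 310.15
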