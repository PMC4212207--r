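# Physical constants (CODATA); voltages in mV throughout the package.
.FARADAY <- 96485.33212      # C / mol
.GAS_CONSTANT <- 8.314462618 # J / (mol K)

#' Thermal voltage RT/F in millivolts
#'
#' The voltage scale of Boltzmann gating expressions. At the package default of
#' 298 K it equals 25.693 mV.
#'
#' @param temperature Absolute temperature in kelvin.
#' @return RT/F in mV.
#' @export
#' @examples
#' thermal_voltage(298)
thermal_voltage <- function(temperature = 298) {
  stopifnot(is.numeric(temperature), temperature > 0)
  1000 * .GAS_CONSTANT * temperature / .FARADAY
}
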