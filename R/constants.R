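#' Physical constants
#'
#' Constants used by the permeation and gating machinery.  Units follow the
#' package conventions: voltages in mV, concentrations/activities in mM,
#' rate constants in 1/s, currents in pA.
#'
#' @return A list with elements `e` (elementary charge, C), `R` (gas
#'   constant, J/(mol K)), `F` (Faraday constant, C/mol) and `T_default`
#'   (default temperature, degrees C).
#' @examples
#' channel_constants()$e
#' @export
channel_constants <- function() {
  list(
    e = 1.602176634e-19,
    R = 8.314462618,
    F = 96485.33212,
    T_default = 25
  )
}

#' Thermal voltage RT/F
#'
#' @param T_C temperature in degrees Celsius.
#' @return Thermal voltage in mV (about 25.7 mV at 25 degrees C).
#' @examples
#' thermal_voltage(25)
#' @export
thermal_voltage <- function(T_C = channel_constants()$T_default) {
  cst <- channel_constants()
  1000 * cst$R * (T_C + 273.15) / cst$F
}

#' Mean transport-cycle duration implied by a single-channel current
#'
#' At steady state one elementary charge crosses the membrane per transport
#' cycle, so the mean cycle duration is e/I.
#'
#' @param current_pA single-channel current in pA.
#' @return Cycle duration in nanoseconds.
#' @examples
#' cycle_time_ns(16) # about 10 ns
#' @export
cycle_time_ns <- function(current_pA) {
  stopifnot(is.numeric(current_pA), all(current_pA != 0))
  channel_constants()$e / (abs(current_pA) * 1e-12) * 1e9
}
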