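#' Build a table of experimental conditions
#'
#' A condition is a membrane voltage (mV, internal/cis side relative to the
#' grounded external/trans side) combined with internal and external KCl
#' concentrations (mM) and a temperature.  K+ activities are derived from
#' the concentrations via the mean activity coefficient table.  Positive
#' voltages and positive currents are outward.
#'
#' @param V voltage(s), mV.
#' @param c_in,c_out internal / external KCl concentration(s), mM (> 0);
#'   recycled to a common length with `V`.
#' @param T_C temperature, degrees C.
#' @param coeff_table activity coefficient table, see
#'   [kcl_activity_table()].
#' @return A data.frame with columns `V`, `c_in`, `c_out`, `a_in`, `a_out`,
#'   `T_C`.
#' @examples
#' make_conditions(seq(-160, 160, 20), c_in = 100, c_out = 100)
#' @export
make_conditions <- function(V, c_in, c_out,
                            T_C = channel_constants()$T_default,
                            coeff_table = kcl_activity_table()) {
  if (any(c_in <= 0) || any(c_out <= 0)) {
    stop("concentrations must be > 0")
  }
  n <- max(length(V), length(c_in), length(c_out))
  out <- data.frame(V = rep_len(V, n),
                    c_in = rep_len(c_in, n),
                    c_out = rep_len(c_out, n),
                    T_C = rep_len(T_C, n))
  out$a_in <- activity_from_concentration(out$c_in, coeff_table)
  out$a_out <- activity_from_concentration(out$c_out, coeff_table)
  out[c("V", "c_in", "c_out", "a_in", "a_out", "T_C")]
}

#' Nernst reversal potential for K+
#'
#' `E_K = (R T / F) ln(a_out / a_in)`, in mV.  K+ is assumed to be the only
#' permeant ion.
#'
#' @param cond a condition table from [make_conditions()] (columns `a_in`,
#'   `a_out`, `T_C`).
#' @return Numeric vector of reversal potentials, mV.
#' @examples
#' nernst_potential(make_conditions(0, 100, 1000))
#' @export
nernst_potential <- function(cond) {
  if (any(cond$a_in <= 0) || any(cond$a_out <= 0)) {
    stop("activities must be > 0")
  }
  thermal_voltage(cond$T_C) * log(cond$a_out / cond$a_in)
}

#' K+ motive force
#'
#' The driving force `Kmf = V - E_K` with `E_K` the Nernst reversal
#' potential.
#'
#' @inheritParams nernst_potential
#' @return A data.frame with columns `E_K` and `Kmf` (mV).
#' @export
kmf <- function(cond) {
  E_K <- nernst_potential(cond)
  data.frame(E_K = E_K, Kmf = cond$V - E_K)
}
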