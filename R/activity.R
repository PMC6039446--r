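#' Mean activity coefficients of KCl at 25 degrees C
#'
#' Standard literature (Robinson & Stokes) mean molal activity coefficients
#' of aqueous KCl, used to convert nominal K+ concentrations into
#' thermodynamic activities.  The table covers 10--3000 mM; any monotone
#' table with the same two columns can be supplied instead.
#'
#' @return A data.frame with columns `c_mM` (concentration, mM) and `gamma`
#'   (mean activity coefficient, dimensionless in (0, 1]).
#' @export
kcl_activity_table <- function() {
  data.frame(
    c_mM  = c(10, 20, 50, 100, 200, 300, 500, 700, 1000, 1500, 2000, 3000),
    gamma = c(0.902, 0.869, 0.816, 0.768, 0.717, 0.687, 0.649, 0.626,
              0.604, 0.583, 0.573, 0.569)
  )
}

#' Convert a K+ concentration to an activity
#'
#' Interpolates the mean activity coefficient log-linearly in concentration
#' and returns `c * gamma(c)`.  Below the table support the Debye-Hueckel
#' limiting law (`log10 gamma = -0.509 sqrt(I)`, I in M) is used, so the
#' activity/concentration ratio tends to 1 at ideal dilution.
#'
#' @param c_mM concentration(s) in mM, `>= 0`.
#' @param coeff_table monotone coefficient table, see [kcl_activity_table()].
#' @return Activity in mM, same length as `c_mM`.
#' @examples
#' activity_from_concentration(100)
#' @export
activity_from_concentration <- function(c_mM, coeff_table = kcl_activity_table()) {
  if (!is.numeric(c_mM) || any(is.na(c_mM))) {
    stop("`c_mM` must be numeric and non-missing")
  }
  if (any(c_mM < 0)) stop("concentration must be >= 0")
  stopifnot(is.data.frame(coeff_table),
            all(c("c_mM", "gamma") %in% names(coeff_table)))
  tab <- coeff_table[order(coeff_table$c_mM), ]
  if (any(tab$gamma <= 0) || any(tab$gamma > 1)) {
    stop("activity coefficients must lie in (0, 1]")
  }
  if (any(c_mM > max(tab$c_mM))) {
    stop("concentration above the support of the activity coefficient table (",
         max(tab$c_mM), " mM)")
  }
  gamma <- numeric(length(c_mM))
  lo <- c_mM < min(tab$c_mM)
  if (any(lo)) {
    # Debye-Hueckel limiting law for a 1:1 electrolyte, I in mol/L
    gamma[lo] <- 10^(-0.509 * sqrt(c_mM[lo] / 1000))
  }
  if (any(!lo)) {
    gamma[!lo] <- approx(log(tab$c_mM), tab$gamma, xout = log(c_mM[!lo]),
                         rule = 1)$y
  }
  out <- c_mM * gamma
  out[c_mM == 0] <- 0
  out
}
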