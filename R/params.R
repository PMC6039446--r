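#' Construct a rate parameter set
#'
#' Holds the base rate constants of a permeation model together with the
#' Eyring barrier parameters and (optionally) the gating scale factor `w`.
#' Base rates are in 1/s for `plain` and `eyring` edges (value at 0 mV) and
#' in 1/(s mM) for binding edges (value at 1 mM activity).
#'
#' @param base_rates named numeric vector or list, one positive entry per
#'   edge parameter of the model.
#' @param eyring named list, one entry per Eyring group, each a list with
#'   `s` (electrical position of the barrier, in `[0, 1]`) and `V_char`
#'   (characteristic voltage causing an e-fold change, mV > 0).
#' @param w optional gating scale factor (1/s, voltage- and
#'   concentration-independent), kept alongside the permeation rates.
#' @return An object of class `rate_params`.
#' @export
rate_params <- function(base_rates, eyring = list(), w = NA_real_) {
  base_rates <- unlist(base_rates)
  if (is.null(names(base_rates)) || any(!nzchar(names(base_rates)))) {
    stop("base_rates must be named")
  }
  if (!is.numeric(base_rates) || any(!is.finite(base_rates)) ||
      any(base_rates <= 0)) {
    stop("all base rates must be finite and > 0")
  }
  for (g in names(eyring)) {
    ey <- eyring[[g]]
    if (is.null(ey$s) || is.null(ey$V_char)) {
      stop("eyring group '", g, "' needs fields s and V_char")
    }
    if (ey$s < 0 || ey$s > 1) stop("eyring s must lie in [0, 1]")
    if (ey$V_char <= 0) stop("eyring V_char must be > 0")
  }
  if (!is.na(w) && w <= 0) stop("w must be > 0")
  structure(list(base_rates = base_rates,
                 eyring = lapply(eyring, function(e)
                   list(s = as.numeric(e$s), V_char = as.numeric(e$V_char))),
                 w = as.numeric(w)),
            class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Rate parameter set:", length(x$base_rates), "base rates\n")
  print(signif(x$base_rates, 4))
  for (g in names(x$eyring)) {
    cat(sprintf("  %s: s = %.3f, V_char = %.2f mV\n", g,
                x$eyring[[g]]$s, x$eyring[[g]]$V_char))
  }
  if (!is.na(x$w)) cat(sprintf("  gating scale w = %.4g /s\n", x$w))
  invisible(x)
}

#' Read / write a rate parameter set (JSON)
#'
#' Round-trip stable JSON serialisation of [rate_params()] objects.
#'
#' @param path file path.
#' @return [read_parameter_set()] returns a `rate_params` object.
#' @export
read_parameter_set <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  rate_params(base_rates = unlist(doc$base_rates),
              eyring = if (is.data.frame(doc$eyring)) {
                # simplifyVector may tabularise; rebuild the list form
                setNames(lapply(seq_len(nrow(doc$eyring)), function(i)
                  as.list(doc$eyring[i, ])), rownames(doc$eyring))
              } else doc$eyring,
              w = if (is.null(doc$w)) NA_real_ else doc$w)
}

#' @param params a `rate_params` object.
#' @rdname read_parameter_set
#' @export
write_parameter_set <- function(params, path) {
  stopifnot(inherits(params, "rate_params"))
  doc <- list(base_rates = as.list(params$base_rates),
              eyring = params$eyring)
  if (!is.na(params$w)) doc$w <- params$w
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Impose thermodynamic (Nernst) consistency on a parameter set
#'
#' Two constraints make the model cycle thermodynamically consistent so that
#' the current reverses exactly at the Nernst potential:
#' (a) at 0 mV the product of forward base rates around the transport cycle
#' equals the product of backward base rates -- one backward base rate (by
#' default the reverse of the last cycle edge) is eliminated in favour of
#' the others; (b) the characteristic voltages of the two Eyring groups obey
#' `1/V_a + 1/V_b = F/(R T)`, i.e. the cycle carries exactly one elementary
#' charge across the full membrane field -- the `V_char` of the non-anchor
#' group is derived from the anchor group's value.
#'
#' @param model a `perm_model`.
#' @param params a `rate_params` covering the model.
#' @param eliminate parameter name of the backward base rate to recompute;
#'   default: the reverse of the last transport-cycle edge.
#' @param anchor_group Eyring group whose `V_char` is kept; the other
#'   group's `V_char` is derived.  Ignored when the model has a single
#'   Eyring group (then constraint (b) fixes that group directly).
#' @param T_C temperature (degrees C) defining the thermal voltage.
#' @return The adjusted `rate_params`.
#' @export
apply_nernst_constraint <- function(model, params,
                                    eliminate = NULL, anchor_group = NULL,
                                    T_C = channel_constants()$T_default) {
  stopifnot(inherits(model, "perm_model"), inherits(params, "rate_params"))
  ed <- model$edges
  fwd <- ed$param[ed$cycle_forward]
  bwd <- ed$param[ed$cycle_backward]
  if (is.null(eliminate)) {
    tc <- model$transport_cycle
    last_from <- tc[length(tc)]; last_to <- tc[1]
    eliminate <- ed$param[ed$from == last_to & ed$to == last_from]
  }
  if (!eliminate %in% bwd) {
    stop("'eliminate' must name a backward transport-cycle rate")
  }
  br <- params$base_rates
  missing <- setdiff(c(fwd, bwd), names(br))
  if (length(missing)) stop("parameter set lacks: ",
                            paste(missing, collapse = ", "))
  other_b <- setdiff(bwd, eliminate)
  br[eliminate] <- prod(br[fwd]) / prod(br[other_b])

  V_T <- thermal_voltage(T_C)
  ey <- params$eyring
  groups <- names(ey)
  if (length(groups) == 1) {
    ey[[1]]$V_char <- V_T
  } else if (length(groups) == 2) {
    if (is.null(anchor_group)) anchor_group <- groups[1]
    other <- setdiff(groups, anchor_group)
    Va <- ey[[anchor_group]]$V_char
    if (Va <= V_T) {
      stop("anchor V_char must exceed the thermal voltage (", round(V_T, 2),
           " mV) for the derived group to have a positive V_char")
    }
    ey[[other]]$V_char <- 1 / (1 / V_T - 1 / Va)
  } else if (length(groups) > 2) {
    stop("Nernst constraint implemented for at most two Eyring groups")
  }
  rate_params(br, ey, w = params$w)
}
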