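#' Evaluate edge rate constants under experimental conditions
#'
#' [edge_rate_matrix()] evaluates every directed edge of a model for every
#' condition: `plain` edges return their base rate; binding edges scale the
#' base rate with the internal or external K+ activity; Eyring edges in the
#' cycle-forward orientation return `k0 exp(s V / V_char)` and their
#' reverse partners `k0 exp(-(1 - s) V / V_char)`, sharing `s` and `V_char`
#' within the Eyring group.  Voltage is assumed to drop only across the
#' Eyring barriers.
#'
#' @param model a `perm_model`.
#' @param params a `rate_params` covering all edge parameters.
#' @param cond condition table from [make_conditions()].
#' @return A numeric matrix of size `nrow(cond) x nrow(model$edges)` with
#'   edge parameter names as column names.
#' @export
edge_rate_matrix <- function(model, params, cond) {
  stopifnot(inherits(model, "perm_model"), inherits(params, "rate_params"))
  ed <- model$edges
  missing <- setdiff(ed$param, names(params$base_rates))
  if (length(missing)) {
    stop("parameter set lacks rate(s): ", paste(missing, collapse = ", "))
  }
  n <- nrow(cond)
  out <- matrix(NA_real_, n, nrow(ed), dimnames = list(NULL, ed$param))
  for (j in seq_len(nrow(ed))) {
    k0 <- params$base_rates[[ed$param[j]]]
    out[, j] <- switch(
      ed$kind[j],
      plain = rep_len(k0, n),
      bind_internal = k0 * cond$a_in,
      bind_external = k0 * cond$a_out,
      eyring = {
        g <- ed$eyring_group[j]
        ey <- params$eyring[[g]]
        if (is.null(ey)) stop("parameter set lacks Eyring group '", g, "'")
        if (ed$cycle_forward[j]) {
          k0 * exp(ey$s * cond$V / ey$V_char)
        } else {
          k0 * exp(-(1 - ey$s) * cond$V / ey$V_char)
        }
      })
  }
  out
}

#' @param from,to state labels selecting a single directed edge.
#' @return [edge_rate()] returns the scalar rate constant (1/s) of one edge
#'   under one condition.
#' @rdname edge_rate_matrix
#' @export
edge_rate <- function(model, params, cond, from, to) {
  stopifnot(nrow(cond) == 1)
  j <- which(model$edges$from == from & model$edges$to == to)
  if (length(j) != 1) stop("no edge ", from, " -> ", to, " in the model")
  unname(edge_rate_matrix(model, params, cond)[1, j])
}

#' Assemble the master-equation generator matrix
#'
#' Builds the rate (generator) matrix Q of the permeation model for one
#' condition: `Q[i, j]` is the rate constant of the transition i -> j, the
#' diagonal holds minus the row exit sums, so rows sum to zero.
#'
#' @inheritParams edge_rate_matrix
#' @return An `n_states x n_states` matrix with state labels as dimnames.
#' @export
build_generator <- function(model, params, cond) {
  stopifnot(nrow(cond) == 1)
  r <- edge_rate_matrix(model, params, cond)[1, ]
  n <- length(model$states)
  Q <- matrix(0, n, n, dimnames = list(model$states, model$states))
  fi <- match(model$edges$from, model$states)
  ti <- match(model$edges$to, model$states)
  for (j in seq_along(r)) Q[fi[j], ti[j]] <- Q[fi[j], ti[j]] + r[j]
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}
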