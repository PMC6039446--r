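#' Steady-state occupation probabilities of a generator matrix
#'
#' Solves the stationarity system `P Q = 0`, `sum(P) = 1` by a dense linear
#' solve with the normalisation row replacing one balance equation.  For a
#' strongly connected model the solution is unique and strictly positive.
#'
#' @param Q generator matrix from [build_generator()].
#' @return Named numeric vector of probabilities summing to 1.
#' @export
steady_state <- function(Q) {
  n <- nrow(Q)
  stopifnot(n == ncol(Q))
  A <- t(Q)
  A[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  P <- tryCatch(solve(A, b), error = function(e) {
    stop("singular stationarity system (reducible or degenerate generator): ",
         conditionMessage(e))
  })
  if (any(P < -1e-9)) {
    stop("negative stationary probability: degenerate generator")
  }
  P <- pmax(P, 0)
  P <- P / sum(P)
  names(P) <- rownames(Q)
  P
}

#' Steady-state profile over many conditions
#'
#' Vectorised steady state and open-channel current for a batch of
#' conditions.  Edge rates are evaluated with [edge_rate_matrix()] and the
#' per-condition linear solves run in compiled code.  The current is the
#' net stationary probability flux across the first transport-cycle edge
#' (identical on every cycle edge at steady state) times the elementary
#' charge.
#'
#' @inheritParams edge_rate_matrix
#' @return A list with `P` (matrix `n_cond x n_states`), `flux` (net cycle
#'   flux, 1/s; positive = outward) and `current_pA`.
#' @export
steady_profile <- function(model, params, cond) {
  rates <- edge_rate_matrix(model, params, cond)
  fi <- match(model$edges$from, model$states)
  ti <- match(model$edges$to, model$states)
  P <- steady_batch_cpp(rates, fi, ti, length(model$states))
  colnames(P) <- model$states

  tc <- model$transport_cycle
  jf <- which(model$edges$from == tc[1] & model$edges$to == tc[2])
  jb <- which(model$edges$from == tc[2] & model$edges$to == tc[1])
  i1 <- match(tc[1], model$states); i2 <- match(tc[2], model$states)
  flux <- unname(P[, i1] * rates[, jf] - P[, i2] * rates[, jb])
  list(P = P, flux = flux,
       current_pA = channel_constants()$e * flux * 1e12)
}

#' Open-channel current for a single condition
#'
#' @inheritParams edge_rate_matrix
#' @return A list with `current_pA` (positive = outward) and `flux`
#'   (transport cycles per second).
#' @export
steady_current <- function(model, params, cond) {
  stopifnot(nrow(cond) == 1)
  pr <- steady_profile(model, params, cond)
  list(current_pA = pr$current_pA[1], flux = pr$flux[1])
}

#' Current-voltage curve over a set of conditions
#'
#' @inheritParams edge_rate_matrix
#' @return `cond` extended by columns `current_pA` and `flux`.
#' @export
iv_curve <- function(model, params, cond) {
  if (nrow(cond) < 1) stop("empty condition list")
  pr <- steady_profile(model, params, cond)
  cbind(cond, current_pA = pr$current_pA, flux = pr$flux)
}

#' King-Altman spanning-tree state weights (exhaustive oracle)
#'
#' Computes the unnormalised stationary weights `D_m` of each state as the
#' sum over all spanning trees directed toward state m of the product of
#' their edge rate constants (the King-Altman diagram method).  The
#' enumeration is exhaustive and intended as an independent cross-check of
#' the linear-solve steady state; it refuses models with more than 8
#' states.
#'
#' @param model a `perm_model`.
#' @param rates named numeric vector of per-edge rate constants (names =
#'   edge parameter names), e.g. one row of [edge_rate_matrix()].
#' @return Named numeric vector `D` (one weight per state); `D / sum(D)`
#'   equals the stationary distribution.
#' @export
spanning_tree_oracle <- function(model, rates) {
  n <- length(model$states)
  if (n > 8) stop("spanning-tree enumeration is an oracle for <= 8 states")
  ed <- model$edges
  if (!all(ed$param %in% names(rates))) {
    stop("rates must cover every edge parameter")
  }
  r <- rates[ed$param]
  fi <- match(ed$from, model$states)
  ti <- match(ed$to, model$states)

  D <- setNames(numeric(n), model$states)
  for (root in seq_len(n)) {
    non_root <- setdiff(seq_len(n), root)
    # candidate outgoing edges per non-root vertex
    choices <- lapply(non_root, function(v) which(fi == v))
    combos <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
    for (k in seq_len(nrow(combos))) {
      sel <- as.integer(combos[k, ])
      succ <- integer(n)
      succ[non_root] <- ti[sel]
      # each non-root vertex must reach the root without revisiting
      ok <- TRUE
      for (v in non_root) {
        cur <- v; steps <- 0L
        while (cur != root) {
          cur <- succ[cur]
          steps <- steps + 1L
          if (steps > n) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) D[root] <- D[root] + prod(r[sel])
    }
  }
  D
}
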