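# Independent oracles and small generators used across the test files.

# plain-R biquad cascade (direct form I, zero initial state); independent
# of the compiled streaming implementation
r_sos_filter <- function(x, sos) {
  for (i in seq_len(nrow(sos))) {
    b <- sos[i, 1:3]; a <- c(1, sos[i, 4:5])
    y <- numeric(length(x))
    for (n in seq_along(x)) {
      y[n] <- b[1] * x[n] +
        (if (n > 1) b[2] * x[n - 1] - a[2] * y[n - 1] else 0) +
        (if (n > 2) b[3] * x[n - 2] - a[3] * y[n - 2] else 0)
    }
    x <- y
  }
  x
}

# random strictly positive rate assignment for a model's edges
random_rates <- function(model, lo = 1e6, hi = 1e9) {
  setNames(10^runif(nrow(model$edges), log10(lo), log10(hi)),
           model$edges$param)
}

# generator matrix from explicit per-edge rates (independent of
# build_generator's condition handling)
rates_to_Q <- function(model, rates) {
  n <- length(model$states)
  Q <- matrix(0, n, n, dimnames = list(model$states, model$states))
  fi <- match(model$edges$from, model$states)
  ti <- match(model$edges$to, model$states)
  for (j in seq_along(rates)) Q[fi[j], ti[j]] <- rates[[model$edges$param[j]]]
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

# tiny two-series condition family for collapse diagnostics
internal_series <- function(c_in, c_out = 100, V = seq(-160, -20, 20)) {
  setNames(lapply(c_in, function(ci) make_conditions(V, ci, c_out)),
           paste0("int_", c_in))
}
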