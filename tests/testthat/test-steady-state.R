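m5 <- shipped_model("five_state_roux")
m4 <- shipped_model("four_state")

test_that("steady state solves the stationarity system", {
  # uniform 5-cycle is uniformly occupied
  Q <- rates_to_Q(m5, setNames(rep(1e7, nrow(m5$edges)), m5$edges$param))
  expect_equal(unname(steady_state(Q)), rep(0.2, 5), tolerance = 1e-12)
  # normalisation for random instances
  set.seed(7)
  for (i in 1:10) {
    Qr <- rates_to_Q(m5, random_rates(m5))
    expect_equal(sum(steady_state(Qr)), 1, tolerance = 1e-12)
  }
  # reducible generator -> informative error
  Qbad <- matrix(0, 3, 3)
  expect_error(steady_state(Qbad), "singular|degenerate")
})

test_that("spanning-tree enumeration matches known diagram counts", {
  tri <- perm_model("tri", c("A", "B", "C"), c("", "", ""),
                    data.frame(from = c("A", "B", "B", "C", "C", "A"),
                               to   = c("B", "A", "C", "B", "A", "C"),
                               param = c("ab", "ba", "bc", "cb", "ca", "ac"),
                               kind = "plain"),
                    c("A", "B", "C"))
  D <- spanning_tree_oracle(tri, setNames(rep(1, 6),
                                          c("ab", "ba", "bc", "cb", "ca", "ac")))
  # 3 directed spanning trees per root in the full 3-cycle
  expect_equal(unname(D), rep(3, 3))
  # pure cycle: every weight is a sum of products of (N-1) rates
  set.seed(11)
  r <- random_rates(m5, 1, 10)
  D5 <- spanning_tree_oracle(m5, r)
  lam <- 3
  D5s <- spanning_tree_oracle(m5, r * lam)
  expect_equal(D5s, D5 * lam^4, tolerance = 1e-12)  # homogeneity deg N-1
})

test_that("linear solve and King-Altman enumeration agree", {
  set.seed(23)
  for (i in 1:25) {
    mod <- if (i %% 2) m5 else m4
    r <- random_rates(mod)
    D <- spanning_tree_oracle(mod, r)
    P <- steady_state(rates_to_Q(mod, r))
    expect_equal(unname(P), unname(D / sum(D)), tolerance = 1e-10)
  }
})

test_that("stationary flux is conserved along the transport cycle", {
  set.seed(31)
  gt <- default_ground_truth()
  cond <- make_conditions(c(-120, 40), 250, 100)
  rates <- edge_rate_matrix(m5, gt$params, cond)
  pr <- steady_profile(m5, gt$params, cond)
  tc <- m5$transport_cycle
  for (row in 1:2) {
    flux <- vapply(seq_along(tc), function(k) {
      i <- tc[k]; j <- tc[k %% length(tc) + 1]
      jf <- which(m5$edges$from == i & m5$edges$to == j)
      jb <- which(m5$edges$from == j & m5$edges$to == i)
      pr$P[row, i] * rates[row, jf] - pr$P[row, j] * rates[row, jb]
    }, numeric(1))
    expect_equal(max(abs(flux - flux[1])) / abs(flux[1]), 0,
                 tolerance = 1e-10)
    expect_equal(pr$current_pA[row],
                 channel_constants()$e * flux[1] * 1e12)
  }
})

test_that("the cycle current matches the explicit one-cycle closed form", {
  # for a pure cycle: I = e (prod forward - prod backward) / sum(D)
  set.seed(41)
  gt <- default_ground_truth()
  cond <- make_conditions(-100, 500, 100)
  r <- edge_rate_matrix(m5, gt$params, cond)[1, ]
  ed <- m5$edges
  num <- prod(r[ed$param[ed$cycle_forward]]) -
    prod(r[ed$param[ed$cycle_backward]])
  D <- spanning_tree_oracle(m5, r)
  closed_form <- channel_constants()$e * num / sum(D) * 1e12
  expect_equal(steady_current(m5, gt$params, cond)$current_pA,
               closed_form, tolerance = 1e-10)
})

test_that("currents vanish at equilibrium and reverse at the Nernst potential", {
  gt <- default_ground_truth()
  # symmetric solutions, V = 0: equilibrium
  I0 <- steady_current(m5, gt$params, make_conditions(0, 100, 100))
  expect_lt(abs(I0$current_pA), 1e-12)
  # asymmetric: zero crossing within 0.1 mV of E_K
  cond <- make_conditions(0, 1000, 100)
  EK <- nernst_potential(cond)
  f <- function(v) steady_current(m5, gt$params,
                                  make_conditions(v, 1000, 100))$current_pA
  root <- uniroot(f, c(EK - 5, EK + 5), tol = 1e-8)$root
  expect_lt(abs(root - EK), 0.1)
  # iv_curve is a vectorised steady_current
  cc <- make_conditions(seq(-60, 60, 30), 1000, 100)
  iv <- iv_curve(m5, gt$params, cc)
  expect_equal(iv$current_pA[2],
               steady_current(m5, gt$params, cc[2, ])$current_pA)
})
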