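test_that("shipped model specifications validate and round-trip", {
  for (nm in c("five_state_roux", "four_state", "hard_knock_on")) {
    m <- shipped_model(nm)
    expect_s3_class(m, "perm_model")
    # every edge has its reverse
    key <- paste(m$edges$from, m$edges$to)
    expect_true(all(paste(m$edges$to, m$edges$from) %in% key))
    # Eyring groups pair an edge with its reverse
    ey <- m$edges[m$edges$kind == "eyring", ]
    if (nrow(ey)) {
      expect_true(all(table(ey$eyring_group) == 2))
    }
    tmp <- tempfile(fileext = ".json")
    write_model_spec(m, tmp)
    m2 <- read_model_spec(tmp)
    expect_equal(m2$edges, m$edges)
    expect_equal(m2$transport_cycle, m$transport_cycle)
  }
})

test_that("the 5-state cycle carries binding, release and two barriers", {
  m <- shipped_model("five_state_roux")
  expect_length(m$states, 5)
  expect_identical(m$edges$kind[m$edges$param == "k12"], "bind_internal")
  expect_identical(m$edges$kind[m$edges$param == "k54"], "bind_external")
  expect_setequal(unique(na.omit(m$edges$eyring_group)), c("g23", "g51"))
  # the 4-state variant drops the outer-mouth state but keeps both barriers
  m4 <- shipped_model("four_state")
  expect_length(m4$states, 4)
  expect_false("4" %in% m4$states)
  expect_setequal(unique(na.omit(m4$edges$eyring_group)), c("g23", "g51"))
})

test_that("malformed model specifications are rejected", {
  m <- shipped_model("five_state_roux")
  ed <- m$edges[, c("from", "to", "param", "kind", "eyring_group")]
  # drop a reverse edge -> invalid
  expect_error(perm_model("x", m$states, m$occupancy,
                          ed[ed$param != "k21", ], m$transport_cycle),
               "reverse")
  # cycle using a non-existent edge
  expect_error(perm_model("x", m$states, m$occupancy, ed,
                          c("1", "3", "5")), "non-existent")
  # eyring edge without a partner in its group
  ed2 <- ed
  ed2$eyring_group[ed2$param == "k32"] <- "gX"
  expect_error(perm_model("x", m$states, m$occupancy, ed2,
                          m$transport_cycle), "reverse|group")
  # disconnected graph
  ed3 <- ed[!(ed$param %in% c("k34", "k43")), ]
  expect_error(perm_model("x", m$states, m$occupancy, ed3,
                          m$transport_cycle), "connected|non-existent")
})

test_that("parameter sets validate and round-trip through JSON", {
  p <- rate_params(c(k12 = 2e6, k21 = 1e8),
                   list(g1 = list(s = 0.4, V_char = 40)), w = 900)
  tmp <- tempfile(fileext = ".json")
  write_parameter_set(p, tmp)
  p2 <- read_parameter_set(tmp)
  expect_equal(p2$base_rates, p$base_rates)
  expect_equal(p2$eyring, p$eyring)
  expect_equal(p2$w, 900)
  expect_error(rate_params(c(k12 = -1)), "> 0")
  expect_error(rate_params(c(k12 = 1), list(g = list(s = 1.4, V_char = 1))),
               "s must")
})

test_that("the Nernst constraint balances the cycle and splits the field", {
  m <- shipped_model("five_state_roux")
  p0 <- rate_params(
    c(k12 = 2e6, k21 = 1e8, k23 = 2e8, k32 = 2e8, k34 = 3e8,
      k43 = 3e8, k45 = 3e8, k54 = 2e6, k51 = 2e8, k15 = 1),
    list(g23 = list(s = 0.3, V_char = 40),
         g51 = list(s = 0.6, V_char = 60)))
  p <- apply_nernst_constraint(m, p0, anchor_group = "g23")
  ed <- m$edges
  fwd <- prod(p$base_rates[ed$param[ed$cycle_forward]])
  bwd <- prod(p$base_rates[ed$param[ed$cycle_backward]])
  expect_equal(fwd / bwd, 1, tolerance = 1e-12)
  V_T <- thermal_voltage()
  expect_equal(1 / p$eyring$g23$V_char + 1 / p$eyring$g51$V_char,
               1 / V_T, tolerance = 1e-12)
  # anchor below the thermal voltage is impossible
  p0$eyring$g23$V_char <- 20
  expect_error(apply_nernst_constraint(m, p0, anchor_group = "g23"),
               "thermal")
})
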