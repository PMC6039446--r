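gt <- default_ground_truth()
m5 <- shipped_model("five_state_roux")
ds0 <- generate_dataset(gt, default_design(), noise = FALSE, seed = 1)

test_that("the joint objective vanishes at the generating truth", {
  o <- global_objective(m5, gt$params, gt$link, ds0)
  expect_lt(o$error, 1e-12)
  expect_false(o$penalised)
  # error sum equals the sum of the per-curve breakdown
  o2 <- global_objective(m5, gt$params, gating_link("P4/P3", 2 * gt$params$w),
                         ds0)
  expect_equal(o2$error, sum(o2$per_curve$rss), tolerance = 1e-9)
})

test_that("the objective equals an independently coded double loop", {
  link <- gating_link("1/P3", 5e2)
  cfg <- fit_config()
  o <- global_objective(m5, gt$params, link, ds0, cfg)
  # naive per-point loop
  tot <- 0
  for (i in seq_len(nrow(ds0))) {
    cond <- make_conditions(ds0$V_mV[i], ds0$c_in_mM[i], ds0$c_out_mM[i])
    sc <- steady_current(m5, gt$params, cond)
    tot <- tot + (sc$current_pA - ds0$I_OF_pA[i])^2
    if (ds0$V_mV[i] < 0) {
      P <- steady_state(build_generator(m5, gt$params, cond))
      tot <- tot + (log(predict_kOM(link, P)) - log(ds0$kOM_per_s[i]))^2
    }
  }
  expect_equal(o$error, tot, tolerance = 1e-9)
})

test_that("positive-voltage closing rates are masked by default", {
  ds_pert <- ds0
  pos <- ds_pert$V_mV > 0
  ds_pert$kOM_per_s[pos] <- ds_pert$kOM_per_s[pos] * 37
  o1 <- global_objective(m5, gt$params, gt$link, ds0)
  o2 <- global_objective(m5, gt$params, gt$link, ds_pert)
  expect_identical(o1$error, o2$error)
  # with the mask off the perturbation is seen
  cfg_all <- fit_config(kom_mask = "all")
  o3 <- global_objective(m5, gt$params, gt$link, ds_pert, cfg_all)
  expect_gt(o3$error, o2$error)
})

test_that("weights scale their residual family linearly", {
  link <- gating_link("P4/P3", 0.7 * gt$params$w)
  o1 <- global_objective(m5, gt$params, link, ds0, fit_config())
  o2 <- global_objective(m5, gt$params, link, ds0,
                         fit_config(ln_rate_weight = 2))
  # IV part is zero at the truth rates, so the error is pure rate misfit
  expect_equal(o2$error, 2 * o1$error, tolerance = 1e-12)
  o3 <- global_objective(m5, gt$params, gating_link("P4/P3", gt$params$w),
                         ds0, fit_config(current_weight = 5))
  expect_lt(o3$error, 1e-11)
})

test_that("objective evaluation is deterministic", {
  link <- gating_link("1/P2", 1e3)
  e1 <- global_objective(m5, gt$params, link, ds0)$error
  e2 <- global_objective(m5, gt$params, link, ds0)$error
  expect_identical(e1, e2)
})

test_that("parameter transforms encode and decode losslessly", {
  cfg <- fit_config()
  th <- permgate:::encode_params(gt$params, m5, cfg)
  p2 <- permgate:::decode_params(th, m5, cfg)
  expect_equal(p2$base_rates, gt$params$base_rates, tolerance = 1e-10)
  expect_equal(p2$eyring$g23$s, gt$params$eyring$g23$s, tolerance = 1e-10)
  expect_equal(p2$eyring$g51$V_char, gt$params$eyring$g51$V_char,
               tolerance = 1e-10)
  # free fit (constraint off) round-trips too
  cfg2 <- fit_config(nernst = FALSE)
  th2 <- permgate:::encode_params(gt$params, m5, cfg2)
  p3 <- permgate:::decode_params(th2, m5, cfg2)
  expect_equal(p3$base_rates, gt$params$base_rates, tolerance = 1e-10)
})

test_that("refitting from a recovered optimum is a fixed point", {
  cfg <- fit_config(restarts = 1, maxit = 400, seed = 4)
  fit1 <- run_global_fit(ds0, m5, "P4/P3", cfg, init = gt$params)
  expect_lt(fit1$error, 1e-6)
  fit2 <- run_global_fit(ds0, m5, "P4/P3", cfg, init = fit1$params)
  expect_lt(abs(fit2$error - fit1$error), 1e-3 * max(fit1$error, 1e-9))
})

test_that("drift correction finds and removes voltage offsets", {
  cond <- make_conditions(seq(-160, 160, 20), 1000, 100)
  EK <- nernst_potential(cond)[1]
  iv <- iv_curve(m5, gt$params, cond)
  curve <- data.frame(V = iv$V, I = iv$current_pA)
  # already crossing at E_K: offset ~ 0
  d0 <- drift_correct(curve, EK)
  expect_lt(abs(d0$offset), 0.1)
  # a +4 mV electrode drift is detected within 0.5 mV
  d4 <- drift_correct(data.frame(V = curve$V + 4, I = curve$I), EK)
  expect_lt(abs(d4$offset - 4), 0.5)
  expect_lt(max(abs(d4$curve$V - curve$V)), 0.1)
  # linear synthetic IV: root recovered to 1e-6 mV
  lin <- data.frame(V = seq(-50, 50, 10), I = 0.25 * (seq(-50, 50, 10) - 7))
  dl <- drift_correct(lin, expected_EK = 0)
  expect_equal(dl$apparent_reversal, 7, tolerance = 1e-6)
  # no crossing -> error
  expect_error(drift_correct(data.frame(V = 1:5, I = 1:5 + 10), 0),
               "crossing")
})

test_that("spline averaging honours replicate structure", {
  g <- seq(-100, 100, 20)
  c1 <- data.frame(V = g, y = sin(g / 50))
  expect_equal(spline_average(list(c1, c1))$sd, rep(0, length(g)))
  expect_equal(spline_average(list(c1, c1))$mean, c1$y)
  # two parallel lines: mean halfway, sample sd = delta/sqrt(2)
  d <- 3
  l1 <- data.frame(V = g, y = 2 * g)
  l2 <- data.frame(V = g, y = 2 * g + d)
  av <- spline_average(list(l1, l2))
  expect_equal(av$mean, 2 * g + d / 2)
  expect_equal(av$sd, rep(d / sqrt(2), length(g)), tolerance = 1e-9)
  # a cubic polynomial is reproduced exactly at interior points
  f <- function(v) 1e-4 * v^3 - 0.02 * v^2 + v - 5
  r1 <- data.frame(V = g, y = f(g))
  r2 <- data.frame(V = seq(-110, 110, 10), y = f(seq(-110, 110, 10)))
  grid <- seq(-90, 90, 15)
  av2 <- spline_average(list(r1, r2), grid = grid)
  expect_equal(av2$mean, f(grid), tolerance = 1e-8)
  # disjoint ranges are refused
  expect_error(spline_average(list(data.frame(V = 1:5, y = 1:5),
                                   data.frame(V = 10:15, y = 1:6))),
               "overlap")
})
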