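#' Default synthetic study design
#'
#' Eighteen condition series emulating a symmetric/asymmetric KCl
#' single-channel study: six symmetric concentrations, six internal
#' concentrations against fixed 100 mM external, and six external
#' concentrations against fixed 100 mM internal.  Each series carries a
#' voltage grid from -160 to +160 mV in 20 mV steps and yields one IV
#' curve and one closing-rate curve, i.e. 36 curves enter the global
#' objective.  The replicate noise scales match typical amplitude-histogram
#' results: multiplicative noise below 25% CV on rate constants and
#' additive noise below 1 pA on currents.
#'
#' @param n_rep replicates per series.
#' @param cv_rate coefficient of variation of the multiplicative
#'   (log-normal) noise on rate constants (capped at 0.25).
#' @param sd_current standard deviation of the additive Gaussian noise on
#'   currents, pA (capped at 1).
#' @return A list of class `study_design` with elements `series`
#'   (data.frame: `series_id`, `c_in`, `c_out`, `group`), `V` (voltage
#'   grid), `n_rep`, `cv_rate`, `sd_current`.
#' @export
default_design <- function(n_rep = 3, cv_rate = 0.15, sd_current = 0.5) {
  stopifnot(cv_rate >= 0, cv_rate <= 0.25, sd_current >= 0, sd_current <= 1)
  sym <- c(50, 100, 250, 500, 1000, 1500)
  asym <- c(50, 250, 500, 750, 1000, 1500)
  series <- rbind(
    data.frame(series_id = paste0("sym_", sym), c_in = sym, c_out = sym,
               group = "symmetric"),
    data.frame(series_id = paste0("int_", asym), c_in = asym, c_out = 100,
               group = "internal"),
    data.frame(series_id = paste0("ext_", asym), c_in = 100, c_out = asym,
               group = "external"))
  structure(list(series = series, V = seq(-160, 160, by = 20),
                 n_rep = n_rep, cv_rate = cv_rate,
                 sd_current = sd_current),
            class = "study_design")
}

#' Synthetic ground truth for the default study
#'
#' A thermodynamically consistent parameter set for the 5-state permeation
#' model together with the ratio gating link `k_OM = w P4/P3`.  The values
#' are chosen by the package authors so the synthetic study reproduces the
#' qualitative phenomenology of filter-gated channels -- near-linear
#' symmetric IV curves around 100 mM, an exponential rise of the closing
#' rate at negative voltages spanning about two orders of magnitude, a
#' left-shift of the closing-rate curves with internal K+ that collapses
#' against the K+ motive force, and insensitivity to external K+ at
#' negative voltages.  They are synthetic reference values, not
#' experimentally fitted constants.
#'
#' @return A list of class `ground_truth` with `model_name`, `params`
#'   (`rate_params`, Nernst-constrained, including `w`), `link`
#'   (`gating_link`), and `kMO` (descriptive opening-rate curve:
#'   `k_MO = k0 exp(slope V / V_T)`, carried through the data model but
#'   never linked to occupancies).
#' @export
default_ground_truth <- function() {
  base <- c(k12 = 1.2e7, # 1/(s mM), internal binding
            k21 = 8e8,
            k23 = 5e8,   # Eyring forward at 0 mV
            k32 = 1e9,
            k34 = 5e8,
            k43 = 1e9,
            k45 = 5e8,
            k54 = 2e6,   # 1/(s mM), external rebinding
            k51 = 5e8,
            k15 = 1)     # eliminated by the Nernst constraint
  ey <- list(g23 = list(s = 0.20, V_char = 31),
             g51 = list(s = 0.80, V_char = 150))  # V_char derived below
  model <- shipped_model("five_state_roux")
  params <- apply_nernst_constraint(model, rate_params(base, ey),
                                    anchor_group = "g23")
  params$w <- 1300
  structure(list(model_name = "five_state_roux", params = params,
                 link = gating_link("P4/P3", w = params$w),
                 kMO = list(k0 = 1e4, slope = 0.15),
                 provenance = paste("synthetic ground truth chosen to",
                                    "reproduce the qualitative study",
                                    "phenomenology; not fitted values")),
            class = "ground_truth")
}

#' Generate a synthetic experiment dataset
#'
#' Evaluates the ground-truth model over the study design and emulates
#' replicate measurements: multiplicative log-normal noise (given CV) on
#' the rate constants and additive Gaussian noise on the currents, per
#' replicate; replicate curves are then spline-averaged onto the design
#' grid.  With `noise = FALSE` the dataset equals the model predictions
#' exactly.  Reproducible under `seed`.
#'
#' @param truth a [default_ground_truth()]-shaped list.
#' @param design a [default_design()].
#' @param noise logical.
#' @param seed RNG seed.
#' @return A data.frame in the [load_dataset()] schema (`series_id`,
#'   `c_in_mM`, `c_out_mM`, `V_mV`, `I_OF_pA`, `I_sd_pA`, `kOM_per_s`,
#'   `kOM_sd`, `kMO_per_s`, `kMO_sd`, `n_rep`), with the ground truth
#'   attached as attribute `truth`.
#' @export
generate_dataset <- function(truth = default_ground_truth(),
                             design = default_design(), noise = TRUE,
                             seed = 1) {
  model <- shipped_model(truth$model_name)
  missing <- setdiff(model$edges$param, names(truth$params$base_rates))
  if (length(missing)) {
    stop("ground truth does not cover model '", truth$model_name, "': ",
         paste(missing, collapse = ", "))
  }
  set.seed(seed)
  V_T <- thermal_voltage()
  rows <- lapply(seq_len(nrow(design$series)), function(i) {
    se <- design$series[i, ]
    cond <- make_conditions(design$V, se$c_in, se$c_out)
    pr <- steady_profile(model, truth$params, cond)
    I <- pr$current_pA
    kom <- predict_kOM(truth$link, pr$P)
    kmo <- truth$kMO$k0 * exp(truth$kMO$slope * design$V / V_T)
    if (noise) {
      sdlog <- sqrt(log(1 + design$cv_rate^2))
      n <- design$n_rep
      reps_I <- lapply(seq_len(n), function(r)
        data.frame(V = design$V, y = I + rnorm(length(I),
                                               sd = design$sd_current)))
      reps_kom <- lapply(seq_len(n), function(r)
        data.frame(V = design$V, y = kom * exp(rnorm(length(kom),
                                                     sd = sdlog))))
      reps_kmo <- lapply(seq_len(n), function(r)
        data.frame(V = design$V, y = kmo * exp(rnorm(length(kmo),
                                                     sd = sdlog))))
      avg_I <- spline_average(reps_I, grid = design$V)
      avg_kom <- spline_average(reps_kom, grid = design$V)
      avg_kmo <- spline_average(reps_kmo, grid = design$V)
      data.frame(series_id = se$series_id, c_in_mM = se$c_in,
                 c_out_mM = se$c_out, V_mV = design$V,
                 I_OF_pA = avg_I$mean, I_sd_pA = avg_I$sd,
                 kOM_per_s = avg_kom$mean, kOM_sd = avg_kom$sd,
                 kMO_per_s = avg_kmo$mean, kMO_sd = avg_kmo$sd,
                 n_rep = n)
    } else {
      data.frame(series_id = se$series_id, c_in_mM = se$c_in,
                 c_out_mM = se$c_out, V_mV = design$V,
                 I_OF_pA = I, I_sd_pA = 0,
                 kOM_per_s = kom, kOM_sd = 0,
                 kMO_per_s = kmo, kMO_sd = 0, n_rep = 1)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  attr(out, "seed") <- seed
  out
}

#' Generate a raw-trace fixture with known gating truth
#'
#' Simulates a gating event sequence, renders the Bessel-filtered sampled
#' trace and adds Gaussian baseline noise to the samples
#' (measurement-like).  The generating scheme is attached for recovery
#' scoring.
#'
#' @param scheme a [gating_scheme()].
#' @param duration trace length, s; a couple of minutes matches the
#'   per-voltage recording lengths of steady-state protocols.
#' @param config a [trace_config()].
#' @param seed RNG seed (drives both gating and baseline noise).
#' @return A list of class `trace_fixture`: `trace` (noisy
#'   `trace_record`), `scheme` (the truth), `seed`, `config`.
#' @export
generate_trace_fixture <- function(scheme, duration = 120,
                                   config = trace_config(), seed = 1) {
  ev <- simulate_events(scheme, duration, seed = seed)
  tr <- render_filtered_trace(ev, scheme, config, duration = duration)
  set.seed(seed + 424243L)
  tr$samples <- tr$samples + rnorm(length(tr$samples),
                                   sd = config$baseline_sd)
  structure(list(trace = tr, scheme = scheme, seed = seed,
                 config = config),
            class = "trace_fixture")
}
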