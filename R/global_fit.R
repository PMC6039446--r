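#' Settings for the global fit
#'
#' @param current_weight,ln_rate_weight weights of the squared current
#'   residuals (pA^2) and squared ln-closing-rate residuals in the joint
#'   objective.  Unit weights give the two curve families about equal
#'   influence because the rates enter on the log scale.
#' @param kom_mask `"negative"` (closing-rate residuals only at V < 0, the
#'   voltage range where filter gating dominates) or `"all"`.
#' @param nernst logical; impose the thermodynamic consistency constraint
#'   (see [apply_nernst_constraint()]) so the fitted model reverses exactly
#'   at the Nernst potential.
#' @param restarts number of multi-start repetitions.
#' @param perturb_sd log10-scale standard deviation of the start-value
#'   perturbations.
#' @param maxit,reltol Nelder-Mead control per restart.
#' @param polish logical; refine each restart with BFGS.
#' @param polish_maxit BFGS iteration cap for the polish step.
#' @param fit_current which dataset column the model current is compared
#'   against: `"I_OF"` (the effective current entering the permeation
#'   cycle) or `"I_true"` (requires an `I_true_pA` column).
#' @param seed base RNG seed for the restarts.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(current_weight = 1, ln_rate_weight = 1,
                       kom_mask = c("negative", "all"), nernst = TRUE,
                       restarts = 20, perturb_sd = 0.5, maxit = 2000,
                       reltol = 1e-10, polish = TRUE, polish_maxit = 300,
                       fit_current = c("I_OF", "I_true"), seed = 1) {
  stopifnot(current_weight > 0, ln_rate_weight > 0, restarts >= 1)
  structure(list(current_weight = current_weight,
                 ln_rate_weight = ln_rate_weight,
                 kom_mask = match.arg(kom_mask), nernst = nernst,
                 restarts = restarts, perturb_sd = perturb_sd,
                 maxit = maxit, reltol = reltol, polish = polish,
                 polish_maxit = polish_maxit,
                 fit_current = match.arg(fit_current), seed = seed),
            class = "fit_config")
}

# ---- parameter vector <-> rate_params ------------------------------------

# Free parameters: log base rates (minus the eliminated backward rate when
# the Nernst constraint is on), logit barrier positions, characteristic
# voltages (log, or logit(V_T/V_anchor) under the constraint).  The
# transform guarantees positivity and s in (0,1) without explicit bounds.
fit_parametrisation <- function(model, config) {
  ed <- model$edges
  groups <- unique(stats::na.omit(ed$eyring_group))
  elim <- NULL
  if (config$nernst) {
    tc <- model$transport_cycle
    elim <- ed$param[ed$from == tc[1] & ed$to == tc[length(tc)]]
  }
  free_rates <- setdiff(ed$param, elim)
  list(free_rates = free_rates, eliminated = elim, groups = groups,
       names = c(paste0("log_", free_rates),
                 paste0("logit_s_", groups),
                 if (config$nernst) paste0("tV_", groups[1])
                 else paste0("logV_", groups)))
}

encode_params <- function(params, model, config,
                          T_C = channel_constants()$T_default) {
  pz <- fit_parametrisation(model, config)
  V_T <- thermal_voltage(T_C)
  th <- c(log(params$base_rates[pz$free_rates]),
          vapply(pz$groups, function(g) qlogis(params$eyring[[g]]$s),
                 numeric(1)))
  if (config$nernst) {
    th <- c(th, qlogis(V_T / params$eyring[[pz$groups[1]]]$V_char))
  } else {
    th <- c(th, vapply(pz$groups, function(g)
      log(params$eyring[[g]]$V_char), numeric(1)))
  }
  setNames(th, pz$names)
}

decode_params <- function(theta, model, config,
                          T_C = channel_constants()$T_default) {
  pz <- fit_parametrisation(model, config)
  V_T <- thermal_voltage(T_C)
  nr <- length(pz$free_rates); ng <- length(pz$groups)
  br <- setNames(exp(theta[seq_len(nr)]), pz$free_rates)
  s <- plogis(theta[nr + seq_len(ng)])
  ey <- list()
  if (config$nernst) {
    Va <- V_T / plogis(theta[nr + ng + 1])
    ey[[pz$groups[1]]] <- list(s = s[1], V_char = Va)
    if (ng == 2) {
      ey[[pz$groups[2]]] <- list(s = s[2],
                                 V_char = 1 / (1 / V_T - 1 / Va))
    }
    br[pz$eliminated] <- 1  # placeholder, fixed by the constraint below
    pr <- rate_params(br, ey)
    pr <- apply_nernst_constraint(model, pr, eliminate = pz$eliminated,
                                  anchor_group = pz$groups[1], T_C = T_C)
  } else {
    for (i in seq_len(ng)) {
      ey[[pz$groups[i]]] <- list(s = s[i],
                                 V_char = exp(theta[nr + ng + i]))
    }
    pr <- rate_params(br, ey)
  }
  pr
}

# ---- objective -----------------------------------------------------------

dataset_conditions <- function(dataset) {
  make_conditions(dataset$V_mV, dataset$c_in_mM, dataset$c_out_mM)
}

#' Joint objective over all IV and closing-rate curves
#'
#' `error = w_I * sum (I_model - I_data)^2 + w_k * sum (ln k_OM,model -
#' ln k_OM,data)^2`, the current sum over all IV points and the rate sum
#' over the masked (default: negative-voltage) points.  Deterministic.
#'
#' @param model,params permeation model and parameter set.
#' @param link a [gating_link()] (its `w` is used as given).
#' @param dataset dataset in the schema of [load_dataset()].
#' @param config a [fit_config()].
#' @return A list with `error`, `per_curve` (residual breakdown by series
#'   and curve type) and `penalised` (TRUE if the model prediction was
#'   degenerate somewhere and a penalty value was returned).
#' @export
global_objective <- function(model, params, link, dataset,
                             config = fit_config()) {
  cond <- dataset_conditions(dataset)
  pr <- tryCatch(steady_profile(model, params, cond),
                 error = function(e) NULL)
  if (is.null(pr)) {
    return(list(error = 1e10, per_curve = NULL, penalised = TRUE))
  }
  I_col <- if (config$fit_current == "I_OF") "I_OF_pA" else "I_true_pA"
  res_I <- pr$current_pA - dataset[[I_col]]
  kom_model <- tryCatch(predict_kOM(link, pr$P), error = function(e) NULL)
  mask <- if (config$kom_mask == "negative") dataset$V_mV < 0 else
    rep(TRUE, nrow(dataset))
  mask <- mask & is.finite(dataset$kOM_per_s)
  if (is.null(kom_model) || any(!is.finite(kom_model[mask])) ||
      any(kom_model[mask] <= 0)) {
    return(list(error = 1e10, per_curve = NULL, penalised = TRUE))
  }
  res_k <- rep(0, nrow(dataset))
  res_k[mask] <- log(kom_model[mask]) - log(dataset$kOM_per_s[mask])

  sq_I <- config$current_weight * res_I^2
  sq_k <- config$ln_rate_weight * res_k^2
  per_curve <- rbind(
    data.frame(series_id = dataset$series_id, type = "IV", sq = sq_I),
    data.frame(series_id = dataset$series_id[mask], type = "kOM",
               sq = sq_k[mask]))
  agg <- stats::aggregate(sq ~ series_id + type, per_curve, sum)
  names(agg)[names(agg) == "sq"] <- "rss"
  list(error = sum(sq_I) + sum(sq_k), per_curve = agg, penalised = FALSE)
}

# error with w profiled analytically (the ln k_OM residual is quadratic in
# ln w, so the conditional optimum is the mean log misfit)
objective_profiled <- function(theta, model, link1, dataset, cond, mask,
                               I_data, config) {
  params <- tryCatch(decode_params(theta, model, config),
                     error = function(e) NULL)
  if (is.null(params)) return(list(error = 1e10))
  pr <- tryCatch(steady_profile(model, params, cond),
                 error = function(e) NULL)
  if (is.null(pr)) return(list(error = 1e10))
  ratio <- tryCatch(predict_kOM(link1, pr$P), error = function(e) NULL)
  if (is.null(ratio) || any(!is.finite(ratio[mask])) ||
      any(ratio[mask] <= 0)) {
    return(list(error = 1e10))
  }
  lnw <- mean(log(dataset$kOM_per_s[mask]) - log(ratio[mask]))
  res_I <- pr$current_pA - I_data
  res_k <- lnw + log(ratio[mask]) - log(dataset$kOM_per_s[mask])
  list(error = config$current_weight * sum(res_I^2) +
         config$ln_rate_weight * sum(res_k^2),
       w = exp(lnw), params = params)
}

default_init_params <- function(model, dataset, config) {
  flux_max <- max(abs(dataset$I_OF_pA)) * 1e-12 / channel_constants()$e
  k_scale <- max(6 * flux_max, 1e6)
  a_ref <- activity_from_concentration(100)
  ed <- model$edges
  br <- setNames(ifelse(ed$kind %in% c("bind_internal", "bind_external"),
                        k_scale / a_ref, k_scale), ed$param)
  V_T <- thermal_voltage()
  groups <- unique(stats::na.omit(ed$eyring_group))
  ey <- setNames(lapply(groups, function(g) list(s = 0.5, V_char = 2 * V_T)),
                 groups)
  rate_params(br, ey)
}

#' Global Simplex fit of IV and closing-rate curves
#'
#' Fits one shared permeation parameter set (plus the gating scale `w`) to
#' all IV and ln k_OM curves of a dataset by multi-start Nelder-Mead over
#' log rates, logit barrier positions and transformed characteristic
#' voltages, followed by a BFGS polish.  `w` is profiled analytically at
#' every objective evaluation.  Start values are perturbed log-normally
#' around the initial guess; all restart error sums are logged.
#'
#' @param dataset dataset in the [load_dataset()] schema.
#' @param model a `perm_model`.
#' @param link a [gating_link()] or link specification string.
#' @param config a [fit_config()].
#' @param init optional `rate_params` start values (default: a data-driven
#'   generic guess).
#' @return An object of class `perm_fit`: list with `params` (fitted
#'   `rate_params` including the profiled `w`), `link`, `error`,
#'   `per_curve` residual breakdown, `restart_errors`,
#'   `reversal_offsets_mV` (for unconstrained fits: the residual model
#'   reversal minus E_K per asymmetric series; `NULL` under the Nernst
#'   constraint, where it vanishes by construction), `convergence` and
#'   `config`.
#' @export
run_global_fit <- function(dataset, model, link, config = fit_config(),
                           init = NULL) {
  if (is.character(link)) link <- gating_link(link)
  link1 <- gating_link(link$label, w = 1)
  if (is.null(init)) init <- default_init_params(model, dataset, config)
  cond <- dataset_conditions(dataset)
  mask <- if (config$kom_mask == "negative") dataset$V_mV < 0 else
    rep(TRUE, nrow(dataset))
  mask <- mask & is.finite(dataset$kOM_per_s)
  if (!any(mask)) stop("no closing-rate data under the voltage mask")
  I_col <- if (config$fit_current == "I_OF") "I_OF_pA" else "I_true_pA"
  I_data <- dataset[[I_col]]

  obj <- function(theta) {
    objective_profiled(theta, model, link1, dataset, cond, mask, I_data,
                       config)$error
  }
  th0 <- encode_params(
    if (config$nernst) apply_nernst_constraint(model, init) else init,
    model, config)

  best <- NULL
  restart_errors <- numeric(config$restarts)
  for (r in seq_len(config$restarts)) {
    set.seed(config$seed + 7919L * r)
    th <- th0 + if (r == 1) 0 else
      rnorm(length(th0), sd = config$perturb_sd * log(10))
    o1 <- tryCatch(
      optim(th, obj, method = "Nelder-Mead",
            control = list(maxit = config$maxit, reltol = config$reltol)),
      error = function(e) NULL)
    if (is.null(o1)) { restart_errors[r] <- NA_real_; next }
    o2 <- o1
    if (config$polish) {
      o2 <- tryCatch(
        optim(o1$par, obj, method = "BFGS",
              control = list(maxit = config$polish_maxit,
                             reltol = 1e-12)),
        error = function(e) o1)
      if (o2$value > o1$value) o2 <- o1
    }
    restart_errors[r] <- o2$value
    if (is.null(best) || o2$value < best$value) best <- o2
  }
  if (is.null(best)) stop("all restarts failed to produce a finite objective")

  fin <- objective_profiled(best$par, model, link1, dataset, cond, mask,
                            I_data, config)
  params <- fin$params
  params$w <- fin$w
  link_fit <- gating_link(link$label, w = fin$w)
  brk <- global_objective(model, params, link_fit, dataset, config)
  # without the Nernst constraint the fitted cycle need not reverse at
  # E_K; report the residual reversal offset per asymmetric series rather
  # than hiding it
  rev_off <- NULL
  if (!config$nernst) {
    ser <- unique(dataset[dataset$c_in_mM != dataset$c_out_mM,
                          c("series_id", "c_in_mM", "c_out_mM")])
    rev_off <- vapply(seq_len(nrow(ser)), function(i) {
      EK <- nernst_potential(make_conditions(0, ser$c_in_mM[i],
                                             ser$c_out_mM[i]))
      f <- function(v) steady_current(model, params,
                                      make_conditions(v, ser$c_in_mM[i],
                                                      ser$c_out_mM[i]))$current_pA
      root <- tryCatch(stats::uniroot(f, c(EK - 60, EK + 60),
                                      tol = 1e-6)$root,
                       error = function(e) NA_real_)
      root - EK
    }, numeric(1))
    names(rev_off) <- ser$series_id
  }
  structure(list(params = params, link = link_fit, error = brk$error,
                 per_curve = brk$per_curve,
                 restart_errors = restart_errors,
                 reversal_offsets_mV = rev_off,
                 convergence = best$convergence, config = config),
            class = "perm_fit")
}

#' @export
print.perm_fit <- function(x, ...) {
  cat("Global fit with link", x$link$label,
      sprintf("| error sum %.6g | w = %.4g /s\n", x$error, x$params$w))
  print(x$params)
  invisible(x)
}

#' Compare gating links by global-fit error sums
#'
#' Runs one independent multi-start global fit per candidate link and
#' tabulates the best error sums; the link with the smallest error sum is
#' the selected gating mechanism.  A failing fit is reported as a row with
#' `NA` error instead of aborting the table.
#'
#' @param dataset,model,config as in [run_global_fit()].
#' @param links character vector of link specifications (default: every
#'   `P_m` and `1/P_m` plus, for models with states 3 and 4, `P4/P3`).
#' @param init optional shared start values.
#' @return A data.frame of class `link_comparison` with columns `link`,
#'   `error`, `converged`; attribute `best` holds the argmin link label
#'   (ties are reported in attribute `ties`), attribute `fits` the
#'   per-link `perm_fit` objects.
#' @export
compare_gating_links <- function(dataset, model,
                                 links = candidate_links(model),
                                 config = fit_config(), init = NULL) {
  fits <- vector("list", length(links))
  err <- rep(NA_real_, length(links))
  conv <- rep(FALSE, length(links))
  for (i in seq_along(links)) {
    cfg <- config
    cfg$seed <- config$seed + 104729L * i
    fits[[i]] <- tryCatch(
      run_global_fit(dataset, model, links[i], cfg, init = init),
      error = function(e) e)
    if (inherits(fits[[i]], "perm_fit")) {
      err[i] <- fits[[i]]$error
      conv[i] <- fits[[i]]$convergence == 0
    }
  }
  out <- data.frame(link = links, error = err, converged = conv)
  ok <- which(is.finite(err))
  best_i <- ok[which.min(err[ok])]
  ties <- links[which(abs(err - err[best_i]) < 1e-9 * max(err[best_i], 1))]
  structure(out, best = links[best_i],
            ties = if (length(ties) > 1) ties else NULL,
            fits = fits, class = c("link_comparison", "data.frame"))
}

# ---- reversal-drift correction and replicate averaging -------------------

#' Correct electrode-drift voltage offsets from the apparent reversal
#'
#' Fits a cubic polynomial to the IV curve near its zero crossing, locates
#' the apparent reversal potential and shifts the voltage axis so the
#' crossing lands on the expected Nernst potential.
#'
#' @param curve data.frame with columns `V` (mV) and `I` (pA), bracketing a
#'   sign change.
#' @param expected_EK expected reversal potential, mV.
#' @param window number of points around the crossing used for the fit.
#' @return A list with `offset` (detected apparent reversal minus
#'   `expected_EK`, mV), `apparent_reversal` and `curve` (the V-shifted
#'   data).
#' @export
drift_correct <- function(curve, expected_EK, window = 4) {
  stopifnot(all(c("V", "I") %in% names(curve)))
  curve <- curve[order(curve$V), ]
  sgn <- sign(curve$I)
  cross <- which(sgn[-length(sgn)] * sgn[-1] <= 0 &
                   (sgn[-length(sgn)] != 0 | sgn[-1] != 0))
  if (!length(cross)) stop("IV curve does not bracket a zero crossing")
  ctr <- cross[which.min(abs((curve$V[cross] + curve$V[cross + 1]) / 2 -
                               expected_EK))]
  idx <- max(1, ctr - window %/% 2 + 1):min(nrow(curve), ctr + window %/% 2)
  sub <- curve[idx, ]
  deg <- min(3, nrow(sub) - 1)
  fit <- lm(I ~ poly(V, deg, raw = TRUE), data = sub)
  cf <- rev(coef(fit))                       # highest degree first
  roots <- polyroot(rev(cf))
  real <- Re(roots[abs(Im(roots)) < 1e-6 * (abs(Re(roots)) + 1)])
  inside <- real[real >= min(sub$V) - 10 & real <= max(sub$V) + 10]
  if (!length(inside)) stop("no real reversal root near the crossing")
  if (length(inside) > 1) {
    warning("multiple reversal roots; choosing the one nearest E_K")
  }
  vrev <- inside[which.min(abs(inside - expected_EK))]
  offset <- vrev - expected_EK
  shifted <- curve
  shifted$V <- curve$V - offset
  list(offset = offset, apparent_reversal = vrev, curve = shifted)
}

#' Average replicate curves after cubic-spline interpolation
#'
#' Each replicate is interpolated by a cubic spline onto a common grid
#' restricted to the overlap of all replicates' abscissa ranges, then the
#' pointwise mean and sample standard deviation are returned.
#'
#' @param curves list of data.frames with columns `V` and `y`.
#' @param grid optional common grid (restricted to the overlap); default:
#'   the first replicate's points inside the overlap.
#' @return data.frame with columns `V`, `mean`, `sd`, `n`.
#' @export
spline_average <- function(curves, grid = NULL) {
  stopifnot(length(curves) >= 2)
  lo <- max(vapply(curves, function(cu) min(cu$V), numeric(1)))
  hi <- min(vapply(curves, function(cu) max(cu$V), numeric(1)))
  if (hi < lo) stop("replicate voltage ranges do not overlap")
  if (is.null(grid)) grid <- sort(unique(curves[[1]]$V))
  grid <- grid[grid >= lo & grid <= hi]
  if (!length(grid)) stop("empty common grid in the overlap")
  vals <- vapply(curves, function(cu) {
    splinefun(cu$V, cu$y, method = "fmm")(grid)
  }, numeric(length(grid)))
  data.frame(V = grid, mean = rowMeans(vals),
             sd = apply(vals, 1, sd), n = length(curves))
}
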