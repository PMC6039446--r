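#' Candidate links between filter occupation and the closing rate
#'
#' A gating link maps the steady-state occupation probabilities `P_m` of the
#' permeation model to the predicted sub-millisecond closing rate constant
#' `k_OM`, with a scale factor `w` (1/s) that is independent of voltage and
#' K+ concentration.  Three kinds are supported, written in the same
#' notation as the model-comparison tables:
#' * `"P3"` -- proportional: `k_OM = w * P_3` (conformational coupling),
#' * `"1/P3"` -- inverse: `k_OM = w / P_3` (flexibility coupling),
#' * `"P4/P3"` -- ratio: `k_OM = w * P_4 / P_3`.
#'
#' @param spec link specification string, e.g. `"P3"`, `"1/P3"`, `"P4/P3"`.
#' @param w scale factor (1/s, > 0).
#' @return An object of class `gating_link`.
#' @examples
#' gating_link("P4/P3", w = 2e3)
#' @export
gating_link <- function(spec, w = 1) {
  stopifnot(is.character(spec), length(spec) == 1, w > 0)
  spec <- gsub(" ", "", spec)
  if (grepl("^1/P[0-9]+$", spec)) {
    kind <- "inverse"; m <- sub("^1/P", "", spec); m2 <- NA_character_
  } else if (grepl("^P[0-9]+/P[0-9]+$", spec)) {
    kind <- "ratio"
    parts <- strsplit(sub("P", "", sub("/P", "/", spec)), "/")[[1]]
    m <- parts[1]; m2 <- parts[2]
  } else if (grepl("^P[0-9]+$", spec)) {
    kind <- "proportional"; m <- sub("^P", "", spec); m2 <- NA_character_
  } else {
    stop("cannot parse gating link spec '", spec, "'")
  }
  structure(list(kind = kind, m = m, m2 = m2, w = w, label = spec),
            class = "gating_link")
}

#' @export
print.gating_link <- function(x, ...) {
  cat("Gating link k_OM = w *", switch(x$kind,
      proportional = paste0("P", x$m),
      inverse = paste0("1/P", x$m),
      ratio = paste0("P", x$m, "/P", x$m2)),
      sprintf(" (w = %.4g /s)\n", x$w))
  invisible(x)
}

#' All occupancy-link candidates for a model
#'
#' The standard comparison set: `P_m` and `1/P_m` for every model state,
#' plus -- when the model has states 3 and 4 -- the ratio `P4/P3`.
#'
#' @param model a `perm_model`.
#' @return Character vector of link specification strings.
#' @export
candidate_links <- function(model) {
  st <- model$states
  out <- c(paste0("P", st), paste0("1/P", st))
  if (all(c("3", "4") %in% st)) out <- c(out, "P4/P3")
  out
}

#' Predict the closing rate constant from occupation probabilities
#'
#' @param link a [gating_link()].
#' @param P occupation probabilities: a named vector (one condition) or a
#'   matrix with state labels as column names (one row per condition).
#' @return Predicted `k_OM` (1/s), one value per condition.
#' @export
predict_kOM <- function(link, P) {
  stopifnot(inherits(link, "gating_link"))
  if (is.null(dim(P))) P <- matrix(P, 1, dimnames = list(NULL, names(P)))
  pick <- function(m) {
    if (!m %in% colnames(P)) stop("state '", m, "' not in occupation vector")
    unname(P[, m])
  }
  switch(link$kind,
    proportional = link$w * pick(link$m),
    inverse = {
      d <- pick(link$m)
      if (any(d < 1e-300)) stop("degenerate occupancy: P_", link$m,
                                " vanishes in an inverse link")
      link$w / d
    },
    ratio = {
      d <- pick(link$m2)
      if (any(d < 1e-300)) stop("degenerate occupancy: P_", link$m2,
                                " vanishes in a ratio link")
      link$w * pick(link$m) / d
    })
}

#' Collapse of predicted closing-rate curves against the K+ motive force
#'
#' When the internal K+ concentration is varied, measured closing-rate
#' curves superimpose when plotted against the K+ motive force
#' `Kmf = V - E_K` rather than against raw voltage.  This diagnostic
#' quantifies the phenomenon for model predictions: for a family of
#' condition series sharing a voltage grid it computes a collapse score --
#' the mean (over matched abscissa values) coefficient of variation of
#' `k_OM` across series -- both on the raw voltage axis and on the Kmf
#' axis, and fits the empirical saturating form
#' `P4/P3 ~ c2 / (c1 exp(f1 Kmf / V_T) + exp(f2 Kmf / V_T))`
#' to the pooled occupancy ratios by least squares on the log scale.
#'
#' @param model,params permeation model and parameters.
#' @param link a [gating_link()].
#' @param series named list of condition tables ([make_conditions()]), one
#'   per concentration series; at least two, sharing a voltage grid.
#' @param n_grid number of Kmf grid points in the common overlap.
#' @return A list with `score_kmf`, `score_v`, their `ratio`
#'   (`score_v / score_kmf`, large when Kmf collapses the curves), and --
#'   for models with states 3 and 4 -- `fit`: the fitted constants
#'   `c1`, `c2`, `f1`, `f2` and the residual sum of squares.
#' @export
kmf_collapse_diagnostic <- function(model, params, link, series,
                                    n_grid = 17) {
  if (length(series) < 2) {
    return(list(score_kmf = 0, score_v = 0, ratio = NA_real_, fit = NULL))
  }
  curves <- lapply(series, function(cond) {
    pr <- steady_profile(model, params, cond)
    data.frame(V = cond$V, Kmf = kmf(cond)$Kmf,
               kOM = predict_kOM(link, pr$P),
               ratio43 = if (all(c("3", "4") %in% model$states))
                 pr$P[, "4"] / pr$P[, "3"] else NA_real_)
  })

  cv <- function(x) sd(x) / mean(x)
  # raw-voltage axis: series share the grid
  Vg <- curves[[1]]$V
  if (!all(vapply(curves, function(cu) identical(cu$V, Vg), logical(1)))) {
    stop("series must share a voltage grid")
  }
  score_v <- mean(vapply(seq_along(Vg), function(i)
    cv(vapply(curves, function(cu) cu$kOM[i], numeric(1))), numeric(1)))

  # Kmf axis: spline-interpolate log k_OM onto the common overlap
  lo <- max(vapply(curves, function(cu) min(cu$Kmf), numeric(1)))
  hi <- min(vapply(curves, function(cu) max(cu$Kmf), numeric(1)))
  if (hi <= lo) stop("Kmf ranges of the series do not overlap")
  grid <- seq(lo, hi, length.out = n_grid)
  interp <- vapply(curves, function(cu) {
    exp(splinefun(cu$Kmf, log(cu$kOM), method = "fmm")(grid))
  }, numeric(n_grid))
  score_kmf <- mean(apply(interp, 1, cv))

  fit <- NULL
  if (all(c("3", "4") %in% model$states)) {
    pooled <- do.call(rbind, curves)
    V_T <- thermal_voltage()
    obj <- function(th) {
      c1 <- exp(th[1]); c2 <- exp(th[2]); f1 <- th[3]; f2 <- th[4]
      pred <- c2 / (c1 * exp(f1 * pooled$Kmf / V_T) +
                      exp(f2 * pooled$Kmf / V_T))
      sum((log(pred) - log(pooled$ratio43))^2)
    }
    init <- c(0, log(mean(pooled$ratio43)), 1, 0.3)
    opt <- optim(init, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10))
    fit <- list(c1 = exp(opt$par[1]), c2 = exp(opt$par[2]),
                f1 = opt$par[3], f2 = opt$par[4], residual = opt$value)
  }
  list(score_kmf = score_kmf, score_v = score_v,
       ratio = score_v / score_kmf, fit = fit)
}
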