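#' Load / write an experiment dataset (CSV)
#'
#' The dataset schema has one row per (series, voltage): `series_id`,
#' `c_in_mM`, `c_out_mM`, `V_mV`, `I_OF_pA`, `I_sd_pA`, `kOM_per_s`,
#' `kOM_sd`, `kMO_per_s`, `kMO_sd`, `n_rep`.  Loading validates column
#' presence, types, positivity of concentrations and rate constants,
#' non-negative standard deviations and a strictly increasing voltage grid
#' within every series; the first violation is reported with its row and
#' column.
#'
#' @param path CSV file path.
#' @return [load_dataset()] returns the validated data.frame.
#' @export
load_dataset <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_dataset(df)
}

#' @param dataset dataset data.frame.
#' @rdname load_dataset
#' @export
write_dataset <- function(dataset, path) {
  validate_dataset(dataset)
  write.csv(dataset, path, row.names = FALSE)
  invisible(path)
}

#' @rdname load_dataset
#' @export
validate_dataset <- function(dataset) {
  cols <- c("series_id", "c_in_mM", "c_out_mM", "V_mV", "I_OF_pA",
            "I_sd_pA", "kOM_per_s", "kOM_sd", "kMO_per_s", "kMO_sd",
            "n_rep")
  miss <- setdiff(cols, names(dataset))
  if (length(miss)) {
    stop("dataset lacks column(s): ", paste(miss, collapse = ", "))
  }
  fail <- function(rows, col, why) {
    stop("dataset validation failed at row ", rows[1], ", column '", col,
         "': ", why)
  }
  num_cols <- setdiff(cols, "series_id")
  for (cl in num_cols) {
    if (!is.numeric(dataset[[cl]])) fail(which(TRUE), cl, "not numeric")
    bad <- which(!is.finite(dataset[[cl]]))
    if (length(bad)) fail(bad, cl, "non-finite value")
  }
  for (cl in c("c_in_mM", "c_out_mM", "kOM_per_s", "kMO_per_s")) {
    bad <- which(dataset[[cl]] <= 0)
    if (length(bad)) fail(bad, cl, "must be > 0")
  }
  for (cl in c("I_sd_pA", "kOM_sd", "kMO_sd")) {
    bad <- which(dataset[[cl]] < 0)
    if (length(bad)) fail(bad, cl, "standard deviation must be >= 0")
  }
  for (sid in unique(dataset$series_id)) {
    v <- dataset$V_mV[dataset$series_id == sid]
    if (any(diff(v) <= 0)) {
      fail(which(dataset$series_id == sid)[which(diff(v) <= 0)[1] + 1],
           "V_mV", paste0("voltage grid of series '", sid,
                          "' not strictly increasing"))
    }
  }
  dataset
}

#' Write / read a trace fixture (CSV samples + JSON sidecar)
#'
#' The samples are stored as a two-column CSV (`time_s`, `current_pA`);
#' the sidecar JSON records the generating scheme, acquisition settings
#' and seed so the fixture is fully reproducible and scoreable.
#'
#' @param fixture a `trace_fixture` from [generate_trace_fixture()].
#' @param prefix file path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @return [read_trace_fixture()] returns a `trace_fixture`.
#' @export
write_trace_fixture <- function(fixture, prefix) {
  stopifnot(inherits(fixture, "trace_fixture"))
  tr <- fixture$trace
  df <- data.frame(time_s = seq_along(tr$samples) / tr$sample_rate,
                   current_pA = tr$samples)
  write.csv(df, paste0(prefix, ".csv"), row.names = FALSE)
  side <- list(scheme = unclass(fixture$scheme),
               config = unclass(fixture$config),
               seed = fixture$seed)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_trace_fixture
#' @export
read_trace_fixture <- function(prefix) {
  df <- read.csv(paste0(prefix, ".csv"))
  side <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  cfg <- trace_config(sample_rate = side$config$sample_rate,
                      cutoff = side$config$cutoff,
                      fine_dt = side$config$fine_dt,
                      baseline_sd = side$config$baseline_sd)
  tr <- structure(list(samples = df$current_pA,
                       sample_rate = cfg$sample_rate, cutoff = cfg$cutoff,
                       baseline_sd = cfg$baseline_sd,
                       fine_dt = cfg$fine_dt),
                  class = "trace_record")
  sc <- do.call(gating_scheme, side$scheme)
  structure(list(trace = tr, scheme = sc, seed = side$seed, config = cfg),
            class = "trace_fixture")
}

#' Write an amplitude histogram as CSV
#'
#' @param h an `amp_histogram`.
#' @param path CSV path (`bin_left`, `bin_right`, `count`).
#' @export
write_histogram <- function(h, path) {
  stopifnot(inherits(h, "amp_histogram"))
  write.csv(data.frame(bin_left = h$edges[-length(h$edges)],
                       bin_right = h$edges[-1], count = h$counts),
            path, row.names = FALSE)
  invisible(path)
}

#' Write a global-fit report (JSON)
#'
#' Serialises the fitted parameters, error breakdown and convergence
#' metadata of a [run_global_fit()] result.
#'
#' @param fit a `perm_fit`.
#' @param path JSON path.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "perm_fit"))
  doc <- list(link = fit$link$label, w = fit$params$w,
              base_rates = as.list(fit$params$base_rates),
              eyring = fit$params$eyring, error = fit$error,
              per_curve = fit$per_curve,
              restart_errors = fit$restart_errors,
              convergence = fit$convergence,
              config = unclass(fit$config))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a link-comparison table as CSV
#'
#' One row per candidate gating link with the best global-fit error sum;
#' the selected (argmin) link is marked.
#'
#' @param comparison a `link_comparison` from [compare_gating_links()].
#' @param path CSV path.
#' @export
write_link_table <- function(comparison, path) {
  stopifnot(inherits(comparison, "link_comparison"))
  df <- as.data.frame(comparison)
  df$best <- df$link == attr(comparison, "best")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Diagnostic overlay plots
#'
#' Quick ggplot2 overlays of the dataset (and optionally a fit): IV curves
#' or closing-rate curves per series, and occupation-probability profiles
#' of a fitted model.  Plots are diagnostic conveniences; all quantitative
#' results come from the fitting functions.
#'
#' @param dataset dataset in the [load_dataset()] schema.
#' @param fit optional `perm_fit`; overlays model curves.
#' @param model `perm_model` used with `fit`.
#' @return A ggplot object.
#' @export
plot_iv_overlay <- function(dataset, fit = NULL, model = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  p <- ggplot2::ggplot(dataset,
                       ggplot2::aes(x = .data$V_mV, y = .data$I_OF_pA,
                                    colour = .data$series_id)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "V (mV)", y = "I_OF (pA)") +
    ggplot2::theme_minimal()
  if (!is.null(fit) && !is.null(model)) {
    pr <- steady_profile(model, fit$params, dataset_conditions(dataset))
    md <- cbind(dataset, model_I = pr$current_pA)
    p <- p + ggplot2::geom_line(data = md,
                                ggplot2::aes(y = .data$model_I))
  }
  p
}

#' @rdname plot_iv_overlay
#' @export
plot_kom_overlay <- function(dataset, fit = NULL, model = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  neg <- dataset[dataset$V_mV < 0, ]
  p <- ggplot2::ggplot(neg,
                       ggplot2::aes(x = .data$V_mV, y = .data$kOM_per_s,
                                    colour = .data$series_id)) +
    ggplot2::geom_point(size = 0.8) + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "V (mV)", y = "k_OM (1/s)") +
    ggplot2::theme_minimal()
  if (!is.null(fit) && !is.null(model)) {
    pr <- steady_profile(model, fit$params, dataset_conditions(neg))
    md <- cbind(neg, model_k = predict_kOM(fit$link, pr$P))
    p <- p + ggplot2::geom_line(data = md,
                                ggplot2::aes(y = .data$model_k))
  }
  p
}

#' @param params a `rate_params` for the occupancy plot.
#' @param cond condition table for the occupancy plot.
#' @rdname plot_iv_overlay
#' @export
plot_occupancy <- function(model, params, cond) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  pr <- steady_profile(model, params, cond)
  long <- do.call(rbind, lapply(colnames(pr$P), function(st)
    data.frame(V = cond$V, state = paste0("P", st), P = pr$P[, st])))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$V, y = .data$P)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::labs(x = "V (mV)", y = "occupation probability") +
    ggplot2::theme_minimal()
}
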