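Package: permgate
Title: Model-Based IV-Curve and Fast-Gating Analysis of Potassium Channel
    Selectivity Filters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Steady-state Markov models of ion permeation through the
    selectivity filter of small potassium channels, with King-Altman
    (spanning-tree) steady states, Eyring voltage-dependent rate constants
    and activity-proportional binding steps. Links filter occupation
    probabilities to the sub-millisecond closing rate of the channel,
    performs global Simplex fits of current-voltage and closing-rate curves
    over many ionic conditions, discriminates permeation models and gating
    links by error sums, and reimplements the extended-beta-distribution
    machinery: stochastic simulation of gating, Bessel-filtered current
    traces, amplitude histograms convolved with baseline noise, and
    histogram fitting to recover gating rate constants beyond the recording
    bandwidth. Ships a synthetic-data generator emulating an 18-condition
    symmetric/asymmetric KCl single-channel study.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
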