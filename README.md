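# permgate

Model-based IV-curve and fast-gating analysis of potassium-channel
selectivity filters.

## The problem

Some small K⁺ channels (e.g. the viral Kcv channels) gate in a strongly
voltage-dependent way although they have no voltage-sensor domain.  Their
sub-millisecond closing process — closed dwells of 50–150 µs, far too fast
for ordinary dwell-time analysis — produces an apparent negative slope in
the single-channel IV curve.  The working hypothesis is that the
selectivity filter itself is the sensor: the occupation of its ion binding
sites (S0–S4) changes with voltage and K⁺ concentration, and the closing
rate constant k_OM follows that occupation.

`permgate` is for electrophysiologists and modellers who want to test this
hypothesis quantitatively on single-channel data.  It provides:

* **Ion-hopping permeation models** of the filter as cyclic Markov chains
  (5-state, 4-state and an approximate direct knock-on topology, shipped
  as JSON), with activity-proportional binding steps and Eyring
  voltage-dependent translocation steps
  `k_ij(V) = k_ij,0 · exp(s·V / V_char)`.
* **King–Altman steady states**: occupation probabilities
  `P_m = D_m / Σ D_m` (dense linear solve, with an exhaustive
  spanning-tree enumeration as an independent oracle) and open-channel
  currents `I = e · (Π k_fwd − Π k_bwd) / Σ D_m`.
* **Gating links** `k_OM = w·P_m`, `w/P_m`, `w·P4/P3` mapping occupation
  to the closing rate, plus Nernst/K⁺-motive-force utilities and a curve
  collapse diagnostic.
* **A global Simplex fit** of all IV and ln k_OM(V) curves over an entire
  symmetric/asymmetric concentration design with one shared parameter
  set, and an error-sum comparison table across all candidate links.
* **The extended-beta-distribution engine**: stochastic simulation of the
  O/S/M/F gating scheme, rendering through a digital 4-pole Bessel
  low-pass, amplitude histograms convolved with baseline noise, and
  Simplex histogram fitting that recovers rate constants faster than the
  recording bandwidth together with the true open-channel current.
* **A synthetic-data module** that generates the full 18-condition study
  (and raw-trace fixtures with known gating truth), so the entire
  pipeline is testable without access to recordings.

## A worked example

```r
library(permgate)

model <- shipped_model("five_state_roux")
truth <- default_ground_truth()          # synthetic reference parameters

# currents and occupation at symmetric 100 mM KCl
cond <- make_conditions(V = c(-120, 120), c_in = 100, c_out = 100)
iv_curve(model, truth$params, cond)[, c("V", "current_pA")]
#>      V current_pA
#> 1 -120     -6.008
#> 2  120     10.587

P <- steady_state(build_generator(model, truth$params, cond[1, ]))
round(P, 4)
#>      1      2      3      4      5
#> 0.2478 0.3323 0.0052 0.0401 0.3746
predict_kOM(truth$link, P)      # closing rate at -120 mV: w * P4/P3
#> [1] 10102.6

nernst_potential(make_conditions(0, 1000, 100))
#> [1] -52.99   # mV; the fitted model reverses exactly here

# generate a noisy synthetic study and refit it globally
ds  <- generate_dataset(truth, default_design(), noise = TRUE, seed = 7)
fit <- run_global_fit(ds, model, "P4/P3",
                      fit_config(restarts = 3, maxit = 1500, seed = 7))
fit
#> Global fit with link P4/P3 | error sum 23.9713 | w = 1124 /s
#> Rate parameter set: 10 base rates
#>       k12       k21       k23       k32       k34  ...
#> 1.232e+07 7.119e+08 5.143e+08 1.122e+09 5.337e+08  ...
#>   g23: s = 0.203, V_char = 31.16 mV
#>   g51: s = 0.765, V_char = 146.50 mV
```

At −120 mV the outermost site S0 is almost depleted (P₃ ≈ 0.005), which
is what drives the fast closing rate up to ~10⁴ s⁻¹ through the
`w·P4/P3` link.  The refitted base rates land within a few percent of the
generating values despite 15% replicate noise on the rate constants, and
`compare_gating_links()` reproduces the error-sum table that discriminates
the occupancy–gating couplings.

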