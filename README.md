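# mmlineage

Statistics of single-cell lineages in mother-machine microfluidic devices.

A mother machine traps one cell lineage per dead-end growth channel: growth
pushes progeny out of the open end, so one cell per channel can be followed
for arbitrarily many generations under constant conditions. Time-lapse
imaging of such devices yields, per channel, the times of every division and
death event. `mmlineage` implements the statistical analysis of such event
tables, motivated by long-term tracking of mouse lymphocytic leukemia
(L1210) cells, where a minority of slow-cycling lineages persists for
generations and survives drug exposure differently from fast-cycling ones.

The package covers:

* **Data model** (`read_events`, `extract_cycles`,
  `ancestor_descendant_pairs`, `filter_lineages`): a CSV event-table dialect,
  extraction of complete cell cycles (the incomplete first and last
  generations are excluded), and ancestor–descendant pair construction.
* **Generation-time model** (`mixture_pdf`, `mixture_survival`,
  `two_stage_fit`, `mle_fit`, `single_shifted_exponential_fit`,
  `slow_cycling_cutoff`, `classify_lineages`): the mixed shifted-exponential
  distribution

  g(τ) = (1−a)·λ₁e^(−λ₁(τ−τ₀)) + a·λ₂e^(−λ₂(τ−τ₀)),  τ ≥ τ₀,

  with survival function B(τ) = (1−a)e^(−λ₁(τ−τ₀)) + a·e^(−λ₂(τ−τ₀)): a
  fixed no-division period τ₀, a fast component with decay constant λ₁ and a
  slow-cycling fraction `a` with decay constant λ₂. Both the two-stage
  survival-window fitting recipe (descriptive, with a documented window
  bias) and a consistent EM maximum-likelihood fit are provided, plus the
  survival-threshold cutoff and the fast/slow lineage classification rule.
* **Growth statistics** (`cumulative_division_probability`,
  `fit_division_rate`, `death_rate`, `correlation`, `autocorrelation`,
  `one_pair_per_lineage_correlation`, `intra_lineage_correlations`,
  `division_count_distribution`): division and death rates under balanced
  growth, and the full heritability toolkit for generation times.
* **Correlation-dimension analysis** (`embed_lineages`,
  `correlation_integral`, `estimate_dimension`, `gp_analysis`): the
  Grassberger–Procaccia method on ensembles of short lineage series,
  C^m(r) = N⁻² Σ_{i≠j} I(r − |T^m(i) − T^m(j)|), distinguishing stochastic
  generation-time dynamics (dimension estimates grow with the embedding
  dimension m) from deterministic ones (estimates saturate).
* **Drug response** (`split_phases`, `stratified_survival`): phase splitting
  at drug-exposure onset and survival curves stratified by pre-exposure
  growth state.
* **Synthetic lineages** (`generator_config`, `simulate_lineages`,
  `calibrate_copula`, `sample_mixture`, `sample_shifted_gamma`,
  `deterministic_series`, `pseudo_lineage_division_counts`): a generator
  whose generation times follow the mixture marginal exactly while a
  lineage-persistent-plus-AR(1) Gaussian copula reproduces the observed
  two-timescale heritability (mother–daughter correlation ≈ 0.62 decaying
  to ≈ 0.20 at lag 10), with constant baseline death hazard and an optional
  delayed, state-dependent drug-killing phase.

## Worked example

```r
library(mmlineage)

p <- l1210_params()        # lambda1 = 0.571/h, lambda2 = 0.134/h,
print(p)                   # tau0 = 8.375 h, a = 0.060
#> Mixed shifted-exponential generation-time model
#>   lambda1 = 0.571 /h (fast), lambda2 = 0.134 /h (slow)
#>   tau0 = 8.375 h, slow fraction a = 0.06
#>   mean generation time = 10.47 h

mixture_survival(14, p)            # 0.0661: ~6.6% of newborns undivided at 14 h
slow_cycling_cutoff(p, 0.06)       # 14.265 h: where B(tau) first drops to 0.06

# simulate a seven-day experiment: 500 channels, 10-min frames
ev  <- simulate_lineages(generator_config(n_channels = 500, seed = 1))
cyc <- extract_cycles(ev)
nrow(cyc)                          # 6022 complete cell cycles

print(mle_fit(cyc$tau_h))
#> Generation-time model fit (mle)
#>   lambda1 = 0.5882 +/- 0.012 /h
#>   lambda2 = 0.1506 +/- 0.021 /h
#>   tau0    = 8.333 +/- 0.00029 h
#>   a       = 0.04415 +/- 0.013
#>   objective = -9817.28

r <- correlation(ancestor_descendant_pairs(cyc, 1), "pearson")
sprintf("mother-daughter r = %.3f +/- %.3f (n = %d)", r$estimate, r$se, r$n)
#> "mother-daughter r = 0.624 +/- 0.008 (n = 5537)"

dr <- death_rate(ev)
sprintf("death rate = %.3g +/- %.2g per h", dr$rate_per_h, dr$se)
#> "death rate = 0.00243 +/- 0.00021 per h"
```

The fitted parameters recover the generator's marginal (within sampling
error; `tau0` is estimated by the sample minimum of frame-snapped times),
the mother–daughter correlation matches the calibration target 0.62, and
the death rate recovers the generative hazard 2.239e-3 per hour.

A command-line wrapper ships with the package
(`system.file("cli", "mmlineage", package = "mmlineage")`) with subcommands
`simulate | fit | stats | gpdim | drug | report`; see `?run_command`.

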