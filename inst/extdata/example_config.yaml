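# Example configuration for the mmlineage command-line wrapper.
# Unset keys fall back to the package defaults (see ?default_config).
generator:
  marginal:
    lambda1: 0.571      # fast decay constant, per hour
    lambda2: 0.134      # slow decay constant, per hour
    tau0: 8.375         # minimum cell-cycle length, hours
    a: 0.060            # slow-cycling fraction
  lineage_var_frac_c: 0.382
  ar1_phi: 0.583
  n_channels: 500
  window_h: 168         # seven days
  dt_h: 0.16666667      # 10-min frames
  baseline_hazard_per_h: 0.002239
  seed: 1
  drug:
    exposure_start_h: 96
    onset_delay_h: 50
    hazard_fast_per_h: 0.02
    hazard_slow_per_h: 0.002
    fast_threshold: 7
analysis:
  stage1_window: [10, 12]   # hours; fast-component survival window
  stage2_window: [25, 42]   # hours; slow-component survival window
  survival_threshold: 0.06
  tau_cutoff_h: 14.0
  classification_window_h: 96
  min_divisions: 5
  m_range: [1, 6]
  n_resamples: 1000
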