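# Two-year synthetic-city demo: simulate, build metrics, fit the 124-cell
# relative-risk grid, and write all artifacts plus the truth ledger.
simulation:
  years: 2
  cadence_minutes: 15
  seed: 7
  effect_hour: 15
  effect_lag: 0
  effect_slope: 0.0064
  missing_fraction: 0.01
analysis:
  df_per_year: 5
  baseline: 85
  k_temp: 4
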