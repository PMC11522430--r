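# Preset: monthly global sea surface temperature anomalies.
# Point 'input' at a CSV with (date, anomaly_degC) columns, e.g. the
# NOAA global ocean monthly series.
input: null
time_col: 1
value_col: 2
time_unit: month
label: GSST
detrend:
  method: linear
msd:
  max_lag_fraction: 0.25
  anchored: false
fit:
  n_bootstrap: 500
  t_c: 1.0
  weights: none
pdd:
  horizons: [2.0, 3.0, 4.0]
  delta_x: 1.5
seed: 1
output_dir: null
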