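# Preset: weekly atmospheric CO2 concentrations (Keeling-curve style).
# Point 'input' at a CSV with (date, ppm) columns.
input: null
time_col: 1
value_col: 2
time_unit: week
label: CO2
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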