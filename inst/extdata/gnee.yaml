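# Preset: monthly global net ecosystem exchange (PgC/month), e.g. a
# 120-point assimilated flux product. Spectral detrending strips the
# seasonal carbon cycle and its harmonics.
input: null
time_col: 1
value_col: 2
time_unit: month
label: GNEE
detrend:
  method: fourier
  spike_threshold: 4.0
  max_spikes: 8
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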