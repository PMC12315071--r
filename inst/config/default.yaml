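# Default pipeline configuration: the counteracting-pathways scenario
# at the study scale (5 transects x 7 stations x 2 paired tiles,
# 11 censuses).
mode: synthetic
seed: 1
alpha: 0.05
n_boot: 200
design:
  n_transects: 5
  stations_per_transect: 7
  emersion_range: [0.1, 0.9]
synth:
  seed: 1
  n_censuses: 11
  ar1_rho: 0.4
  noise_sd: 0.6
  n_points: 500
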