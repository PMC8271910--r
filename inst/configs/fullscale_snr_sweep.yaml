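# Full-scale SNR sweep on a user-supplied anatomical model: 100 test
# dipoles, 1000 white-noise patterns per SNR level in {0,10,20,30,Inf} dB.
# Run with:  cardiosource sweep --config fullscale_snr_sweep.yaml --out out/
model:
  path: "taro.raw"
electrodes: "taro_electrodes.csv"
solver:
  tol: 1.0e-6
  levels: 6
  method: "multigrid"
lfm:
  spacing_mm: 6
study:
  n_dipoles: 100
  seed: 1
sweep:
  snr_grid: [0, 10, 20, 30, ".inf"]
  n_noise: 1000
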