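# Full-scale R-wave tracking on a user-supplied anatomical model.
# x0_mm must be set to the AV-node location digitised on the model
# (initial Kalman state); Q and R are calibrated automatically from a
# 100-dipole study and ten 500-point LFM sub-dictionaries when left null.
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
  snr_db: 20
  seed: 1
track:
  v_m_s: 1.9
  dt_s: 0.001
  n_steps: 34
  Q: null
  R: null
  x0_mm: null
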