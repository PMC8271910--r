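# Full-scale study configuration for a user-supplied whole-body anatomical
# voxel model (e.g. the TARO model from NICT: 51 tissues, 2 mm pitch,
# convert to raw little-endian + JSON sidecar as described in ?save_model).
# Electrode coordinates must be digitised on the model surface by the user.
# Expect hours of runtime: ~900 source points x 3 directions of forward
# solves at whole-body scale.
model:
  path: "taro.raw"          # user-supplied; not redistributable
electrodes: "taro_electrodes.csv"
solver:
  tol: 1.0e-6
  levels: 6
  omega: 1.5
  method: "multigrid"
lfm:
  spacing_mm: 6
study:
  n_dipoles: 100
  snr_db: ".inf"
  seed: 1
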