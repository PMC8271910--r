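# Quick-demo configuration: self-contained block-torso phantom, reduced to
# 24^3 voxels so the whole study runs in well under a minute. Remove the
# `model.phantom` block to use the 40^3 default phantom.
model:
  phantom:
    dims: [24, 24, 24]
    pitch_mm: 2
solver:
  method: "multigrid"
  tol: 1.0e-6
lfm:
  spacing_mm: 6
study:
  n_dipoles: 25
  snr_db: 20
  seed: 1
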