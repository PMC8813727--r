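# 2D field with the regular wizard hat (kappa_s < 0): a lattice of
# localised spots whose cores oscillate while the tissue in between
# stays at a constant low rate.
model: field2d
params:
  eta0: 0.1
  kappa_v: 1.0
  kappa_s: -25
  tau: 1
  alpha: 5
  gamma: 0.5
  c: 10
  "n": 64
  L: 40
experiment:
  ic: gaussian-bump
  amplitude: 0.06
numerics:
  T: 120
  record_dt: 0.5
outdir: out/fig12_spots
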