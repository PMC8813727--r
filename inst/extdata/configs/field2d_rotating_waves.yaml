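# 2D field beyond the dynamic Turing instability: rotating waves with
# alternating senses of rotation (lattice-seeded).
model: field2d
params:
  eta0: 2
  kappa_v: 0.695
  kappa_s: 12
  tau: 20
  alpha: 0.5
  gamma: 0.5
  c: 1
  "n": 64
  L: 40
experiment:
  ic: periodic-lattice
  amplitude: 0.015
  cells: 5
numerics:
  T: 3000
  record_dt: 4
outdir: out/fig10_rotating
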