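# 1D field just above the Hopf threshold at slow axonal speed: bulk
# oscillation (no spatial structure).
model: field1d
params:
  eta0: 1
  kappa_v: 0.85
  kappa_s: 10
  tau: 15
  alpha: 0.5
  gamma: 0.5
  c: 0.1
  "n": 256
  L: 50.26548
experiment:
  ic: uniform+noise
  amplitude: 0.002
numerics:
  T: 2000
  record_dt: 4
outdir: out/fig8_bulk
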