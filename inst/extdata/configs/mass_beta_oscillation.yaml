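# Single-population limit cycle (beta-band oscillation).
model: mass
params:
  eta0: 1
  kappa_v: 1.2
  kappa_s: 1
  tau: 15
  alpha: 0.5
  gamma: 0.5
numerics:
  T: 2000
  dt: 0.5
outdir: out/fig4_mass
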