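# Two-population E-I network in the seizure-like bursting regime.
model: ei
params:
  eta0_E: 5
  eta0_I: -3
  kappa_v_E: 0.5
  kappa_v_I: 0.5
numerics:
  T: 500
  dt: 0.02
outdir: out/fig6_ei
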