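# Spiking-network validation run: 1000 QIF neurons whose population
# statistics should match the mean-field mass model.
model: network
params:
  N: 1000
  eta0: 2
  gamma: 0.5
  tau: 16
  kappa_v: 1
  kappa_s: 1
  alpha: 0.5
  dt: 0.05
  T: 1200
outdir: out/fig2_network
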