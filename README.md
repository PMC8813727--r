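# nmfield

Next-generation neural mass and neural field models with gap junctions,
in R.

## What this package is for

Coarse-grained models of brain rhythms (Wilson–Cowan, Jansen–Rit, ...)
are phenomenological: they cannot say anything about *within-population
synchrony*, which is what EEG/MEG band power actually reflects. A newer
family of models is derived **exactly** from networks of quadratic
integrate-and-fire (QIF) neurons with Lorentzian-distributed drives: in
the large-N limit the population is described by its firing rate R and
mean voltage V,

    tau R' = -kappa_v R + 2 R V + gamma / (pi tau)
    tau V' = eta_0 + V^2 - pi^2 tau^2 R^2 + kappa_s U,

with synaptic activity U driven by the rate through
(1 + alpha^-1 d/dt)^2 U = R. Electrical (gap-junction) coupling of
strength `kappa_v` damps the rate equation directly; chemical coupling
of strength `kappa_s` acts through U. The complex Kuramoto order
parameter is recovered from (R, V) by a conformal (Möbius) map

    Z = (1 - W*) / (1 + W*),   W = pi tau R + i V,

so the same simulation yields both a local-field-potential-like view
(V) and a synchrony view (|Z|). Spatial tissue is modelled by coupling
such masses over a continuum with a balanced "wizard-hat" kernel and
axonal conduction delays |r - r'|/c.

The package implements, and tests against each other:

- `simulate_qif_network()` — the microscopic spiking network (the
  ground truth the mean field must reproduce);
- `simulate_mass()`, `simulate_ei()` — one- and two-population mass
  models, with `to_kuramoto()` / `from_kuramoto()`;
- `simulate_field_1d()`, `simulate_field_2d()` — delayed neural fields
  on periodic domains (bulk oscillations, standing/travelling waves,
  rotating spirals, localised oscillating spots), with a
  direct-summation reference solver as the numerical contract;
- `dispersion_relation()`, `critical_threshold()`,
  `instability_curves()`, `hopf_locus_mass()` — linear stability of the
  uniform state: Hopf, Turing and Turing–Hopf onsets, two-parameter
  instability curves and their codimension-2 crossing;
- `sweep_attractors()`, `hopf_point_1param()` — attractor sweeps and
  bistability windows for the E–I model;
- `band_power_spectrogram()`, `beta_rebound_experiment()` — Morlet/STFT
  time–frequency observables and the movement-related beta-rebound
  experiment;
- `load_config()`, `run_config()` and a thin CLI
  (`inst/exec/nmfield-run`) with shipped YAML fixtures for the main
  experiments.

## Worked example

Where does a single excitatory population start to oscillate as
gap-junction coupling grows, and what rhythm does it produce?

```r
library(nmfield)

p <- mass_params(eta0 = 1, kappa_s = 1, tau = 15, alpha = 0.5, gamma = 0.5)

# Hopf point in kappa_v, from the fixed-point Jacobian
h <- hopf_point_1param(p, bracket = c(0.3, 1.4))
h$value
#> [1] 0.9714656
1000 * h$omega / (2 * pi)   # frequency at onset, Hz
#> [1] 21.37315

# beyond the Hopf point: a beta-band limit cycle
run <- simulate_mass(set_param(p, "kappa_v", 1.2), T = 2000, dt = 0.25)
run$summary
#> $min        [1] 0.008390797
#> $max        [1] 0.05977003
#> $period     [1] 47.25
#> $n_peaks    [1] 21
#> $oscillatory [1] TRUE
```

With `kappa_v = 1.2` the population sits on a stable limit cycle: the
firing rate swings between about 0.008 and 0.06 spikes/ms with a 47 ms
period (≈21 Hz, beta band), and the synchrony |Z| computed through the
conformal map peaks together with the rate. Below `h$value` the same
model spirals into a stable fixed point.

The same machinery scales up: `instability_curves()` reproduces the
(c, kappa_v) stability diagram of the 1D field — for slow axonal speeds
the first instability is a bulk Hopf, for faster speeds a Turing–Hopf
that spawns travelling waves — and `simulate_field_2d()` produces
rotating waves whose local synchrony range grows with gap-junction
coupling.

A ready-made experiment from the command line:

```sh
inst/exec/nmfield-run --list-fixtures
inst/exec/nmfield-run --fixture mass_beta_oscillation --out out/demo
```

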