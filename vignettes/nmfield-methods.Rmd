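---
title: "Models and numerical methods in nmfield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in nmfield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nmfield)
```

# The models

## Microscopic network

The microscopic substrate is a heterogeneous, all-to-all network of $N$
quadratic integrate-and-fire (QIF) neurons with both chemical and
electrical coupling,

$$\tau \dot v_i = \eta_i + v_i^2
  + \frac{\kappa_v}{N}\sum_j (v_j - v_i)
  + \frac{\kappa_s}{N}\sum_j \sum_m s(t - T_j^m),$$

with reset $v_i \to v_r$ on upward passage of $v_{\rm th}$ and the
post-synaptic response $s(t) = \alpha^2 t e^{-\alpha t}$, the Green's
function of $Q = (1 + \alpha^{-1}\,\mathrm d/\mathrm dt)^2$.  The
background drives $\eta_i$ are Lorentzian with median $\eta_0$
(excitability) and half-width $\gamma$ (heterogeneity): this specific
heterogeneity is what makes an *exact* mean-field closure possible.
Time is in milliseconds throughout; with $\tau \sim 15$ ms the
single-population rhythms land in the beta band, which fixes the unit.

## Mean field

In the thermodynamic limit the network reduces exactly to the
firing-rate/voltage pair

$$\tau \dot R = -\kappa_v R + 2RV + \gamma/(\pi\tau), \qquad
  \tau \dot V = \eta_0 + V^2 - \pi^2\tau^2R^2 + \kappa_s U,$$

with $QU = R$ kept in state-space form
$\ddot U = \alpha^2(R - U) - 2\alpha\dot U$ (exactly equivalent to the
operator form).  Gap junctions appear as the linear damping
$-\kappa_v R$ of the rate — they shift the balance toward synchrony
without entering the voltage equation.  The within-population synchrony
is not an extra state: the Kuramoto order parameter is obtained from
$(R, V)$ through the Möbius map $Z = (1 - W^*)/(1 + W^*)$,
$W = \pi\tau R + iV$, which maps the physical half-plane $R \ge 0$ into
the unit disc.  The package never integrates a $Z$ equation; `absZ` and
`theta` columns are always computed pointwise through this map, and the
inverse map is used in tests as an algebraic oracle.

External stimulation enters as $\eta_0 \to \eta_0 + A(t)$;
`filtered_pulse()` provides the low-pass-filtered square pulse used in
the movement (beta-rebound) experiments.

## Two populations

`ei_params()`/`simulate_ei()` implement the excitatory–inhibitory
extension: each population keeps its own $(R_a, V_a)$ with
within-population gap junctions only, and four synaptic variables
$U_{ab}$ with independent kinetics $\alpha_{ab}$, driven by the source
rate, $Q_{ab} U_{ab} = R_b$.  **Convention:** the first index is the
target, so `kappa_s_IE = 25` is the excitatory drive onto the
inhibitory population.  This wiring convention is not fixed by the
equations alone; we fixed it by
simulation: with target-first wiring the model reproduces the
seizure-like bursting regime, the intermediate-drive oscillation window
without gap junctions, and — quantitatively — the low-amplitude
inhibitory branch that sits at $R_I \approx 0.7$ when only the
excitatory population has gap junctions.  Both alternative
cross-pairings of $(\kappa, \alpha)$ fail these checks and were
rejected.

## Neural field

`simulate_field_1d()`/`simulate_field_2d()` extend the mass model over
periodic 1D/2D domains: the local dynamics hold pointwise, and the
synaptic operator is driven by the delayed non-local input

$$\Psi(\mathbf r, t) = \int w(|\mathbf r - \mathbf r'|)\,
  R(\mathbf r', t - |\mathbf r - \mathbf r'|/c)\,\mathrm d\mathbf r',$$

with axonal speed $c$ and the balanced (inverted) wizard-hat kernels
$w(x) = (|x| - 1)e^{-|x|}$ (1D) and $w(r) = (r/2 - 1)e^{-r}/(2\pi)$
(2D).  The regular wizard hat is the same shape with $\kappa_s < 0$.
Gap junctions remain purely local: masses interact only synaptically.

# Linear stability

Because the kernel is balanced, the spatially uniform steady state
solves the mass fixed-point equations with the synaptic term absent
(`uniform_steady_state()`), independent of $\kappa_s$.  Linearising
about it with $e^{\lambda t + ikx}$ and eliminating the synaptic
variable gives the dispersion function

$$E(k, \lambda) = (\tau\lambda + \kappa_v - 2V_0)(\tau\lambda - 2V_0)
  \left(1 + \tfrac{\lambda}{\alpha}\right)^2
  + 4\pi^2\tau^2R_0^2\left(1 + \tfrac{\lambda}{\alpha}\right)^2
  - 2R_0\kappa_s\,G(k, \lambda),$$

where $G$ is the spatial Fourier transform of
$w(\cdot)e^{-\lambda|\cdot|/c}$ (`transfer_function()`), in closed form
in both dimensions with $\beta = 1 + \lambda/c$ and the branch
condition $\mathrm{Re}\,\beta > 0$.  Both closed forms are verified
against adaptive quadrature in the test suite.

In 1D, $G$ is rational in $\beta$, so $E(k,\cdot) = 0$ clears to a
degree-8 polynomial: `leading_eigenvalue()` takes all `polyroot()`
roots, polishes them by Newton, discards acausal roots
($\mathrm{Re}\,\beta \le 0$) and any artefacts of the cleared
denominator (checked against the original residual), and returns the
root of largest real part.  In 2D the half-integer powers preclude
clearing; a damped Newton iteration with multi-start (mass-model
spectrum, continuation in $k$) is used instead, and is cross-checked
against the polynomial path in 1D.

Bifurcation geometry:

* `critical_threshold()` bisects a parameter (usually $\kappa_v$) on
  $\max_k \mathrm{Re}\,\lambda(k) = 0$ and classifies the onset by
  $(k_c, \omega_c)$ with $\varepsilon_k = \varepsilon_\omega = 10^{-3}$:
  Hopf ($k_c \approx 0$, $\omega_c > 0$), Turing ($k_c > 0$,
  $\omega_c \approx 0$), Turing–Hopf (both positive).
* The **patterned branch** is traced by the largest *interior* local
  maximum of $\mathrm{Re}\,\lambda(k)$ beyond the initial descent from
  $k = 0$: a plain maximum over $k > 0$ would be shadowed by the tail
  of the bulk mode near the Hopf.  The wavenumber window is capped at
  $k = 3$ and the speed sweep starts at $c = 0.05$: for slower
  conduction the delay structure spawns additional short-wavelength
  resonance branches (local maxima near $k \approx 5$ at $c = 0.02$)
  that belong to a different family than the one the two-parameter
  diagram follows; rows whose $k_c$ pins at the window edge are
  excluded from the codimension-2 crossing detection.
* `instability_curves()` assembles both loci over $c$, locates the
  codimension-2 speed where they exchange order by bisection, and the
  minimum first-instability coupling over the sweep.
* `hopf_locus_mass()` traces the mass-model Hopf locus in
  $(\kappa_v, \eta_0)$ for several $\gamma$; the oscillatory window
  shrinks with heterogeneity.

# Numerics

## Network integrator

Fixed-step integration with step `dt` (default $0.01\tau$).  Explicit
Euler alone cannot traverse the spike sweep at $v_{\rm th} = 1000$: a
step at $|v| \sim 1000$ moves by $\sim v^2\,\mathrm dt/\tau$, skipping
the slow region entirely.  Wherever
$|v| \ge \max(50, 0.05\,|v_{\rm th}|)$ — where the drive is below ~2%
of $v^2$ — the update uses the exact solution of $\tau\dot v = v^2$,
$v \mapsto v/(1 - v\,\mathrm dt/\tau)$, with the analytic passage time
$\tau(1/v - 1/v_{\rm th})$ locating the spike inside the step; reset is
instantaneous with no refractory period, and the remainder of the step
is evolved exactly from $v_r$.  The single-neuron period then matches
$\pi\tau/\sqrt\eta$ to 0.13% at `dt = 0.02`.

All-to-all synapses are implemented as one shared second-order filter
driven by the population spike density (count per step / $N\,$dt) —
mathematically identical to per-spike kernels, $O(N)$ per step.
Heterogeneity uses equally spaced Lorentzian quantiles by default
(reproducible, tail-controlled); i.i.d. Cauchy draws sit behind
`eta_mode = "random"`.

Population observables: $R(t)$ counts spikes in a centred window
(default 10 ms for display, 5 ms in validation tests); $V(t)$ averages
voltages excluding neurons within 1 ms of a reset (a de-spiking choice:
the blanking suppresses the spike artefact in the population mean);
$Z(t)$ averages $e^{2i\arctan v_j}$ (theta-phase transform).  The mean
voltage retains an $O(0.1)$ finite-size bias — the underlying voltage
distribution is Lorentzian, whose sample mean converges slowly — so
voltage agreement is judged on the O(1) voltage scale rather than
relative to its near-zero mean.

## Mass and E–I integration

`deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`.  A trajectory is
classified oscillatory when, after discarding a 50% transient, the
peak-to-peak amplitude of $R$ exceeds $10^{-4}$ with at least 5 periods
observed; periods come from mean peak spacing, with sub-quarter-amplitude
ripples ignored.

## Field solver

Method of lines with Heun (explicit trapezoid) stepping; the step obeys
`dt <= 0.25 dx / c` and `dt <= 0.01 tau` (violations are refused with a
suggested step).  The delayed convolution is evaluated spectrally per
*delay shell*: grid offsets are grouped by minimum-image distance (each
exact distance is its own shell in 1D; bins of width `dx` with the
$|w|$-weighted mean delay in 2D), each shell has one conduction delay
and a precomputed spatial Fourier transform, and the rate history is
stored as FFTs in a ring buffer with linear interpolation between
slices.  On a periodic grid this is algebraically identical to the
direct sum in 1D and differs only by the delay binning in 2D; the
direct-summation stepper `simulate_field_reference()` is the contract,
and the suite pins the spectral solver to it (1D to $10^{-12}$, 2D to
$10^{-4}$ relative).  The kernel is truncated where
$|w| < 10^{-8}$ ($d \approx 21$), and the discrete kernel is
re-balanced by absorbing the (order $10^{-3}$) quadrature imbalance of
the grid sum into the zero-distance weight, so a uniform steady rate
receives exactly zero drive, as in the continuum.  Note the balanced
kernel annihilates only *steady* uniform rates: a uniform rate that
varies in time feels its own history through the delay spread, which is
physical, vanishes as $c \to \infty$, and is why the uniform-reduction
test runs at large $c$.

Histories are initialised by holding the initial rate field for
$t < 0$.

## Initial conditions

`make_initial_condition()` starts from the uniform steady state and
adds: seeded Gaussian noise, a Gaussian bump, horizontal bars, a
periodic cosine lattice (with exact discrete translation symmetry), a
single Fourier mode, or a *travelling eigenmode* — all four fields set
to the linearised eigenvector of the leading eigenvalue at one
wavenumber, so a single travelling wave dominates from the start (used
to reach the travelling-wave attractor without waiting out the slow
symmetry-breaking from noise).  Amplitude 0 returns the exact uniform
state.  Pattern experiments near threshold use finite amplitudes
(0.3 of the uniform rate for the 2D lattice seeds): linear growth rates
just beyond onset are $\sim 10^{-3}$/ms, so seeding at the scale of the
pattern shortcuts an otherwise $\sim 10^4$ ms linear transient; this
selects the attractor, it does not change it.

## Growth-rate measurement

For the dispersion-versus-simulation oracle the seeded mode's complex
amplitude $a_k(t)$ contains both eigenvalues of the conjugate pair, so
$|a_k|$ beats at $2\omega$: `mode_growth_rate()` fits the envelope
peaks for $\sigma$ and reads $\omega$ from their spacing.  Agreement
with the characteristic-equation eigenvalues is within 5% on
$\mathrm{Re}\,\lambda$ (typically ~1–2%) at ten $(k, \kappa_v)$ points.

## Spectrograms and the rebound experiment

`band_power_spectrogram()` offers a 6-cycle analytic Morlet CWT
(default; per-row normalisation such that a unit sinusoid at an
analysed frequency has unit power, with the white-noise row expectation
in closed form as the test oracle) and an STFT path
(`signal::specgram`, Hann, 50% overlap) normalised so total power
integrates to the signal variance (Parseval, tested at 5%).

`beta_rebound_experiment()` applies a 400 ms filtered pulse of
magnitude 3 (the "3 μA" of the source experiment is treated as 3 units
of dimensionless drive; filter constant 50 ms, verdicts insensitive
over 20–100 ms), measures beta-band (13–30 Hz) power of the synaptic
current $\kappa_s U$, and issues three verdicts against a 1000 ms
pre-pulse baseline: oscillating baseline, in-pulse drop (< 0.8×), and
post-offset overshoot (> 1.2× within 500 ms).  Both drop and overshoot
additionally require an oscillatory baseline — with no rhythm there is
no band power to lose or recover; without this gate a near-zero
baseline makes the overshoot ratio meaningless.

## Attractor sweeps

`sweep_attractors()` sweeps one parameter (default grid step 0.25) in
both directions with continuation (each run starts from the previous
attractor's end state), plus a perturbed-fixed-point start and a
large-amplitude kick where no carry exists.  Stable attractors are
classified from post-transient extrema of $R_E$ and $R_I$; distinct
branches are clustered on the $R_I$ signature (max and amplitude) and a
coexistence window is a maximal parameter interval carrying at least
two distinct stable oscillations.  Limit-cycle classifications at window
boundaries are re-verified at doubled horizon (continuing from the
stored end state): a slowly escaping transient otherwise masquerades as
a distinct oscillation and widens a window by a grid step or two.
Unstable orbits are not continued — coexistence is established from
stable attractors only.  Consequently
window edges are sweep-detected stability boundaries, not
continuation-software bifurcation points: in the
inhibitory-gap-junction regime the lower edge of the bistable window
(loss of the high-amplitude branch near $\eta_0^I \approx -7.7$)
matches the reported value, while the moderate branch loses stability
near $\eta_0^I \approx -4.5$, well below the reported upper edge of
$2.5$ — direct jumps onto the branch with long horizons confirm a
genuine instability there rather than a continuation artefact, so the
package reports the stable-coexistence window it actually computes.

# Problem sizes and runtime choices

Defaults were chosen as the sizes a desk study of this model family
would use: 1D fields at $n = 512$ on $L = 40\pi$ (tests use 64–256 on
shorter domains), 2D fields at $64^2$ on a $40 \times 40$ domain,
networks of $N = 1000$ (finite-size scans at 250–4000, five seeds), E–I
sweeps at grid step 0.25 with 600 ms per point.  The 2D pattern
statistics (synchrony extrema near rotating cores) are grid-sensitive
at the tens-of-percent level, which is why those comparisons are made
with wide tolerances and an ordering claim (stronger electrical
coupling ⇒ higher synchrony) that is robust across sizes.

# Known limitations

* The brain-wave PDE reformulation is not implemented; the delayed
  integral is the normative model and the spectral solver already makes
  it affordable.  Consequently very large 2D grids are out of reach.
* No continuation of unstable periodic orbits; bistability windows are
  stable-attractor windows (see above).
* The microscopic model is all-to-all; sparse or structured
  connectivity, conductance synapses with reversal potentials, and
  stochastic QIF variants are out of scope.
* Gap junctions have no spatial extent in the field model, by
  construction.
* The synthetic initial conditions emulate the standard perturbation
  protocols (noise, bumps, bars, lattices); they do not emulate
  measurement noise, spatial heterogeneity of parameters, or realistic
  cortical geometry, so passing tests validate the dynamics and
  numerics, not fit to recorded data.
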