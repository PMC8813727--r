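# Shared parameter sets (the canonical experimental regimes) and builders.

# single population, oscillatory (limit cycle) regime
params_limit_cycle <- function(kappa_v = 1.2)
  mass_params(eta0 = 1, gamma = 0.5, tau = 15, kappa_v = kappa_v,
              kappa_s = 1, alpha = 0.5)

# spiking-network validation regime
params_network_validation <- function(N = 1000L, T = 1200, dt = 0.05, seed = 1L,
                                eta_mode = "deterministic-quantile")
  network_params(N = N, eta0 = 2, gamma = 0.5, tau = 16, kappa_v = 1,
                 kappa_s = 1, alpha = 0.5, dt = dt, T = T, seed = seed,
                 eta_mode = eta_mode)

params_mass_validation <- function()
  mass_params(eta0 = 2, gamma = 0.5, tau = 16, kappa_v = 1, kappa_s = 1,
              alpha = 0.5)

# 1D field, the two-parameter stability-diagram regime
params_field_1d <- function(c = 0.1, kappa_v = 0.85, n = 512L, L = 40 * pi,
                          dt = NULL)
  field_params(eta0 = 1, gamma = 0.5, tau = 15, kappa_v = kappa_v,
               kappa_s = 10, alpha = 0.5, c = c, dim = 1, n = n, L = L,
               dt = dt)

# numerical quadrature of the delayed-kernel transfer function, used as
# the independent oracle for the closed forms
transfer_by_quadrature <- function(k, lam, c, dim) {
  beta <- 1 + lam / c
  if (dim == 1) {
    f_re <- function(x) Re((x - 1) * exp(-beta * x)) * cos(k * x)
    f_im <- function(x) Im((x - 1) * exp(-beta * x)) * cos(k * x)
    2 * (stats::integrate(f_re, 0, Inf, rel.tol = 1e-12)$value +
           1i * stats::integrate(f_im, 0, Inf, rel.tol = 1e-12)$value)
  } else {
    f_re <- function(r) Re((r / 2 - 1) * exp(-beta * r) * r) * besselJ(k * r, 0)
    f_im <- function(r) Im((r / 2 - 1) * exp(-beta * r) * r) * besselJ(k * r, 0)
    stats::integrate(f_re, 0, Inf, rel.tol = 1e-12)$value +
      1i * stats::integrate(f_im, 0, Inf, rel.tol = 1e-12)$value
  }
}
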