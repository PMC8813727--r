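test_that("the uniform steady state is the kappa_s-free mass fixed point", {
  p <- params_field_1d()
  ss <- uniform_steady_state(p)
  p0 <- mass_params(eta0 = p$eta0, gamma = p$gamma, tau = p$tau,
                    kappa_v = p$kappa_v, kappa_s = 0, alpha = p$alpha)
  fp <- mass_fixed_points(p0)
  expect_equal(ss$R0, max(vapply(fp, function(f) f$state[["R"]], numeric(1))))
  # residuals of both defining equations
  V0 <- ss$V0; R0 <- ss$R0
  expect_lt(abs(V0 - (p$kappa_v / 2 - p$gamma / (2 * pi * p$tau * R0))), 1e-12)
  expect_lt(abs(p$eta0 + V0^2 - pi^2 * p$tau^2 * R0^2), 1e-10)
  # independence from the synaptic gain
  for (ks in c(-60, 0, 12)) {
    pk <- p; pk$kappa_s <- ks
    expect_equal(uniform_steady_state(pk)$R0, R0)
  }
})

test_that("eigenvalues are genuine roots of the characteristic function", {
  p <- params_field_1d(c = 1, kappa_v = 0.9)
  ss <- uniform_steady_state(p)
  scale <- abs(characteristic_residual(1, 0.5 + 0.5i, p, ss))
  for (k in c(0, 0.3, 0.8, 1.5, 3)) {
    lam <- leading_eigenvalue(k, p, ss)
    expect_lt(Mod(characteristic_residual(k, lam, p, ss)), 1e-8 * scale)
    # isotropy: lambda(k) = lambda(-k) by symmetry of the kernel
    expect_equal(lam, leading_eigenvalue(-k, p, ss))
  }
})

test_that("with instantaneous uniform feedback the field modes reduce to the mass spectrum", {
  # replacing G by 1 in the k = 0 characteristic function recovers the
  # local mass model with kappa_s intact, whose spectrum the 4x4
  # Jacobian gives independently
  p <- params_field_1d(c = 1, kappa_v = 0.9)
  ss <- uniform_steady_state(p)
  A <- c(p$kappa_v - 2 * ss$V0, p$tau)
  B <- c(-2 * ss$V0, p$tau)
  P <- c(1, 1 / p$alpha)
  PP <- nmfield:::poly_mult(P, P)
  lhs <- nmfield:::poly_mult_n(A, B, PP)
  t2 <- (4 * pi^2 * p$tau^2 * ss$R0^2) * PP
  cf <- lhs
  cf[seq_along(t2)] <- cf[seq_along(t2)] + t2
  cf[1] <- cf[1] - 2 * ss$R0 * p$kappa_s          # minus D * G with G = 1
  roots <- polyroot(cf * p$alpha^2 / (p$tau^2))
  pm <- mass_params(eta0 = p$eta0, gamma = p$gamma, tau = p$tau,
                    kappa_v = p$kappa_v, kappa_s = p$kappa_s,
                    alpha = p$alpha)
  J <- mass_jacobian(c(ss$R0, ss$V0, ss$R0, 0), pm)
  ev <- eigen(J, only.values = TRUE)$values
  d <- vapply(ev, function(z) min(Mod(roots - z)), numeric(1))
  expect_lt(max(d), 1e-8)
})

test_that("polynomial and damped-Newton eigenvalues agree in 1D", {
  p1 <- params_field_1d(c = 0.5, kappa_v = 0.9, n = 64L, L = 24)
  ss <- uniform_steady_state(p1)
  for (k in c(0.2, 0.9, 1.7)) {
    lam_poly <- leading_eigenvalue(k, p1, ss)
    # run the generic Newton path against the same 1D residual
    f <- function(z) characteristic_residual(k, z, p1, ss)
    z <- lam_poly + 0.02 + 0.02i
    for (it in 1:50) {
      h <- 1e-7 * (1 + Mod(z))
      z <- z - f(z) / ((f(z + h) - f(z - h)) / (2 * h))
    }
    expect_lt(Mod(z - lam_poly), 1e-8)
  }
})

test_that("weak gap junctions leave every wavenumber stable", {
  p <- params_field_1d(c = 1, kappa_v = 0.1)
  d <- dispersion_relation(p, k_grid = seq(0, 5, by = 0.1))
  expect_true(all(Re(d$lambda) < 0))
  expect_identical(d$classification, "stable")
})

test_that("first instabilities classify as Hopf at slow c and Turing-Hopf at fast c", {
  p_slow <- params_field_1d(c = 0.1)
  th_slow <- critical_threshold(p_slow, bracket = c(0.3, 2),
                                k_set = seq(0, 3, by = 0.05))
  expect_identical(th_slow$branch, "Hopf")
  expect_lt(th_slow$k_c, 1e-3)
  expect_gt(th_slow$omega_c, 1e-3)
  p_fast <- params_field_1d(c = 1)
  th_fast <- critical_threshold(p_fast, bracket = c(0.3, 2),
                                k_set = seq(0, 3, by = 0.05))
  expect_identical(th_fast$branch, "Turing-Hopf")
  expect_gt(th_fast$k_c, 0.5)
  expect_gt(th_fast$omega_c, 0.05)
  # threshold is insensitive to doubling the k resolution
  th2 <- critical_threshold(p_fast, bracket = c(0.3, 2),
                            k_set = seq(0, 3, by = 0.025))
  expect_lt(abs(th2$value - th_fast$value), 1e-4)
})

test_that("points on the mass Hopf locus carry a pure-imaginary pair and gamma shrinks the window", {
  p <- mass_params(eta0 = 1, kappa_s = 1, tau = 15, alpha = 0.5)
  loc <- hopf_locus_mass(p, gamma_values = c(0.25, 0.5, 1),
                         eta0_values = c(0.75, 1, 1.5))
  expect_gt(nrow(loc), 6)
  for (i in seq_len(nrow(loc))) {
    pp <- mass_params(eta0 = loc$eta0[i], gamma = loc$gamma[i], tau = 15,
                      kappa_v = loc$kappa_v[i], kappa_s = 1, alpha = 0.5)
    fps <- mass_fixed_points(pp)
    R0s <- vapply(fps, function(f) f$state[["R"]], numeric(1))
    ev <- fps[[which.max(R0s)]]$eigenvalues
    expect_lt(abs(max(Re(ev))), 1e-6)
    expect_gt(abs(Im(ev[1])), 1e-3)
  }
  # larger heterogeneity pushes the onset to stronger coupling
  for (e in unique(loc$eta0)) {
    sub <- loc[loc$eta0 == e, ]
    expect_true(all(diff(sub$kappa_v[order(sub$gamma)]) > 0))
  }
})

test_that("the one-parameter Hopf point separates decay from oscillation", {
  p <- mass_params(eta0 = 1, kappa_s = 1, tau = 15, alpha = 0.5, gamma = 0.5)
  h <- hopf_point_1param(p, bracket = c(0.3, 1.4))
  expect_gt(h$omega, 0)
  run_above <- simulate_mass(set_param(p, "kappa_v", h$value + 0.05),
                             T = 6000, dt = 0.5)
  expect_true(run_above$summary$oscillatory)
  run_below <- simulate_mass(set_param(p, "kappa_v", h$value - 0.05),
                             T = 6000, dt = 0.5)
  expect_false(run_below$summary$oscillatory)
})

test_that("oscillation amplitude grows with gap-junction strength at the Hopf frequency", {
  p <- mass_params(eta0 = 1, kappa_s = 1, tau = 15, alpha = 0.5, gamma = 0.5)
  h <- hopf_point_1param(p, bracket = c(0.3, 1.4))
  kvs <- seq(1.05, 1.45, by = 0.1)
  amp <- per <- numeric(length(kvs))
  for (i in seq_along(kvs)) {
    run <- simulate_mass(set_param(p, "kappa_v", kvs[i]), T = 3000, dt = 0.5)
    amp[i] <- run$summary$max - run$summary$min
    per[i] <- run$summary$period
  }
  expect_true(all(diff(amp) > 0))
  # the limit-cycle period stays close to the linear Hopf frequency
  expect_true(all(abs(per - 2 * pi / h$omega) / (2 * pi / h$omega) < 0.03))
})
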