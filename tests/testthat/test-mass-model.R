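test_that("rate zero is repelled and steady synapse tracks steady rate", {
  p <- mass_params()
  d <- mass_rhs(c(R = 0, V = -0.3, U = 0, Udot = 0), p)
  expect_gt(d[["R"]], 0)
  expect_equal(d[["R"]], p$gamma / (pi * p$tau^2))
  # Q(const) = const: at U = R = const with Udot = 0, U does not move
  d2 <- mass_rhs(c(R = 0.1, V = 0, U = 0.1, Udot = 0), p)
  expect_equal(d2[["U"]], 0)
  expect_equal(d2[["Udot"]], 0)
})

test_that("fixed points satisfy the steady-state equations to near machine precision", {
  set.seed(42)
  n_checked <- 0
  for (i in 1:100) {
    p <- mass_params(eta0 = runif(1, -2, 3), gamma = runif(1, 0.1, 1),
                     tau = runif(1, 5, 25), kappa_v = runif(1, 0, 2),
                     kappa_s = runif(1, -5, 5), alpha = runif(1, 0.1, 1))
    fps <- mass_fixed_points(p)
    for (f in fps) {
      expect_lt(max(abs(mass_rhs(f$state, p))), 1e-10)
      expect_gt(f$state[["R"]], 0)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 100)  # every draw admits at least one fixed point
})

test_that("fixed-point eigenvalues match a finite-difference Jacobian", {
  p <- mass_params(eta0 = 1, kappa_v = 0.5)
  f <- mass_fixed_points(p)[[1]]
  J_fd <- nmfield:::num_jacobian(function(s) mass_rhs(s, p), f$state)
  ev_fd <- sort(Re(eigen(J_fd, only.values = TRUE)$values))
  ev <- sort(Re(f$eigenvalues))
  expect_lt(max(abs(ev - ev_fd)), 1e-6)
})

test_that("conformal map sends reference states correctly and inverts", {
  tau <- 15
  expect_equal(to_kuramoto(1 / (pi * tau), 0, tau), 0 + 0i)   # W = 1
  expect_equal(to_kuramoto(0, 0, tau), 1 + 0i)                # full synchrony
  set.seed(7)
  R <- rexp(1000, rate = 10); V <- rnorm(1000)
  Z <- to_kuramoto(R, V, tau)
  expect_true(all(Mod(Z) <= 1 + 1e-12))
  back <- from_kuramoto(Z, tau)
  expect_lt(max(abs(back$R - R)), 1e-12)
  expect_lt(max(abs(back$V - V)), 1e-12)
})

test_that("filtered pulse has unit-mass filter properties and closed-form values", {
  tt <- seq(-100, 3000, by = 0.05)
  for (tau_f in c(0, 20, 50, 100)) {
    A <- filtered_pulse(tt, t_on = 0, duration = 400, magnitude = 3,
                        tau_f = tau_f)
    expect_lte(max(A), 3 + 1e-12)
    # convolution with a unit-mass kernel preserves the integral
    expect_equal(sum(A) * 0.05, 3 * 400, tolerance = 1e-3)
  }
  # first-order step response at pulse offset
  expect_equal(filtered_pulse(400, 0, 400, 3, tau_f = 50),
               3 * (1 - exp(-8)), tolerance = 1e-12)
  # tau_f -> 0 limit is the raw square pulse
  expect_equal(filtered_pulse(c(-1, 0, 200, 399.9, 400.1), 0, 400, 3, 0),
               c(0, 3, 3, 3, 0))
})

test_that("limit-cycle regime oscillates with aligned rate and synchrony peaks", {
  run <- simulate_mass(params_limit_cycle(), T = 2000, dt = 0.25)
  expect_true(run$summary$oscillatory)
  tr <- run$trajectory
  post <- tr[tr$t > 1000, ]
  # positivity and synchrony bounds along the trajectory
  expect_true(all(tr$R >= 0))
  expect_true(all(tr$absZ <= 1 + 1e-12))
  # peaks of the rate and of the synchrony roughly coincide: each R peak
  # has a |Z| peak within a tenth of the period
  pkR <- post$t[nmfield:::local_maxima(post$R)]
  pkZ <- post$t[nmfield:::local_maxima(post$absZ)]
  pkR <- pkR[post$R[match(pkR, post$t)] > mean(post$R)]
  pkZ <- pkZ[post$absZ[match(pkZ, post$t)] > mean(post$absZ)]
  offset <- vapply(pkR, function(t) min(abs(pkZ - t)), numeric(1))
  expect_lt(mean(offset), run$summary$period / 10)
})

test_that("measured period is converged in the time step", {
  p <- params_limit_cycle()
  per <- vapply(c(0.25, 0.125), function(dt)
    simulate_mass(p, T = 2000, dt = dt)$summary$period, numeric(1))
  expect_lt(abs(per[2] - per[1]) / per[1], 1e-3)
})

test_that("below the Hopf point the trajectory converges to the stable fixed point", {
  p <- params_limit_cycle(kappa_v = 0.6)   # well below the Hopf value
  fp <- mass_fixed_points(p)
  expect_length(fp, 1)
  expect_true(fp[[1]]$stable)
  run <- simulate_mass(p, T = 2000, dt = 0.5)
  tail_R <- tail(run$trajectory$R, 50)
  expect_lt(max(abs(tail_R - fp[[1]]$state[["R"]])), 1e-6)
  expect_false(run$summary$oscillatory)
})
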