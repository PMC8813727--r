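small_field_1d <- function(n = 128L, L = 40, ...)
  field_params(eta0 = 1, kappa_s = 10, tau = 15, alpha = 0.5, gamma = 0.5,
               dim = 1, n = n, L = L, ...)

test_that("an unperturbed uniform state stays put", {
  p <- small_field_1d(kappa_v = 0.5, c = 1)
  ic <- make_initial_condition(p, amplitude = 0)
  run <- simulate_field_1d(p, ic, T = 10 * p$tau, record_dt = 10)
  expect_lt(max(abs(run$R - ic$R0)), 1e-8)
  expect_lt(max(abs(run$V - ic$V0)), 1e-8)
})

test_that("a uniform field follows the kappa_s = 0 mass model in the fast-conduction limit", {
  # balanced kernel: a uniform *steady* rate receives zero non-local
  # drive for any c, and a uniform time-varying rate does so in the
  # limit of fast conduction (the delay spread otherwise lets the
  # kernel see the rate's history); so compare at large c
  p <- small_field_1d(n = 64L, kappa_v = 0.9, c = 10)
  ss <- uniform_steady_state(p)
  ic <- make_initial_condition(p, amplitude = 0)
  ic$R <- ic$R + 0.2 * ss$R0          # spatially uniform kick
  run <- simulate_field_1d(p, ic, T = 100, record_dt = 1)
  # spatial uniformity is preserved
  expect_lt(max(apply(run$R, 1, function(x) diff(range(x)))), 1e-10)
  pm <- mass_params(eta0 = p$eta0, gamma = p$gamma, tau = p$tau,
                    kappa_v = p$kappa_v, kappa_s = 0, alpha = p$alpha)
  mass <- simulate_mass(pm, s0 = c(R = 1.2 * ss$R0, V = ss$V0, U = 0,
                                   Udot = 0), T = 100, dt = 1)
  expect_equal(run$R[, 1], mass$trajectory$R, tolerance = 1e-3)
})

test_that("the delayed drive annihilates constants and reproduces the transfer function", {
  p <- small_field_1d(kappa_v = 0.9, c = 1, n = 256L, L = 32 * pi)
  n <- p$n; x <- p$L * (0:(n - 1)) / n
  times <- seq(-100, 0, by = 1)
  # constant field -> zero drive (balanced, after discrete rebalancing)
  h0 <- matrix(0.37, length(times), n)
  expect_lt(max(abs(delayed_drive(h0, times, p))), 1e-12)
  # frozen plane wave -> G(k, 0) * cos(kx)
  k <- 2 * pi * 8 / p$L
  hw <- matrix(rep(cos(k * x), length(times)), nrow = length(times),
               byrow = TRUE)
  Psi <- delayed_drive(hw, times, p)
  G0 <- Re(transfer_function(k, 0, p$c, 1))
  expect_lt(max(abs(Psi - G0 * cos(k * x))), 5e-4 * abs(G0))
  # exponentially growing plane wave over the history -> G(k, sigma)
  sigma <- 0.01
  hg <- outer(exp(sigma * times), cos(k * x))
  Psig <- delayed_drive(hg, times, p)
  Gs <- Re(transfer_function(k, sigma, p$c, 1))
  expect_lt(max(abs(Psig - Gs * cos(k * x))) / abs(Gs), 0.01)
})

test_that("infinite-speed delayed drive reduces to the plain convolution", {
  p_fast <- small_field_1d(kappa_v = 0.9, c = 1e6, n = 128L, L = 40)
  n <- p_fast$n; x <- p_fast$L * (0:(n - 1)) / n
  set.seed(5)
  R <- 0.1 + 0.01 * sin(2 * pi * 3 * x / p_fast$L) + rnorm(n, sd = 1e-3)
  times <- seq(-10, 0, by = 1)
  hist <- matrix(rep(R, length(times)), nrow = length(times), byrow = TRUE)
  Psi <- delayed_drive(hist, times, p_fast)
  # direct minimum-image convolution without any delay
  m <- pmin(0:(n - 1), n - (0:(n - 1)))
  d <- p_fast$dx * m
  K <- kernel_value(d, dim = 1) * p_fast$dx
  K[d > 25] <- 0
  K[1] <- K[1] - sum(K)
  conv <- Re(stats::fft(stats::fft(K) * stats::fft(R), inverse = TRUE)) / n
  expect_lt(max(abs(Psi - conv)), 1e-6)
})

test_that("the spectral solver matches the direct-summation reference", {
  p <- field_params(eta0 = 1, kappa_s = 10, tau = 15, alpha = 0.5,
                    gamma = 0.5, c = 0.5, kappa_v = 0.9, dim = 1,
                    n = 64L, L = 24, dt = 0.1)
  ic <- make_initial_condition(p, kind = "fourier-mode",
                               amplitude = 0.2 * uniform_steady_state(p)$R0,
                               mode = 3)
  r1 <- simulate_field_1d(p, ic, T = 40, record_dt = 2)
  r2 <- simulate_field_reference(p, ic, T = 40, record_dt = 2)
  expect_lt(max(abs(r1$R - r2$R)), 1e-12)
  p2 <- field_params(eta0 = 2, kappa_v = 0.695, kappa_s = 12, tau = 20,
                     alpha = 0.5, gamma = 0.5, c = 1, dim = 2, n = 24L,
                     L = 15, dt = 0.15)
  ic2 <- make_initial_condition(p2, kind = "periodic-lattice",
                                amplitude = 0.2 * uniform_steady_state(p2)$R0,
                                cells = 2)
  r3 <- simulate_field_2d(p2, ic2, T = 30, record_dt = 3)
  r4 <- simulate_field_reference(p2, ic2, T = 30, record_dt = 3)
  # 2D differs only through the delay-shell binning of the kernel
  expect_lt(max(abs(r3$R - r4$R)) / diff(range(r3$R)), 1e-4)
})

test_that("time steps violating the stability bounds are refused", {
  p <- small_field_1d(kappa_v = 0.5, c = 10, dt = 0.1)  # CFL needs ~0.008
  ic <- make_initial_condition(p, amplitude = 0)
  expect_error(simulate_field_1d(p, ic, T = 10), "dt <=")
  expect_error(delayed_drive(matrix(0.1, 3, 128), c(-2, -1, 0),
                             small_field_1d(kappa_v = 0.5, c = 0.1)),
               "history")
})

test_that("initial-condition kinds have their construction symmetries", {
  p2 <- field_params(eta0 = 2, kappa_v = 0.695, kappa_s = 12, tau = 20,
                     alpha = 0.5, gamma = 0.5, c = 1, dim = 2, n = 32L,
                     L = 20)
  lat <- make_initial_condition(p2, kind = "periodic-lattice",
                                amplitude = 0.01, cells = 4)
  # exact discrete translation symmetry by L / cells
  sh <- 32L / 4L
  R <- lat$R
  expect_equal(R, R[c((sh + 1):32, 1:sh), ], tolerance = 1e-12)
  expect_equal(R, R[, c((sh + 1):32, 1:sh)], tolerance = 1e-12)
  bars <- make_initial_condition(p2, kind = "horizontal-bars",
                                 amplitude = 0.01, cells = 3)
  expect_lt(max(abs(bars$R - bars$R[, c(2:32, 1)])), 1e-12)
  noise <- make_initial_condition(p2, kind = "uniform+noise",
                                  amplitude = 0.01, seed = 9)
  noise2 <- make_initial_condition(p2, kind = "uniform+noise",
                                   amplitude = 0.01, seed = 9)
  expect_identical(noise$R, noise2$R)
  expect_error(make_initial_condition(p2, kind = "no-such-kind"),
               "arg")
})

test_that("a seeded linear mode grows at the predicted complex rate", {
  p <- field_params(eta0 = 1, kappa_s = 10, tau = 15, alpha = 0.5,
                    gamma = 0.5, c = 1, kappa_v = 0.9, dim = 1,
                    n = 256L, L = 16 * pi)
  ss <- uniform_steady_state(p)
  mode <- 8L
  k <- 2 * pi * mode / p$L
  lam <- leading_eigenvalue(k, p, ss)
  ic <- make_initial_condition(p, kind = "fourier-mode",
                               amplitude = 1e-4 * ss$R0, mode = mode)
  run <- simulate_field_1d(p, ic, T = 300, record_dt = 1)
  g <- mode_growth_rate(run, mode, t_window = c(100, 300))
  expect_lt(abs(g$sigma - Re(lam)), 0.05 * max(abs(Re(lam)), 1e-3))
  expect_lt(abs(g$omega - Im(lam)) / Im(lam), 0.02)
})
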