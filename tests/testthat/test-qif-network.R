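test_that("background drives follow the Lorentzian in both modes", {
  expect_equal(draw_eta(2, 0.5, 1), 2)                  # single quantile = median
  e3 <- draw_eta(0, 1, 3)
  expect_equal(e3[2], 0)                                # middle quantile
  expect_equal(e3[1], -e3[3])                           # symmetry
  # random mode: sample median close to the distribution median
  er <- draw_eta(2, 0.5, 1e4, mode = "random", seed = 11)
  expect_lt(abs(median(er) - 2), 0.05)
  expect_equal(er, draw_eta(2, 0.5, 1e4, mode = "random", seed = 11))
  expect_error(draw_eta(1, -0.1, 10), "gamma")
})

test_that("a subthreshold neuron relaxes to the stable root of eta + v^2", {
  p <- network_params(N = 1L, eta0 = -1, gamma = 1e-9, kappa_v = 0,
                      kappa_s = 0, tau = 16, dt = 0.1, T = 500)
  r <- simulate_qif_network(p)
  expect_equal(nrow(r$spikes), 0)
  expect_equal(tail(r$voltages[, 1], 1), -1, tolerance = 1e-3)
})

test_that("the single-neuron firing period matches the analytic QIF rate", {
  p <- network_params(N = 1L, eta0 = 4, gamma = 1e-9, kappa_v = 0,
                      kappa_s = 0, tau = 16, dt = 0.02, T = 300)
  r <- simulate_qif_network(p)
  isi <- diff(r$spikes$time)
  expect_gt(length(isi), 5)
  expect_lt(abs(mean(isi) - pi * 16 / 2) / (pi * 16 / 2), 0.02)
  # spike times strictly increasing per neuron
  expect_true(all(isi > 0))
})

test_that("uncoupled homogeneous neurons fire with identical intervals", {
  p <- network_params(N = 20L, eta0 = 4, gamma = 1e-12, kappa_v = 0,
                      kappa_s = 0, tau = 16, dt = 0.05, T = 120)
  r <- simulate_qif_network(p)
  isi_by <- vapply(spike_times_list(r), function(s) mean(diff(s)), numeric(1))
  expect_lt(diff(range(isi_by)), 1e-6)
})

test_that("population observables are invariant under neuron relabelling", {
  p <- network_params(N = 50L, eta0 = 2, T = 250, dt = 0.05)
  r <- simulate_qif_network(p)
  perm <- rev(seq_len(p$N))
  r2 <- r
  r2$voltages <- r$voltages[, perm]
  inv <- order(perm)
  r2$spikes$neuron <- inv[r$spikes$neuron]
  r2$eta <- r$eta[perm]
  o1 <- population_observables(r, window = 10)
  o2 <- population_observables(r2, window = 10)
  expect_equal(o1$R, o2$R)
  expect_equal(o1$V, o2$V)
  expect_equal(o1$absZ, o2$absZ)
})

test_that("population observables recover engineered synchrony states", {
  p <- network_params(N = 8L, T = 10, dt = 0.1)
  r <- simulate_qif_network(p)
  # all neurons silent at v = 0: R = 0, V = 0, |Z| = 1
  r$voltages <- matrix(0, length(r$v_times), p$N)
  r$spikes <- r$spikes[0, ]
  o <- population_observables(r, window = 5)
  expect_true(all(o$R == 0))
  expect_true(all(o$V == 0))
  expect_true(all(abs(o$absZ - 1) < 1e-12))
  # phases spread uniformly on the circle: |Z| ~ 0
  theta <- 2 * pi * (seq_len(p$N) - 0.5) / p$N - pi
  r$voltages <- matrix(tan(theta / 2), length(r$v_times), p$N, byrow = TRUE)
  o2 <- population_observables(r, window = 5)
  expect_true(all(o2$absZ < 1e-10))
})

test_that("unstable integration is detected and reported", {
  p <- network_params(N = 1L, eta0 = 4, gamma = 1e-9, kappa_v = 0,
                      kappa_s = 0, tau = 16, dt = 0.02, T = 50, v_th = 30,
                      v_r = -30)
  # v_fast exceeds v_th here, so the Euler branch must catch the sweep
  expect_no_error(simulate_qif_network(p))
})
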