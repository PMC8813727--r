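#' @keywords internal
# Truncation radius beyond which |w(d)| < tol (kernel tails are dropped).
kernel_truncation_radius <- function(dim, tol = 1e-8) {
  stats::uniroot(function(d) abs(kernel_value(d, dim = dim)) - tol,
                 c(5, 80), tol = 1e-10)$root
}

# Discretised kernel decomposed into delay shells on the periodic grid.
#
# Each shell groups grid offsets whose minimum-image distance falls in a
# band of width dx, carries a single conduction delay (the |w|-weighted
# mean distance divided by c), and is represented by its spatial Fourier
# transform, so the delayed convolution becomes a sum of per-shell
# products in k-space.  In 1D every shell is a single exact distance.
# The discrete kernel is re-balanced by absorbing the (small) quadrature
# imbalance of the grid sum into the zero-distance weight, so that a
# spatially uniform rate receives exactly zero drive, as in the continuum.
make_kernel_shells <- function(p) {
  n <- p$n; dx <- p$dx
  d_trunc <- kernel_truncation_radius(p$dim)
  m <- pmin(0:(n - 1), n - (0:(n - 1)))  # min-image index magnitudes
  if (p$dim == 1) {
    d <- dx * m
    K <- kernel_value(d, dim = 1) * dx
    K[d > d_trunc] <- 0
    K[1] <- K[1] - sum(K)               # balance the discrete kernel
    shells <- list()
    for (j in 0:(n / 2)) {
      idx <- if (j == 0 || j == n / 2) j + 1 else c(j + 1, n - j + 1)
      if (all(K[idx] == 0)) next
      slice <- numeric(n); slice[idx] <- K[idx]
      shells[[length(shells) + 1]] <-
        list(delay = (dx * j) / p$c, What = stats::fft(slice))
    }
  } else {
    D <- dx * sqrt(outer(m^2, m^2, "+"))
    K <- kernel_value(D, dim = 2) * dx^2
    K[D > d_trunc] <- 0
    K[1, 1] <- K[1, 1] - sum(K)
    b <- round(D / dx)
    shells <- list()
    for (bv in sort(unique(as.vector(b)))) {
      mask <- (b == bv) & (K != 0 | D == 0)
      if (!any(mask & K != 0) && bv != 0) next
      slice <- matrix(0, n, n)
      slice[mask] <- K[mask]
      wsum <- sum(abs(slice))
      delay <- if (wsum > 0) sum(abs(slice) * D) / wsum / p$c else 0
      shells[[length(shells) + 1]] <-
        list(delay = delay, What = stats::fft(slice))
    }
  }
  shells
}

#' Delayed non-local drive (reference implementation)
#'
#' Direct evaluation of the space-dependent-delay convolution
#' \deqn{\Psi(x, t) = \int w(|x - x'|)\, R(x', t - |x - x'|/c)\, dx'}
#' on the periodic grid: for every grid offset the minimum-image distance
#' sets both the weight and the conduction delay, and delayed rates are
#' linearly interpolated between stored history slices.  This is the
#' normative (if slow) definition; the spectral solver used by
#' [simulate_field_1d()] must agree with it.
#'
#' @param history Matrix of stored rate fields, one row per time slice
#'   (oldest first); columns index the flattened grid.
#' @param times Times of the history rows (increasing; the drive is
#'   evaluated at the last one).
#' @param p A [field_params()] object describing the grid.
#' @return Numeric vector/matrix `Psi` over the grid at `times[nrow]`.
#' @export
delayed_drive <- function(history, times, p) {
  n <- p$n; dx <- p$dx
  t_now <- times[length(times)]
  d_trunc <- kernel_truncation_radius(p$dim)
  # on a small periodic domain the largest minimum-image distance caps
  # the reach of the kernel before the truncation radius does
  d_trunc <- min(d_trunc, if (p$dim == 1) p$L / 2 else p$L / sqrt(2))
  if (t_now - times[1] < d_trunc / p$c - 1e-9)
    stop(sprintf("history too short: need at least %.1f ms at this c",
                 d_trunc / p$c))
  m <- pmin(0:(n - 1), n - (0:(n - 1)))
  lookup <- function(tpast) {
    # linear interpolation of the stored rate field at time tpast
    if (tpast <= times[1]) return(history[1, ])
    i <- findInterval(tpast, times)
    if (i >= length(times)) return(history[nrow(history), ])
    th <- (tpast - times[i]) / (times[i + 1] - times[i])
    (1 - th) * history[i, ] + th * history[i + 1, ]
  }
  if (p$dim == 1) {
    d <- dx * m
    K <- kernel_value(d, dim = 1) * dx
    K[d > d_trunc] <- 0
    K[1] <- K[1] - sum(K)
    Psi <- numeric(n)
    for (j in which(K != 0)) {
      Rj <- lookup(t_now - d[j] / p$c)
      shift <- j - 1L
      idx <- ((0:(n - 1) - shift) %% n) + 1L
      Psi <- Psi + K[j] * Rj[idx]
    }
    Psi
  } else {
    D <- dx * sqrt(outer(m^2, m^2, "+"))
    K <- kernel_value(D, dim = 2) * dx^2
    K[D > d_trunc] <- 0
    K[1, 1] <- K[1, 1] - sum(K)
    Psi <- matrix(0, n, n)
    row_i <- matrix(0:(n - 1), n, n)
    col_i <- t(row_i)
    for (a in 0:(n - 1)) for (b in 0:(n - 1)) {
      if (K[a + 1, b + 1] == 0) next
      Rj <- matrix(lookup(t_now - D[a + 1, b + 1] / p$c), n, n)
      ri <- ((row_i - a) %% n) + 1L
      ci <- ((col_i - b) %% n) + 1L
      Psi <- Psi + K[a + 1, b + 1] * Rj[cbind(as.vector(ri), as.vector(ci))]
    }
    Psi
  }
}

#' Initial conditions for field simulations
#'
#' Builds a field state at the spatially uniform steady state plus a
#' named perturbation of the rate field: seeded spatial noise, a Gaussian
#' bump, horizontal bars (2D), a periodic lattice of `cells` x `cells`
#' cosine cells (2D), or a single Fourier mode (for linear-regime
#' dispersion checks).  `amplitude = 0` returns the exact uniform state.
#'
#' @param p A [field_params()] object.
#' @param kind One of `"uniform+noise"`, `"gaussian-bump"`,
#'   `"horizontal-bars"`, `"periodic-lattice"`, `"fourier-mode"`,
#'   `"travelling-mode"`.
#' @param amplitude Perturbation amplitude added to `R` (>= 0).
#' @param seed Seed for the noise kind.
#' @param cells Number of lattice cells (or bars) per dimension.
#' @param width Gaussian bump width.
#' @param mode Integer mode index for `"fourier-mode"` and
#'   `"travelling-mode"` (wavenumber `2 * pi * mode / L`).  The
#'   travelling kind seeds all four fields with the linearised
#'   eigenvector of the leading eigenvalue at that wavenumber, so a
#'   single travelling eigenmode dominates from the start (1D only).
#' @return A list of class `field_state` with arrays `R, V, U, Udot`,
#'   and the steady state used (`R0`, `V0`).
#' @export
make_initial_condition <- function(p, kind = c("uniform+noise",
                                               "gaussian-bump",
                                               "horizontal-bars",
                                               "periodic-lattice",
                                               "fourier-mode",
                                               "travelling-mode"),
                                   amplitude = 1e-2, seed = 1L,
                                   cells = 4, width = 2, mode = 1L) {
  kind <- match.arg(kind)
  if (amplitude < 0) stop("'amplitude' must be >= 0")
  ss <- uniform_steady_state(p)
  n <- p$n
  x <- p$L * (0:(n - 1)) / n
  pert <- if (p$dim == 1) numeric(n) else matrix(0, n, n)
  if (amplitude > 0) {
    if (kind == "uniform+noise") {
      set.seed(seed)
      vals <- stats::rnorm(if (p$dim == 1) n else n * n)
      pert[] <- amplitude * vals
    } else if (kind == "gaussian-bump") {
      d <- pmin(abs(x - p$L / 2), p$L - abs(x - p$L / 2))
      g1 <- exp(-d^2 / (2 * width^2))
      pert[] <- if (p$dim == 1) amplitude * g1 else amplitude * outer(g1, g1)
    } else if (kind == "horizontal-bars") {
      if (p$dim != 2) stop("'horizontal-bars' requires dim = 2")
      bars <- cos(2 * pi * cells * x / p$L)
      pert[] <- amplitude * matrix(bars, n, n, byrow = FALSE)
    } else if (kind == "periodic-lattice") {
      if (p$dim != 2) stop("'periodic-lattice' requires dim = 2")
      cx <- cos(2 * pi * cells * x / p$L)
      pert[] <- amplitude * outer(cx, cx)
    } else if (kind == "fourier-mode") {
      k <- 2 * pi * mode / p$L
      c1 <- cos(k * x)
      pert[] <- if (p$dim == 1) amplitude * c1 else
        amplitude * matrix(c1, n, n)
    } else if (kind == "travelling-mode") {
      if (p$dim != 1) stop("'travelling-mode' requires dim = 1")
      k <- 2 * pi * mode / p$L
      lam <- leading_eigenvalue(k, p, ss = list(R0 = ss$R0, V0 = ss$V0))
      # eigenvector components relative to the rate perturbation r = 1
      v <- (p$tau * lam + p$kappa_v - 2 * ss$V0) / (2 * ss$R0)
      u <- transfer_function(k, lam, p$c, dim = 1) / (1 + lam / p$alpha)^2
      e <- exp(1i * k * x)
      R <- ss$R0 + amplitude * Re(e)
      V <- ss$V0 + amplitude * Re(v * e)
      U <- 0 + amplitude * Re(u * e)
      Ud <- 0 + amplitude * Re(lam * u * e)
      return(structure(list(R = R, V = V, U = U, Udot = Ud,
                            R0 = ss$R0, V0 = ss$V0, kind = kind),
                       class = "field_state"))
    }
  }
  R <- pert + ss$R0
  V <- R * 0 + ss$V0
  U <- R * 0
  structure(list(R = R, V = V, U = U, Udot = R * 0,
                 R0 = ss$R0, V0 = ss$V0, kind = kind),
            class = "field_state")
}

# Shared spectral time stepper (Heun) for 1D and 2D periodic fields.
field_engine <- function(p, ic, T, record_dt = 2) {
  dt <- p$dt
  cfl <- 0.25 * p$dx / p$c
  if (dt > cfl + 1e-12 || dt > 0.01 * p$tau + 1e-12)
    stop(sprintf(
      "time step %.4g violates stability bounds; use dt <= %.4g",
      dt, min(cfl, 0.01 * p$tau)))
  shells <- make_kernel_shells(p)
  lags <- vapply(shells, function(s) s$delay / dt, numeric(1))
  i0 <- floor(lags + 1e-12)
  th <- lags - i0
  depth <- max(i0) + 3L
  npts <- length(ic$R)
  Hist <- vector("list", depth)      # ring buffer of rate FFTs
  slot <- function(s) (s %% depth) + 1L

  R <- ic$R; V <- ic$V; U <- ic$U; Ud <- ic$Udot
  Rhat0 <- stats::fft(R)
  for (i in seq_len(depth)) Hist[[i]] <- Rhat0

  psi_at <- function(s) {
    acc <- 0
    for (m in seq_along(shells)) {
      ia <- max(0L, s - i0[m])
      a <- Hist[[slot(ia)]]
      if (th[m] > 0) {
        ib <- max(0L, s - i0[m] - 1L)
        a <- (1 - th[m]) * a + th[m] * Hist[[slot(ib)]]
      }
      acc <- acc + shells[[m]]$What * a
    }
    Re(stats::fft(acc, inverse = TRUE)) / npts
  }
  rhs <- function(R, V, U, Ud, Psi) {
    list(dR = (-p$kappa_v * R + 2 * R * V + p$gamma / (pi * p$tau)) / p$tau,
         dV = (p$eta0 + V^2 - pi^2 * p$tau^2 * R^2 + p$kappa_s * U) / p$tau,
         dU = Ud,
         dUd = p$alpha^2 * (Psi - U) - 2 * p$alpha * Ud)
  }

  n_steps <- ceiling(T / dt)
  rec_every <- max(1L, round(record_dt / dt))
  rec_steps <- seq(0L, n_steps, by = rec_every)
  n_rec <- length(rec_steps)
  Rrec <- matrix(0, n_rec, npts)
  Vrec <- matrix(0, n_rec, npts)
  t_rec <- rec_steps * dt
  Rrec[1, ] <- as.vector(R); Vrec[1, ] <- as.vector(V)
  ri <- 1L

  for (s in 0:(n_steps - 1L)) {
    Psi <- psi_at(s)
    f1 <- rhs(R, V, U, Ud, Psi)
    R1 <- R + dt * f1$dR; V1 <- V + dt * f1$dV
    U1 <- U + dt * f1$dU; Ud1 <- Ud + dt * f1$dUd
    Hist[[slot(s + 1L)]] <- stats::fft(R1)
    Psi1 <- psi_at(s + 1L)
    f2 <- rhs(R1, V1, U1, Ud1, Psi1)
    R <- R + dt / 2 * (f1$dR + f2$dR)
    V <- V + dt / 2 * (f1$dV + f2$dV)
    U <- U + dt / 2 * (f1$dU + f2$dU)
    Ud <- Ud + dt / 2 * (f1$dUd + f2$dUd)
    Hist[[slot(s + 1L)]] <- stats::fft(R)
    if (max(abs(V)) > 1e6 || any(!is.finite(V)))
      stop("field integration blew up (|V| > 1e6)")
    if ((s + 1L) %% rec_every == 0L) {
      ri <- ri + 1L
      Rrec[ri, ] <- as.vector(R)
      Vrec[ri, ] <- as.vector(V)
    }
  }
  Z <- to_kuramoto(pmax(Rrec, 0), Vrec, p$tau)
  structure(list(t = t_rec, R = Rrec, V = Vrec,
                 absZ = matrix(Mod(Z), n_rec, npts),
                 theta = matrix(Arg(Z), n_rec, npts),
                 params = p, ic = ic), class = "field_run")
}

#' Reference field integrator built on the direct delayed convolution
#'
#' A deliberately simple Heun stepper that evaluates the non-local drive
#' with [delayed_drive()] (direct summation over grid offsets, exact
#' per-offset delays) at every stage.  It is the normative definition of
#' the discretised model and the contract for the spectral solver used
#' by [simulate_field_1d()] / [simulate_field_2d()], which must agree
#' with it; being O(n^2) per step it is only practical on small grids.
#'
#' @param p A [field_params()] object.
#' @param ic A `field_state`.
#' @param T Horizon, ms.
#' @param record_dt Snapshot interval, ms.
#' @return A `field_run` with the same layout as the spectral solver.
#' @export
simulate_field_reference <- function(p, ic, T, record_dt = 2) {
  dt <- p$dt
  n_steps <- ceiling(T / dt)
  npts <- length(ic$R)
  d_trunc <- min(kernel_truncation_radius(p$dim),
                 if (p$dim == 1) p$L / 2 else p$L / sqrt(2))
  depth <- ceiling(d_trunc / p$c / dt) + 3L
  hist_times <- numeric(0)
  hist_R <- NULL
  push <- function(tval, R) {
    hist_times <<- c(hist_times, tval)
    hist_R <<- rbind(hist_R, as.vector(R))
    if (length(hist_times) > depth + 2L) {
      hist_times <<- hist_times[-1]
      hist_R <<- hist_R[-1, , drop = FALSE]
    }
  }
  # pre-fill history with the initial rate field
  for (i in seq_len(depth + 1L))
    push(-(depth + 1L - i) * dt, ic$R)
  shape <- function(v) if (p$dim == 1) v else matrix(v, p$n, p$n)
  psi_now <- function() {
    shape(delayed_drive(hist_R, hist_times, p))
  }
  rhs <- function(R, V, U, Ud, Psi) {
    list(dR = (-p$kappa_v * R + 2 * R * V + p$gamma / (pi * p$tau)) / p$tau,
         dV = (p$eta0 + V^2 - pi^2 * p$tau^2 * R^2 + p$kappa_s * U) / p$tau,
         dU = Ud,
         dUd = p$alpha^2 * (Psi - U) - 2 * p$alpha * Ud)
  }
  R <- ic$R; V <- ic$V; U <- ic$U; Ud <- ic$Udot
  rec_every <- max(1L, round(record_dt / dt))
  rec_steps <- seq(0L, n_steps, by = rec_every)
  Rrec <- matrix(0, length(rec_steps), npts)
  Vrec <- matrix(0, length(rec_steps), npts)
  Rrec[1, ] <- as.vector(R); Vrec[1, ] <- as.vector(V)
  ri <- 1L
  for (s in 0:(n_steps - 1L)) {
    Psi <- psi_now()
    f1 <- rhs(R, V, U, Ud, Psi)
    R1 <- R + dt * f1$dR; V1 <- V + dt * f1$dV
    U1 <- U + dt * f1$dU; Ud1 <- Ud + dt * f1$dUd
    push((s + 1L) * dt, R1)
    Psi1 <- psi_now()
    f2 <- rhs(R1, V1, U1, Ud1, Psi1)
    R <- R + dt / 2 * (f1$dR + f2$dR)
    V <- V + dt / 2 * (f1$dV + f2$dV)
    U <- U + dt / 2 * (f1$dU + f2$dU)
    Ud <- Ud + dt / 2 * (f1$dUd + f2$dUd)
    hist_R[nrow(hist_R), ] <- as.vector(R)
    if ((s + 1L) %% rec_every == 0L) {
      ri <- ri + 1L
      Rrec[ri, ] <- as.vector(R)
      Vrec[ri, ] <- as.vector(V)
    }
  }
  Z <- to_kuramoto(pmax(Rrec, 0), Vrec, p$tau)
  structure(list(t = rec_steps * dt, R = Rrec, V = Vrec,
                 absZ = matrix(Mod(Z), length(rec_steps), npts),
                 theta = matrix(Arg(Z), length(rec_steps), npts),
                 params = p, ic = ic), class = "field_run")
}

#' Simulate the 1D neural field with axonal delays
#'
#' Method-of-lines integration (Heun) of the spatially extended mass
#' model on a periodic interval: at every grid point the local (R, V, U)
#' dynamics of [mass_rhs()] hold, with the synaptic operator driven by
#' the delayed non-local input of [delayed_drive()].  The delayed
#' convolution is evaluated spectrally per delay shell, which is
#' algebraically identical to the direct sum on the periodic grid.
#'
#' @param p A [field_params()] object with `dim = 1`.
#' @param ic A `field_state` from [make_initial_condition()].
#' @param T Horizon, ms.
#' @param record_dt Snapshot interval, ms.
#' @return A `field_run`: list with `t` (snapshot times), matrices
#'   `R, V, absZ, theta` (snapshots x grid points), `params`, `ic`.
#' @examples
#' \donttest{
#' p <- field_params(kappa_v = 0.85, c = 0.1, n = 128L, L = 40)
#' run <- simulate_field_1d(p, make_initial_condition(p), T = 100)
#' }
#' @export
simulate_field_1d <- function(p, ic = make_initial_condition(p), T = 1000,
                              record_dt = 2) {
  if (p$dim != 1) stop("'p' must have dim = 1")
  field_engine(p, ic, T, record_dt)
}

#' Simulate the 2D neural field with axonal delays
#'
#' As [simulate_field_1d()], on a periodic square; kernel distances are
#' minimum-image Euclidean, and offsets are grouped into delay shells of
#' width one grid cell.
#'
#' @param p A [field_params()] object with `dim = 2`.
#' @param ic A `field_state` from [make_initial_condition()].
#' @param T Horizon, ms.
#' @param record_dt Snapshot interval, ms.
#' @return A `field_run`; the grid is flattened column-major in the
#'   snapshot matrices (`matrix(run$R[i, ], n, n)` restores a frame).
#' @export
simulate_field_2d <- function(p, ic = make_initial_condition(p), T = 1000,
                              record_dt = 2) {
  if (p$dim != 2) stop("'p' must have dim = 2")
  field_engine(p, ic, T, record_dt)
}

#' Growth rate and frequency of a single spatial Fourier mode
#'
#' Fits `log |a_k(t)|` and the unwrapped phase of the mode amplitude
#' \eqn{a_k(t)} (FFT of the rate field at mode index `mode`) with a line
#' over a time window, giving the measured complex rate
#' \eqn{\lambda = \sigma + i\omega} of the linearised dynamics.  Used as
#' the simulation-side oracle for the dispersion relation.
#'
#' @param run A `field_run` from a 1D simulation seeded with a single
#'   Fourier mode.
#' @param mode Integer mode index (wavenumber `2 pi mode / L`).
#' @param t_window Time window `c(t0, t1)` for the fit.
#' @return A list with `sigma` (1/ms), `omega` (rad/ms) and `lambda`.
#' @export
mode_growth_rate <- function(run, mode, t_window) {
  sel <- run$t >= t_window[1] & run$t <= t_window[2]
  tt <- run$t[sel]
  a <- apply(run$R[sel, , drop = FALSE], 1,
             function(row) stats::fft(row)[mode + 1L])
  # a(t) = b1 e^{lambda t} + b2 e^{conj(lambda) t}: a real-rate seed
  # excites the conjugate eigenvalue pair, so |a| carries e^{sigma t}
  # modulated at 2 omega.  Fit sigma on the envelope peaks and read
  # omega from their spacing (peaks of |a| are pi/omega apart).
  amp <- log(Mod(a))
  pk <- local_maxima(amp)
  if (length(pk) >= 3) {
    sigma <- stats::coef(stats::lm(amp[pk] ~ tt[pk]))[[2]]
    omega <- pi / mean(diff(tt[pk]))
  } else {
    sigma <- stats::coef(stats::lm(amp ~ tt))[[2]]
    omega <- NA_real_
  }
  list(sigma = sigma, omega = omega, lambda = complex(real = sigma,
                                                      imaginary = omega))
}
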