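#' Right-hand side of the single-population mass model
#'
#' The exact mean field of a globally coupled QIF network evolves the
#' population firing rate `R`, mean membrane potential `V` and synaptic
#' activity `U`:
#' \deqn{\tau \dot R = -\kappa_v R + 2RV + \gamma/(\pi\tau),}
#' \deqn{\tau \dot V = \eta_0 + A + V^2 - \pi^2\tau^2 R^2 + \kappa_s U,}
#' with `U` driven by the rate through the second-order synaptic operator
#' \eqn{(1 + \alpha^{-1} d/dt)^2 U = R}, kept in state-space form
#' `(U, Udot)` with \eqn{\ddot U = \alpha^2 (R - U) - 2\alpha \dot U}.
#' An external drive `A` (e.g. a stimulation current) adds to the
#' background excitability \eqn{\eta_0}.
#'
#' @param state Numeric vector `c(R, V, U, Udot)`.
#' @param p A [mass_params()] object.
#' @param A External drive added to `eta0` (scalar, default 0).
#' @return Numeric vector of time derivatives `c(dR, dV, dU, dUdot)`.
#' @examples
#' mass_rhs(c(R = 0.05, V = -1, U = 0.05, Udot = 0), mass_params())
#' @export
mass_rhs <- function(state, p, A = 0) {
  R <- state[[1]]; V <- state[[2]]; U <- state[[3]]; Ud <- state[[4]]
  dR <- (-p$kappa_v * R + 2 * R * V + p$gamma / (pi * p$tau)) / p$tau
  dV <- (p$eta0 + A + V^2 - pi^2 * p$tau^2 * R^2 + p$kappa_s * U) / p$tau
  c(R = dR, V = dV, U = Ud,
    Udot = p$alpha^2 * (R - U) - 2 * p$alpha * Ud)
}

#' Jacobian of the mass model at a state
#'
#' @param state Numeric vector `c(R, V, U, Udot)`.
#' @param p A [mass_params()] object.
#' @return A 4x4 numeric matrix.
#' @export
mass_jacobian <- function(state, p) {
  R <- state[[1]]; V <- state[[2]]
  tau <- p$tau; a <- p$alpha
  matrix(c(
    (-p$kappa_v + 2 * V) / tau, 2 * R / tau,      0,         0,
    -2 * pi^2 * tau * R,        2 * V / tau,      p$kappa_s / tau, 0,
    0,                          0,                0,         1,
    a^2,                        0,               -a^2,      -2 * a),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("R", "V", "U", "Udot"), c("R", "V", "U", "Udot")))
}

#' Fixed points of the single-population mass model
#'
#' Steady states satisfy \eqn{V_0 = \kappa_v/2 - \gamma/(2\pi\tau R_0)}
#' (from the rate equation) and
#' \eqn{\eta_0 + V_0^2 - \pi^2\tau^2 R_0^2 + \kappa_s R_0 = 0} (the
#' voltage equation with `U0 = R0`, since the synaptic operator passes
#' constants through unchanged).  Eliminating `V0` and multiplying by
#' `R0^2` turns the steady-state condition into a quartic in `R0`, whose
#' real positive roots are returned together with the eigenvalues of the
#' 4x4 Jacobian at each.
#'
#' @param p A [mass_params()] object.
#' @return A list of fixed points, each a list with elements `state`
#'   (named vector `R, V, U, Udot`), `eigenvalues` (complex vector,
#'   ordered by decreasing real part) and `stable` (logical).
#' @examples
#' fp <- mass_fixed_points(mass_params(eta0 = 1, kappa_v = 0.5))
#' fp[[1]]$stable
#' @export
mass_fixed_points <- function(p) {
  tau <- p$tau; g <- p$gamma
  # quartic coefficients, constant term first:
  # -pi^2 tau^2 R^4 + kappa_s R^3 + (eta0 + kappa_v^2/4) R^2
  #   - kappa_v gamma/(2 pi tau) R + gamma^2/(4 pi^2 tau^2) = 0
  coef <- c(g^2 / (4 * pi^2 * tau^2),
            -p$kappa_v * g / (2 * pi * tau),
            p$eta0 + p$kappa_v^2 / 4,
            p$kappa_s,
            -pi^2 * tau^2)
  roots <- polyroot(coef)
  R0 <- Re(roots[abs(Im(roots)) < 1e-8 * (1 + abs(Re(roots))) & Re(roots) > 0])
  R0 <- sort(unique(R0))
  # polish each root on the original residual to full precision
  resid <- function(R) {
    V <- p$kappa_v / 2 - g / (2 * pi * tau * R)
    p$eta0 + V^2 - pi^2 * tau^2 * R^2 + p$kappa_s * R
  }
  lapply(R0, function(R) {
    for (i in 1:50) {
      f <- resid(R)
      df <- (resid(R * (1 + 1e-7)) - f) / (R * 1e-7)
      step <- f / df
      R <- R - step
      if (abs(step) < 1e-14 * (1 + abs(R))) break
    }
    V <- p$kappa_v / 2 - g / (2 * pi * tau * R)
    st <- c(R = R, V = V, U = R, Udot = 0)
    ev <- eigen(mass_jacobian(st, p), only.values = TRUE)$values
    ev <- ev[order(-Re(ev))]
    list(state = st, eigenvalues = ev, stable = all(Re(ev) < 0))
  })
}

#' Conformal map between (R, V) and the Kuramoto order parameter
#'
#' The firing-rate description and the synchrony description of the same
#' population are related by a Moebius map: with
#' \eqn{W = \pi\tau R + iV}, the complex Kuramoto order parameter is
#' \eqn{Z = (1 - W^*)/(1 + W^*)}.  For `R >= 0` the map lands inside the
#' closed unit disc, so `|Z|` is a bona fide synchrony measure (1 = full
#' synchrony, 0 = full asynchrony).
#'
#' @param R Population firing rate(s), `>= 0` (vectorised).
#' @param V Mean membrane potential(s).
#' @param tau Membrane time constant.
#' @return Complex vector `Z`.
#' @examples
#' to_kuramoto(1 / (pi * 15), 0, 15)  # W = 1 -> Z = 0, perfect asynchrony
#' @export
to_kuramoto <- function(R, V, tau) {
  if (any(R < 0)) stop("'R' must be >= 0 (the map leaves the disc otherwise)")
  W <- pi * tau * R + 1i * V
  if (any(abs(1 + Conj(W)) == 0)) stop("W = -1 is outside the domain of the map")
  (1 - Conj(W)) / (1 + Conj(W))
}

#' Inverse of the conformal synchrony map
#'
#' Recovers `(R, V)` from the Kuramoto order parameter:
#' \eqn{W = (1 - Z^*)/(1 + Z^*)}, then \eqn{R = Re(W)/(\pi\tau)},
#' \eqn{V = Im(W)}.
#'
#' @param Z Complex order parameter(s), `|Z| <= 1`, `Z != -1`.
#' @param tau Membrane time constant.
#' @return A list with numeric components `R` and `V`.
#' @export
from_kuramoto <- function(Z, tau) {
  if (any(abs(1 + Conj(Z)) == 0)) stop("Z = -1 is outside the domain of the map")
  W <- (1 - Conj(Z)) / (1 + Conj(Z))
  list(R = Re(W) / (pi * tau), V = Im(W))
}

#' Temporally filtered square pulse
#'
#' A square pulse of given onset, duration and magnitude passed through a
#' first-order low-pass filter with time constant `tau_f`; used to model
#' smoothed stimulation such as a movement-related drive.  The filtered
#' pulse rises as \eqn{m(1 - e^{-(t-t_{on})/\tau_f})} during the pulse and
#' decays exponentially after offset, so its peak never exceeds the
#' magnitude and its time integral equals `magnitude * duration` for any
#' `tau_f`.
#'
#' @param t Time(s) at which to evaluate (vectorised), in ms.
#' @param t_on Pulse onset time, ms.
#' @param duration Pulse length, ms (> 0).
#' @param magnitude Pulse height.
#' @param tau_f Filter time constant, ms; `tau_f = 0` gives the raw
#'   square pulse.
#' @return Numeric vector `A(t)`.
#' @examples
#' filtered_pulse(400, t_on = 0, duration = 400, magnitude = 3, tau_f = 50)
#' @export
filtered_pulse <- function(t, t_on = 0, duration = 400, magnitude = 3,
                           tau_f = 50) {
  if (duration <= 0) stop("'duration' must be > 0")
  if (tau_f < 0) stop("'tau_f' must be >= 0")
  s <- t - t_on
  if (tau_f == 0) return(magnitude * as.numeric(s >= 0 & s < duration))
  out <- numeric(length(t))
  during <- s >= 0 & s < duration
  after <- s >= duration
  out[during] <- magnitude * (1 - exp(-s[during] / tau_f))
  peak <- magnitude * (1 - exp(-duration / tau_f))
  out[after] <- peak * exp(-(s[after] - duration) / tau_f)
  out
}

#' Simulate the single-population mass model
#'
#' Integrates the (R, V, U, Udot) system with `deSolve`'s adaptive
#' `lsoda` (relative tolerance `1e-8`), evaluates the Kuramoto order
#' parameter pointwise along the trajectory, and summarises the
#' post-transient dynamics (oscillation extrema and period, or
#' convergence to a fixed point).
#'
#' @param p A [mass_params()] object.
#' @param s0 Initial state `c(R, V, U, Udot)`; default starts near a
#'   low-rate state.
#' @param T Simulation horizon, ms.
#' @param dt Output sampling step, ms (must be `< tau / 10`).
#' @param A Optional drive: a function of time added to `eta0`.
#' @param transient Fraction of the run discarded before summarising
#'   (default 0.5).
#' @return A list with `trajectory` (data.frame `t, R, V, U, Udot, absZ,
#'   theta`), `params`, and `summary` (from [oscillation_extrema()] on
#'   `R`, plus an `oscillatory` flag).
#' @examples
#' run <- simulate_mass(mass_params(eta0 = 1, kappa_v = 1.2), T = 500)
#' run$summary$oscillatory
#' @export
simulate_mass <- function(p, s0 = c(R = 0.05, V = -1, U = 0.05, Udot = 0),
                          T = 2000, dt = 0.5, A = NULL, transient = 0.5) {
  if (dt >= p$tau / 10) stop("'dt' must be < tau / 10")
  drive <- if (is.null(A)) function(t) 0 else A
  rhs <- function(t, y, parms) list(mass_rhs(y, p, A = drive(t)))
  times <- seq(0, T, by = dt)
  sol <- deSolve::ode(y = s0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  traj <- as.data.frame(sol)
  names(traj) <- c("t", "R", "V", "U", "Udot")
  if (any(!is.finite(traj$V)) || max(abs(traj$V), na.rm = TRUE) > 1e6)
    stop("integration blew up (|V| > 1e6); check parameters")
  Z <- to_kuramoto(pmax(traj$R, 0), traj$V, p$tau)
  traj$absZ <- Mod(Z)
  traj$theta <- Arg(Z)
  summ <- oscillation_extrema(traj$R, transient_fraction = transient,
                              dt = dt)
  summ$oscillatory <- is.finite(summ$period) &&
    (summ$max - summ$min) > 1e-4 && summ$n_peaks >= 5
  list(trajectory = traj, params = p, summary = summ)
}
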