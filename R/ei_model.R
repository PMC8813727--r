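#' Right-hand side of the excitatory-inhibitory mass network
#'
#' Two coupled mean-field populations, each with its own (R, V) dynamics
#' and within-population gap junctions, wired by four synaptic pathways
#' with independent kinetics.  For population \eqn{a \in \{E, I\}}:
#' \deqn{\tau_a \dot R_a = -\kappa_v^a R_a + 2 R_a V_a + \gamma_a/(\pi\tau_a),}
#' \deqn{\tau_a \dot V_a = \eta_0^a + V_a^2 - \pi^2\tau_a^2 R_a^2 +
#'   \kappa_s^{aE} U_{aE} + \kappa_s^{aI} U_{aI},}
#' and each synaptic variable obeys
#' \eqn{\ddot U_{ab} = \alpha_{ab}^2 (R_b - U_{ab}) - 2\alpha_{ab}\dot U_{ab}}
#' (source population `b`, target `a`).
#'
#' @param state Numeric vector of length 12, ordered
#'   `R_E, V_E, R_I, V_I, U_EE, Ud_EE, U_EI, Ud_EI, U_IE, Ud_IE, U_II, Ud_II`.
#' @param p An [ei_params()] object.
#' @return Numeric vector of the 12 time derivatives.
#' @export
ei_rhs <- function(state, p) {
  R_E <- state[[1]]; V_E <- state[[2]]; R_I <- state[[3]]; V_I <- state[[4]]
  U_EE <- state[[5]]; Ud_EE <- state[[6]]
  U_EI <- state[[7]]; Ud_EI <- state[[8]]
  U_IE <- state[[9]]; Ud_IE <- state[[10]]
  U_II <- state[[11]]; Ud_II <- state[[12]]

  dR_E <- (-p$kappa_v_E * R_E + 2 * R_E * V_E +
             p$gamma_E / (pi * p$tau_E)) / p$tau_E
  dV_E <- (p$eta0_E + V_E^2 - pi^2 * p$tau_E^2 * R_E^2 +
             p$kappa_s_EE * U_EE + p$kappa_s_EI * U_EI) / p$tau_E
  dR_I <- (-p$kappa_v_I * R_I + 2 * R_I * V_I +
             p$gamma_I / (pi * p$tau_I)) / p$tau_I
  dV_I <- (p$eta0_I + V_I^2 - pi^2 * p$tau_I^2 * R_I^2 +
             p$kappa_s_IE * U_IE + p$kappa_s_II * U_II) / p$tau_I

  syn <- function(U, Ud, alpha, src) {
    c(Ud, alpha^2 * (src - U) - 2 * alpha * Ud)
  }
  c(R_E = dR_E, V_E = dV_E, R_I = dR_I, V_I = dV_I,
    syn(U_EE, Ud_EE, p$alpha_EE, R_E),
    syn(U_EI, Ud_EI, p$alpha_EI, R_I),
    syn(U_IE, Ud_IE, p$alpha_IE, R_E),
    syn(U_II, Ud_II, p$alpha_II, R_I))
}

ei_state_names <- c("R_E", "V_E", "R_I", "V_I",
                    "U_EE", "Ud_EE", "U_EI", "Ud_EI",
                    "U_IE", "Ud_IE", "U_II", "Ud_II")

#' Default initial state for the E-I model
#'
#' A mildly active state with both populations at a low rate; useful as a
#' generic starting point for attractor sweeps.
#'
#' @param R_E,V_E,R_I,V_I Initial rates and voltages.
#' @return Named numeric vector of length 12 with synaptic variables
#'   initialised at the corresponding source rates.
#' @export
ei_state <- function(R_E = 0.05, V_E = -1, R_I = 0.05, V_I = -1) {
  s <- c(R_E, V_E, R_I, V_I,
         R_E, 0, R_I, 0, R_E, 0, R_I, 0)
  names(s) <- ei_state_names
  s
}

#' Numerically locate a fixed point of the E-I model
#'
#' Newton iteration on the full 12-dimensional vector field from a given
#' starting state (synaptic variables are slaved to the rates at steady
#' state, so only 4 of the 12 components are genuinely free, but a full
#' Newton solve is cheap and robust here).
#'
#' @param p An [ei_params()] object.
#' @param s0 Starting state (length 12); a few stock starting points are
#'   tried as fallbacks if Newton fails from `s0`.
#' @param tol Residual tolerance on the max-norm of the vector field.
#' @return A list with `state`, `residual` and `eigenvalues` of the
#'   numerical Jacobian, or `NULL` if Newton fails to converge.
#' @export
ei_fixed_point <- function(p, s0 = ei_state(), tol = 1e-12) {
  starts <- list(s0, ei_state(R_E = 0.01, V_E = -3, R_I = 0.01, V_I = -3),
                 ei_state(R_E = 1, V_E = 0.2, R_I = 1, V_I = 0.2),
                 ei_state(R_E = 0.2, V_E = -1, R_I = 0.02, V_I = -2))
  for (s0_try in starts) {
    res <- ei_newton(p, s0_try, tol)
    if (!is.null(res)) return(res)
  }
  NULL
}

ei_newton <- function(p, s0, tol) {
  f <- function(s) ei_rhs(s, p)
  s <- s0
  for (it in 1:100) {
    fs <- f(s)
    if (max(abs(fs)) < tol) break
    J <- num_jacobian(f, s)
    step <- tryCatch(solve(J, fs), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    # damped update to survive poor starting points
    lam <- 1
    repeat {
      s_new <- s - lam * step
      if (max(abs(f(s_new))) < max(abs(fs)) || lam < 1e-4) break
      lam <- lam / 2
    }
    s <- s_new
  }
  fs <- f(s)
  if (max(abs(fs)) >= 1e-8) return(NULL)
  names(s) <- ei_state_names
  ev <- eigen(num_jacobian(f, s), only.values = TRUE)$values
  list(state = s, residual = max(abs(fs)), eigenvalues = ev[order(-Re(ev))])
}

#' Simulate the excitatory-inhibitory mass network
#'
#' Adaptive integration of the 12-dimensional E-I system, with the
#' synchrony order parameter of each population obtained pointwise from
#' the conformal map.
#'
#' @param p An [ei_params()] object.
#' @param s0 Initial state (length 12); see [ei_state()].
#' @param T Horizon, ms.
#' @param dt Output sampling step, ms.
#' @param transient Fraction of the run discarded before summarising.
#' @return A list with `trajectory` (data.frame with `t`, the 12 states,
#'   `absZ_E`, `absZ_I`), `params` and `summary` (oscillation extrema of
#'   `R_E` and `R_I`).
#' @examples
#' run <- simulate_ei(ei_params(), T = 100, dt = 0.05)
#' @export
simulate_ei <- function(p, s0 = ei_state(), T = 500, dt = 0.05,
                        transient = 0.5) {
  if (dt >= min(p$tau_E, p$tau_I) / 10) stop("'dt' must be < tau / 10")
  rhs <- function(t, y, parms) list(ei_rhs(y, p))
  times <- seq(0, T, by = dt)
  sol <- deSolve::ode(y = s0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  traj <- as.data.frame(sol)
  names(traj) <- c("t", ei_state_names)
  if (any(!is.finite(traj$V_E)) || max(abs(traj$V_E)) > 1e6)
    stop("integration blew up (|V_E| > 1e6); check parameters")
  traj$absZ_E <- Mod(to_kuramoto(pmax(traj$R_E, 0), traj$V_E, p$tau_E))
  traj$absZ_I <- Mod(to_kuramoto(pmax(traj$R_I, 0), traj$V_I, p$tau_I))
  summ <- list(
    R_E = oscillation_extrema(traj$R_E, transient_fraction = transient, dt = dt),
    R_I = oscillation_extrema(traj$R_I, transient_fraction = transient, dt = dt))
  list(trajectory = traj, params = p, summary = summ)
}
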