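#' Parameters of the single-population neural mass model
#'
#' The mean-field description of an all-to-all network of quadratic
#' integrate-and-fire (QIF) neurons with gap-junction and synaptic coupling
#' carries six scalar parameters.  Time is measured in milliseconds
#' throughout, so rates are in spikes/ms and `alpha` in 1/ms.
#'
#' @param eta0 Median background drive \eqn{\eta_0} of the Lorentzian
#'   distribution of single-cell inputs (sets excitability).
#' @param gamma Half-width \eqn{\gamma > 0} of the Lorentzian (degree of
#'   heterogeneity across the population).
#' @param tau Membrane time constant \eqn{\tau} in ms.
#' @param kappa_v Gap-junction (electrical) coupling strength
#'   \eqn{\kappa_v \ge 0}.
#' @param kappa_s Synaptic coupling strength \eqn{\kappa_s} (signed;
#'   negative values give an inhibitory population).
#' @param alpha Inverse synaptic time-to-peak \eqn{\alpha} in 1/ms; the
#'   post-synaptic response is \eqn{s(t) = \alpha^2 t e^{-\alpha t}}.
#'
#' @return An object of class `mass_params` (a named list).
#' @examples
#' p <- mass_params(eta0 = 1, kappa_v = 1.2)
#' @export
mass_params <- function(eta0 = 1, gamma = 0.5, tau = 15, kappa_v = 1,
                        kappa_s = 1, alpha = 0.5) {
  stopifnot(is.numeric(eta0), length(eta0) == 1L)
  if (!is.numeric(gamma) || gamma <= 0) stop("'gamma' must be > 0")
  if (!is.numeric(tau) || tau <= 0) stop("'tau' must be > 0")
  if (!is.numeric(kappa_v) || kappa_v < 0) stop("'kappa_v' must be >= 0")
  if (!is.numeric(alpha) || alpha <= 0) stop("'alpha' must be > 0")
  structure(list(eta0 = eta0, gamma = gamma, tau = tau,
                 kappa_v = kappa_v, kappa_s = kappa_s, alpha = alpha),
            class = "mass_params")
}

#' Parameters of the two-population excitatory-inhibitory mass model
#'
#' Each population (`E`, `I`) has its own excitability, heterogeneity,
#' membrane time constant and within-population gap-junction strength.
#' Synaptic connections exist within and between populations; gap junctions
#' only within a population.  The connection labelling convention is
#' target-first: `kappa_s_ab` and `alpha_ab` describe the synapse from
#' population `b` onto population `a`, so `kappa_s_IE` is the excitatory
#' drive received by the inhibitory population.
#'
#' @param eta0_E,eta0_I Median background drives.
#' @param gamma_E,gamma_I Lorentzian half-widths (> 0).
#' @param tau_E,tau_I Membrane time constants in ms (> 0).
#' @param kappa_v_E,kappa_v_I Within-population gap-junction strengths.
#' @param kappa_s_EE,kappa_s_EI,kappa_s_IE,kappa_s_II Signed synaptic
#'   strengths, target population first.
#' @param alpha_EE,alpha_EI,alpha_IE,alpha_II Inverse synaptic
#'   times-to-peak (1/ms), target population first.
#'
#' @return An object of class `ei_params`.
#' @examples
#' p <- ei_params(eta0_I = -3)  # bursting regime defaults
#' @export
ei_params <- function(eta0_E = 5, eta0_I = -3,
                      gamma_E = 0.5, gamma_I = 0.5,
                      tau_E = 1, tau_I = 1,
                      kappa_v_E = 0.5, kappa_v_I = 0.5,
                      kappa_s_EE = 15, kappa_s_EI = -15,
                      kappa_s_IE = 25, kappa_s_II = -15,
                      alpha_EE = 0.2, alpha_EI = 0.07,
                      alpha_IE = 0.1, alpha_II = 0.06) {
  vals <- list(eta0_E = eta0_E, eta0_I = eta0_I,
               gamma_E = gamma_E, gamma_I = gamma_I,
               tau_E = tau_E, tau_I = tau_I,
               kappa_v_E = kappa_v_E, kappa_v_I = kappa_v_I,
               kappa_s_EE = kappa_s_EE, kappa_s_EI = kappa_s_EI,
               kappa_s_IE = kappa_s_IE, kappa_s_II = kappa_s_II,
               alpha_EE = alpha_EE, alpha_EI = alpha_EI,
               alpha_IE = alpha_IE, alpha_II = alpha_II)
  for (nm in c("gamma_E", "gamma_I", "tau_E", "tau_I",
               "alpha_EE", "alpha_EI", "alpha_IE", "alpha_II"))
    if (vals[[nm]] <= 0) stop(sprintf("'%s' must be > 0", nm))
  if (kappa_v_E < 0 || kappa_v_I < 0)
    stop("gap-junction strengths must be >= 0")
  structure(vals, class = "ei_params")
}

#' Parameters of the microscopic QIF network
#'
#' Settings for a finite network of `N` all-to-all coupled QIF neurons,
#' whose population statistics the mass model reproduces in the
#' thermodynamic limit.  The finite firing threshold and reset used in
#' network simulations stand in for the infinite values assumed by the
#' mean field.
#'
#' @inheritParams mass_params
#' @param N Number of neurons (>= 1).
#' @param v_th,v_r Firing threshold and reset voltage, `v_r < v_th`.
#' @param dt Integration step in ms (must satisfy `dt < tau`).
#' @param T Simulation horizon in ms.
#' @param seed Integer seed used when `eta_mode = "random"`.
#' @param eta_mode Either `"deterministic-quantile"` (equally spaced
#'   Lorentzian quantiles, reproducible without randomness) or `"random"`
#'   (i.i.d. Cauchy draws).
#'
#' @return An object of class `network_params`.
#' @export
network_params <- function(N = 1000, eta0 = 2, gamma = 0.5, tau = 16,
                           kappa_v = 1, kappa_s = 1, alpha = 0.5,
                           v_th = 1000, v_r = -1000,
                           dt = 0.01 * tau, T = 1000, seed = 1L,
                           eta_mode = c("deterministic-quantile", "random")) {
  eta_mode <- match.arg(eta_mode)
  if (!is.numeric(N) || N < 1) stop("'N' must be >= 1")
  if (gamma <= 0) stop("'gamma' must be > 0")
  if (tau <= 0) stop("'tau' must be > 0")
  if (alpha <= 0) stop("'alpha' must be > 0")
  if (v_r >= v_th) stop("'v_r' must be < 'v_th'")
  if (dt <= 0 || dt >= tau) stop("'dt' must satisfy 0 < dt < tau")
  if (T <= 0) stop("'T' must be > 0")
  structure(list(N = as.integer(N), eta0 = eta0, gamma = gamma, tau = tau,
                 kappa_v = kappa_v, kappa_s = kappa_s, alpha = alpha,
                 v_th = v_th, v_r = v_r, dt = dt, T = T,
                 seed = as.integer(seed), eta_mode = eta_mode),
            class = "network_params")
}

#' Parameters of the spatially extended neural field model
#'
#' Extends [mass_params()] with the axonal conduction speed, the choice of
#' balanced connectivity kernel and the discretisation of the periodic
#' domain.  The "inverted-wizard-hat" kernel (long-range excitation,
#' short-range inhibition) is \eqn{w(x) = (|x|-1)e^{-|x|}} in 1D and
#' \eqn{w(r) = (r/2-1)e^{-r}/(2\pi)} in 2D; the regular wizard hat is
#' realised by the same shape with `kappa_s < 0`.
#'
#' @inheritParams mass_params
#' @param c Axonal action-potential speed (> 0), in kernel length units
#'   per ms.
#' @param kernel Kernel family; both choices share the same functional
#'   form, see Details.
#' @param L Domain length (1D) or square side (2D).
#' @param n Grid points per dimension (even, for spectral symmetry).
#' @param dt Time step in ms; `NULL` picks
#'   `min(0.01 * tau, 0.25 * dx / c)`.
#' @param dim Spatial dimension, 1 or 2.
#'
#' @return An object of class `field_params` (also inherits from
#'   `mass_params`).
#' @examples
#' p <- field_params(eta0 = 1, kappa_v = 0.85, kappa_s = 10, c = 0.1)
#' @export
field_params <- function(eta0 = 1, gamma = 0.5, tau = 15, kappa_v = 1,
                         kappa_s = 10, alpha = 0.5, c = 1,
                         kernel = c("inverted-wizard-hat", "wizard-hat"),
                         L = if (dim == 1) 40 * pi else 40,
                         n = if (dim == 1) 512L else 64L,
                         dt = NULL, dim = 1) {
  kernel <- match.arg(kernel)
  if (!dim %in% c(1, 2)) stop("'dim' must be 1 or 2")
  if (c <= 0) stop("'c' must be > 0")
  if (n %% 2 != 0) stop("'n' must be even")
  base <- mass_params(eta0 = eta0, gamma = gamma, tau = tau,
                      kappa_v = kappa_v, kappa_s = kappa_s, alpha = alpha)
  dx <- L / n
  if (is.null(dt)) dt <- min(0.01 * tau, 0.25 * dx / c)
  p <- c(unclass(base),
         list(c = c, kernel = kernel, L = L, n = as.integer(n),
              dx = dx, dt = dt, dim = as.integer(dim)))
  class(p) <- c("field_params", "mass_params")
  p
}
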