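#' Balanced wizard-hat connectivity kernel
#'
#' The structural connectivity used by the neural field:
#' \eqn{w(x) = (|x| - 1)e^{-|x|}} in 1D and
#' \eqn{w(r) = (r/2 - 1)e^{-r}/(2\pi)} in 2D.  Both are balanced (their
#' integral over the whole domain vanishes) and have the inverted
#' wizard-hat shape: short-range inhibition, longer-range excitation.
#' The regular wizard hat (short-range excitation, long-range inhibition)
#' is obtained by flipping the sign of the synaptic gain `kappa_s`, not by
#' changing `w`; `kappa_sign` applies that flip here for convenience.
#'
#' @param d Nonnegative distance(s).
#' @param dim Spatial dimension, 1 or 2.
#' @param kappa_sign +1 for the inverted wizard hat (default), -1 for the
#'   regular one.
#' @return Numeric kernel value(s).
#' @examples
#' kernel_value(c(0, 1), dim = 1)   # -1, 0
#' @export
kernel_value <- function(d, dim = 1, kappa_sign = 1) {
  if (any(d < 0)) stop("'d' must be >= 0")
  w <- if (dim == 1) (d - 1) * exp(-d) else (d / 2 - 1) * exp(-d) / (2 * pi)
  kappa_sign * w
}

#' Spatio-temporal transfer function of the delayed kernel
#'
#' The Fourier transform in space of \eqn{w(\cdot) e^{-\lambda|\cdot|/c}},
#' which governs how a perturbation \eqn{e^{\lambda t + i k x}} of the
#' firing rate is fed back through the delayed synaptic drive.  With
#' \eqn{\beta = 1 + \lambda/c}:
#' \deqn{G_{1D}(k,\lambda) = 2\left[\frac{\beta^2 - k^2}{(\beta^2+k^2)^2}
#'   - \frac{\beta}{\beta^2+k^2}\right],}
#' \deqn{G_{2D}(k,\lambda) = \frac{(2\beta^2 - k^2)/2 -
#'   \beta(\beta^2+k^2)}{(\beta^2+k^2)^{5/2}},}
#' using the principal square root (positive real part).  The closed
#' forms require the causality/branch condition
#' \eqn{\mathrm{Re}(1 + \lambda/c) > 0}.
#'
#' @param k Real wavenumber.
#' @param lam Complex temporal rate \eqn{\lambda}.
#' @param c Axonal speed (> 0).
#' @param dim Spatial dimension, 1 or 2.
#' @return Complex `G(k, lambda)`.
#' @examples
#' transfer_function(1, 0, c = 1, dim = 1)   # -1
#' @export
transfer_function <- function(k, lam, c, dim = 1) {
  beta <- 1 + lam / c
  if (any(Re(beta) <= 0))
    stop("branch condition Re(1 + lambda/c) > 0 violated")
  q <- beta^2 + k^2
  if (dim == 1) {
    2 * ((beta^2 - k^2) / q^2 - beta / q)
  } else {
    s <- sqrt(as.complex(q))          # principal branch, Re >= 0
    ((2 * beta^2 - k^2) / 2 - beta * q) / s^5
  }
}
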