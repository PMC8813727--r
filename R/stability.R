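#' Spatially uniform steady state of the neural field
#'
#' Because the connectivity kernel is balanced, a spatially uniform rate
#' receives zero non-local drive, so the uniform steady state solves the
#' mass-model fixed-point equations with the synaptic term absent:
#' \eqn{V_0 = \kappa_v/2 - \gamma/(2\pi\tau R_0)} and
#' \eqn{\eta_0 + V_0^2 - \pi^2\tau^2 R_0^2 = 0}.  In particular it does
#' not depend on `kappa_s`.
#'
#' @param p A [field_params()] or [mass_params()] object.
#' @return A list with `R0`, `V0` (the principal root, largest `R0`) and
#'   `all` (every positive root as an `(R0, V0)` pair).
#' @examples
#' uniform_steady_state(field_params(eta0 = 1, kappa_v = 0.85))
#' @export
uniform_steady_state <- function(p) {
  p0 <- mass_params(eta0 = p$eta0, gamma = p$gamma, tau = p$tau,
                    kappa_v = p$kappa_v, kappa_s = 0, alpha = p$alpha)
  fps <- mass_fixed_points(p0)
  if (length(fps) == 0) stop("no positive uniform steady state found")
  R0s <- vapply(fps, function(f) f$state[["R"]], numeric(1))
  i <- which.max(R0s)
  list(R0 = fps[[i]]$state[["R"]], V0 = fps[[i]]$state[["V"]],
       all = lapply(fps, function(f) c(R0 = f$state[["R"]],
                                       V0 = f$state[["V"]])))
}

#' Characteristic residual of the uniform state
#'
#' Linearising the field equations about the uniform steady state with a
#' perturbation \eqn{(r, v, u) e^{\lambda t + i k x}} and eliminating the
#' synaptic variable gives the scalar dispersion function
#' \deqn{E(k,\lambda) = (\tau\lambda + \kappa_v - 2V_0)(\tau\lambda - 2V_0)
#'   (1 + \lambda/\alpha)^2 + 4\pi^2\tau^2 R_0^2 (1 + \lambda/\alpha)^2
#'   - 2 R_0 \kappa_s\, G(k, \lambda),}
#' whose roots in \eqn{\lambda} are the eigenvalues of the mode `k`.
#' `G` is the delayed-kernel transfer function of
#' [transfer_function()].
#'
#' @param k Wavenumber.
#' @param lam Complex rate.
#' @param p A [field_params()] object.
#' @param ss Optional precomputed [uniform_steady_state()] result.
#' @return Complex residual `E(k, lam)` (zero at an eigenvalue).
#' @export
characteristic_residual <- function(k, lam, p, ss = uniform_steady_state(p)) {
  R0 <- ss$R0; V0 <- ss$V0
  A <- p$tau * lam + p$kappa_v - 2 * V0
  B <- p$tau * lam - 2 * V0
  P <- (1 + lam / p$alpha)^2
  G <- transfer_function(k, lam, p$c, dim = p$dim)
  A * B * P + 4 * pi^2 * p$tau^2 * R0^2 * P - 2 * R0 * p$kappa_s * G
}

# Coefficients (constant first) of E(k, lambda) * (beta^2 + k^2)^2,
# a degree-8 polynomial in lambda (1D only, where G is rational in
# beta = 1 + lambda/c).
char_poly_1d <- function(k, p, ss) {
  R0 <- ss$R0; V0 <- ss$V0
  A <- c(p$kappa_v - 2 * V0, p$tau)
  B <- c(-2 * V0, p$tau)
  P <- c(1, 1 / p$alpha)
  beta <- c(1, 1 / p$c)
  beta2 <- poly_mult(beta, beta)
  q <- beta2; q[1] <- q[1] + k^2              # beta^2 + k^2
  q2 <- poly_mult(q, q)
  Cc <- 4 * pi^2 * p$tau^2 * R0^2
  D <- 2 * R0 * p$kappa_s
  # G * q^2 = 2 * ((beta^2 - k^2) - beta * q)
  gnum <- beta2; gnum[1] <- gnum[1] - k^2
  gnum <- 2 * (c(gnum, 0) - poly_mult(beta, q))
  pad <- function(v, n) c(v, numeric(n - length(v)))
  t1 <- poly_mult_n(A, B, P, P, q2)
  t2 <- Cc * poly_mult_n(P, P, q2)
  nmax <- max(length(t1), length(t2), length(gnum))
  pad(t1, nmax) + pad(t2, nmax) - D * pad(gnum, nmax)
}

#' Leading eigenvalue of a spatial mode
#'
#' Finds the root of \eqn{E(k, \cdot) = 0} with the largest real part.
#' In 1D the rational structure of the transfer function is cleared,
#' giving a degree-8 polynomial whose roots are filtered by the branch
#' condition \eqn{\mathrm{Re}(1 + \lambda/c) > 0} and polished on the
#' original residual.  In 2D (half-integer powers, no polynomial form) a
#' damped Newton iteration is run from multiple starts, including the
#' mass-model Jacobian spectrum and any supplied continuation guess.
#'
#' @param k Wavenumber (>= 0).
#' @param p A [field_params()] object.
#' @param ss Optional precomputed steady state.
#' @param guess Optional complex starting value (continuation in `k`).
#' @param all For 1D, return all admissible roots instead of the leading
#'   one.
#' @return Complex eigenvalue (or vector if `all = TRUE`).
#' @export
leading_eigenvalue <- function(k, p, ss = uniform_steady_state(p),
                               guess = NULL, all = FALSE) {
  if (p$dim == 1) {
    coef <- char_poly_1d(k, p, ss)
    roots <- polyroot(coef)
    ok <- Re(1 + roots / p$c) > 1e-9
    roots <- roots[ok]
    # polish on the cleared polynomial (Newton, exact derivative)
    dcoef <- coef[-1] * seq_len(length(coef) - 1)
    for (i in seq_along(roots)) {
      z <- roots[i]
      for (it in 1:5) {
        fz <- poly_eval(coef, z)
        dz <- poly_eval(dcoef, z)
        if (Mod(dz) == 0) break
        z <- z - fz / dz
      }
      roots[i] <- z
    }
    roots <- roots[Re(1 + roots / p$c) > 1e-9]
    # drop spurious roots introduced by clearing the denominator
    scale <- abs(characteristic_residual(k, 1 + 1i, p, ss)) + 1
    res <- vapply(roots, function(z)
      Mod(characteristic_residual(k, z, p, ss)), numeric(1))
    roots <- roots[res < 1e-5 * scale]
    if (length(roots) == 0) stop("no admissible eigenvalue found")
    roots <- roots[order(-Re(roots))]
    if (all) roots else roots[[1]]
  } else {
    f <- function(z) characteristic_residual(k, z, p, ss)
    starts <- c(guess,
                eigen(mass_jacobian(c(ss$R0, ss$V0, ss$R0, 0),
                                    mass_params(eta0 = p$eta0,
                                                gamma = p$gamma, tau = p$tau,
                                                kappa_v = p$kappa_v,
                                                kappa_s = p$kappa_s,
                                                alpha = p$alpha)),
                      only.values = TRUE)$values,
                complex(real = 0.01, imaginary = 0.1))
    best <- NULL
    for (z0 in starts) {
      z <- as.complex(z0)
      if (Re(1 + z / p$c) <= 0) z <- complex(real = -0.9 * p$c + 1e-3,
                                             imaginary = Im(z))
      ok <- FALSE
      for (it in 1:80) {
        fz <- f(z)
        h <- 1e-7 * (1 + Mod(z))
        dz <- (f(z + h) - f(z - h)) / (2 * h)
        if (Mod(dz) == 0) break
        step <- fz / dz
        lam <- 1
        repeat {
          z_new <- z - lam * step
          if (Re(1 + z_new / p$c) > 1e-9 &&
              (Mod(f(z_new)) < Mod(fz) || lam < 1e-4)) break
          lam <- lam / 2
        }
        if (Mod(z_new - z) < 1e-12 * (1 + Mod(z_new))) { z <- z_new; ok <- TRUE; break }
        z <- z_new
      }
      if (Mod(f(z)) < 1e-8 * (1 + Mod(f(0.5 + 0.5i))) &&
          Re(1 + z / p$c) > 1e-9) {
        if (is.null(best) || Re(z) > Re(best)) best <- z
      }
    }
    if (is.null(best)) stop("2D Newton iteration failed to converge for k = ", k)
    best
  }
}

#' Dispersion relation over a wavenumber grid
#'
#' Leading eigenvalue per wavenumber, with continuation (each solve
#' seeded by the previous root in 2D), plus the most unstable wavenumber
#' and a Hopf / Turing / Turing-Hopf classification of the leading mode
#' using thresholds `eps_k`, `eps_w` on `k*` and `|Im lambda(k*)|`.
#'
#' @param p A [field_params()] object.
#' @param k_grid Wavenumber grid (default `seq(0, 5, by = 0.025)`).
#' @param eps_k,eps_w Classification thresholds.
#' @return A list of class `dispersion_result` with `k`, `lambda`,
#'   `k_star`, `lambda_star`, `classification` (one of `"stable"`,
#'   `"Hopf"`, `"Turing"`, `"Turing-Hopf"`).
#' @export
dispersion_relation <- function(p, k_grid = seq(0, 5, by = 0.025),
                                eps_k = 1e-3, eps_w = 1e-3) {
  ss <- uniform_steady_state(p)
  lam <- complex(length(k_grid))
  guess <- NULL
  for (i in seq_along(k_grid)) {
    lam[i] <- leading_eigenvalue(k_grid[i], p, ss, guess = guess)
    guess <- lam[i]
  }
  i_star <- which.max(Re(lam))
  k_star <- k_grid[i_star]
  ls <- lam[i_star]
  cls <- if (Re(ls) < 0) "stable"
  else if (k_star < eps_k && abs(Im(ls)) > eps_w) "Hopf"
  else if (k_star >= eps_k && abs(Im(ls)) <= eps_w) "Turing"
  else if (k_star >= eps_k && abs(Im(ls)) > eps_w) "Turing-Hopf"
  else "stable"
  structure(list(k = k_grid, lambda = lam, k_star = k_star,
                 lambda_star = ls, classification = cls),
            class = "dispersion_result")
}

# max over a k set of Re(leading eigenvalue); returns value and argmax,
# with a local refinement of the argmax between grid neighbours.
# branch = "first": plain maximum over the grid (first instability of any
# type); "bulk": the k = 0 mode only; "patterned": the largest *interior*
# local maximum beyond the initial descent from k = 0, which isolates the
# finite-wavenumber (Turing / Turing-Hopf) branch from the tail of the
# bulk mode.
max_growth <- function(p, k_set, ss = uniform_steady_state(p),
                       refine = TRUE, branch = "first") {
  if (branch == "bulk" || (length(k_set) == 1 && k_set[1] == 0)) {
    lam <- leading_eigenvalue(0, p, ss)
    return(list(value = Re(lam), k_star = 0, omega = abs(Im(lam))))
  }
  re <- vapply(k_set, function(k)
    Re(leading_eigenvalue(k, p, ss)), numeric(1))
  lo_i <- 1L
  if (branch == "patterned") {
    rising <- which(diff(re) > 0)
    if (length(rising) == 0)
      return(list(value = min(re), k_star = k_set[length(k_set)], omega = 0))
    lo_i <- rising[1]            # first index past the initial descent
  }
  i <- (lo_i - 1L) + which.max(re[lo_i:length(re)])
  k_star <- k_set[i]
  val <- re[i]
  if (refine && i > 1 && i < length(k_set)) {
    opt <- stats::optimize(function(k)
      -Re(leading_eigenvalue(k, p, ss)),
      lower = k_set[i - 1], upper = k_set[i + 1], tol = 1e-6)
    if (-opt$objective > val) { val <- -opt$objective; k_star <- opt$minimum }
  }
  lam_star <- leading_eigenvalue(k_star, p, ss)
  list(value = val, k_star = k_star, omega = abs(Im(lam_star)))
}

#' Replace one parameter in a parameter object
#'
#' Convenience for sweeps: returns a copy of `p` with field `name` set to
#' `value` (class and all other fields preserved).
#'
#' @param p A parameter object ([mass_params()], [ei_params()],
#'   [field_params()] or [network_params()]).
#' @param name Field name.
#' @param value New value.
#' @return The modified parameter object.
#' @export
set_param <- function(p, name, value) {
  p[[name]] <- value
  p
}

#' Instability threshold in one parameter
#'
#' Bisects a free parameter (typically `kappa_v`) for the point where the
#' most unstable mode of the uniform state crosses zero growth,
#' \eqn{\max_k \mathrm{Re}\,\lambda(k) = 0}, and classifies the
#' bifurcation from the critical wavenumber and frequency: Hopf
#' (`k_c ~ 0`, `omega_c > 0`), Turing (`k_c > 0`, `omega_c ~ 0`) or
#' Turing-Hopf (both nonzero).
#'
#' @param p A [field_params()] object.
#' @param free Name of the swept parameter (default `"kappa_v"`).
#' @param bracket Length-2 interval with a sign change of the maximal
#'   growth rate.
#' @param k_set Wavenumbers over which the growth is maximised.
#' @param branch `"first"` (any instability), `"bulk"` (the k = 0 Hopf
#'   mode only) or `"patterned"` (the finite-wavenumber local maximum of
#'   the dispersion curve, isolating the Turing / Turing-Hopf branch).
#' @param tol Bisection tolerance on the parameter.
#' @param eps_k,eps_w Classification thresholds.
#' @return A list with `value` (critical parameter), `k_c`, `omega_c`,
#'   `branch` (the classification at threshold).
#' @examples
#' \donttest{
#' p <- field_params(eta0 = 1, kappa_s = 10, c = 0.1)
#' critical_threshold(p, bracket = c(0.5, 1.2), branch = "bulk")
#' }
#' @export
critical_threshold <- function(p, free = "kappa_v", bracket,
                               k_set = seq(0, 3, by = 0.05),
                               branch = c("first", "bulk", "patterned"),
                               tol = 1e-6, eps_k = 1e-3, eps_w = 1e-3) {
  branch <- match.arg(branch)
  g <- function(val) {
    pp <- set_param(p, free, val)
    max_growth(pp, k_set, refine = FALSE, branch = branch)$value
  }
  lo <- bracket[1]; hi <- bracket[2]
  glo <- g(lo); ghi <- g(hi)
  if (glo * ghi > 0)
    stop("no sign change of the growth rate across the bracket")
  if (glo > 0) { tmp <- lo; lo <- hi; hi <- tmp }
  while (abs(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) <= 0) lo <- mid else hi <- mid
  }
  crit <- (lo + hi) / 2
  pp <- set_param(p, free, crit)
  mg <- max_growth(pp, k_set, refine = TRUE, branch = branch)
  cls <- if (mg$k_star < eps_k && mg$omega > eps_w) "Hopf"
  else if (mg$k_star >= eps_k && mg$omega <= eps_w) "Turing"
  else "Turing-Hopf"
  list(value = crit, k_c = mg$k_star, omega_c = mg$omega, branch = cls)
}

#' Hopf and Turing-Hopf instability curves in the (c, kappa_v) plane
#'
#' For each axonal speed in `c_values`, bisects `kappa_v` separately for
#' the bulk (k = 0, Hopf) threshold and the patterned (k > 0,
#' Turing-Hopf) threshold; also locates the codimension-2 speed `c*`
#' where the two thresholds exchange order, and the overall minimum of
#' the first-instability threshold over `c`.
#'
#' @param p A [field_params()] object (with `dim = 1`).
#' @param c_values Axonal speeds to sweep.
#' @param kv_bracket Bisection bracket in `kappa_v`.
#' @param k_max Largest wavenumber considered for the patterned branch.
#' @return A list with `curves` (data.frame: `c, kappa_hopf,
#'   kappa_turing_hopf, k_c, omega_hopf, omega_turing_hopf`),
#'   `crossing_c` (the codim-2 speed, `NA` if no exchange in range) and
#'   `kappa_min` (minimum first-instability threshold over the sweep).
#' @export
instability_curves <- function(p, c_values = c(0.05, 0.08, 0.1, 0.13, 0.16,
                                               0.2, 0.25, 0.3, 0.4, 0.6,
                                               1, 1.5, 2),
                               kv_bracket = c(0.3, 2), k_max = 3) {
  stopifnot(p$dim == 1)
  k_pat <- seq(0, k_max, by = 0.05)
  one <- function(cv) {
    pp <- set_param(p, "c", cv)
    h <- critical_threshold(pp, bracket = kv_bracket, branch = "bulk")
    th <- critical_threshold(pp, bracket = kv_bracket, k_set = k_pat,
                             branch = "patterned")
    c(kappa_hopf = h$value, kappa_th = th$value, k_c = th$k_c,
      omega_h = h$omega_c, omega_th = th$omega_c)
  }
  rows <- t(vapply(c_values, one, numeric(5)))
  curves <- data.frame(c = c_values,
                       kappa_hopf = rows[, "kappa_hopf"],
                       kappa_turing_hopf = rows[, "kappa_th"],
                       k_c = rows[, "k_c"],
                       omega_hopf = rows[, "omega_h"],
                       omega_turing_hopf = rows[, "omega_th"])
  # rows whose critical wavenumber is pinned at the edge of the k window
  # belong to shorter-wavelength delay resonances, not the traced branch
  interior <- curves$k_c < k_max - 0.1
  diffs <- curves$kappa_hopf - curves$kappa_turing_hopf
  diffs[!interior] <- NA
  crossing <- NA_real_
  sgn <- sign(diffs)
  sc <- which(diff(sgn[!is.na(sgn)]) != 0)
  ok_idx <- which(!is.na(sgn))
  if (length(sc) > 0) {
    i <- ok_idx[sc[1]]
    j <- ok_idx[sc[1] + 1]
    dfun <- function(cv) {
      r <- one(cv)
      r[["kappa_hopf"]] - r[["kappa_th"]]
    }
    crossing <- stats::uniroot(dfun, c(c_values[i], c_values[j]),
                               tol = 1e-3)$root
  }
  first <- pmin(curves$kappa_hopf, curves$kappa_turing_hopf)
  i_min <- which.min(first)
  kappa_min <- first[i_min]
  # refine the minimum over c locally
  if (i_min > 1 && i_min < length(c_values)) {
    opt <- stats::optimize(function(cv) {
      r <- one(cv)
      min(r[["kappa_hopf"]], r[["kappa_th"]])
    }, lower = c_values[i_min - 1], upper = c_values[i_min + 1], tol = 1e-3)
    if (opt$objective < kappa_min) kappa_min <- opt$objective
  }
  list(curves = curves, crossing_c = crossing, kappa_min = kappa_min)
}

#' Hopf locus of the mass model in the (kappa_v, eta0) plane
#'
#' For each heterogeneity value `gamma`, traces the curve along which the
#' mass-model fixed point has a purely imaginary eigenvalue pair, by
#' bisecting `kappa_v` at each `eta0` on a grid.  Oscillations emerge to
#' the right of each curve (larger `kappa_v`), and the oscillatory window
#' shrinks as `gamma` grows.
#'
#' @param p A [mass_params()] template (its `kappa_v`, `eta0`, `gamma`
#'   are overridden).
#' @param gamma_values Heterogeneities to trace.
#' @param eta0_values Grid of drives.
#' @param kv_range Scan range for `kappa_v`.
#' @return A data.frame with columns `gamma, eta0, kappa_v, omega`
#'   (rows where no crossing exists in range are omitted).
#' @export
hopf_locus_mass <- function(p, gamma_values = c(0.25, 0.5, 1),
                            eta0_values = seq(0.5, 3, by = 0.25),
                            kv_range = c(0, 3)) {
  max_re <- function(pp) {
    fps <- mass_fixed_points(pp)
    if (length(fps) == 0) return(NA_real_)
    R0s <- vapply(fps, function(f) f$state[["R"]], numeric(1))
    ev <- fps[[which.max(R0s)]]$eigenvalues
    max(Re(ev))
  }
  out <- list()
  for (g in gamma_values) for (e in eta0_values) {
    pp <- mass_params(eta0 = e, gamma = g, tau = p$tau,
                      kappa_v = kv_range[1], kappa_s = p$kappa_s,
                      alpha = p$alpha)
    grid <- seq(kv_range[1], kv_range[2], length.out = 31)
    vals <- vapply(grid, function(kv) max_re(set_param(pp, "kappa_v", kv)),
                   numeric(1))
    sc <- which(diff(sign(vals)) != 0)
    if (length(sc) == 0) next
    i <- sc[1]
    root <- stats::uniroot(function(kv) max_re(set_param(pp, "kappa_v", kv)),
                           c(grid[i], grid[i + 1]), tol = 1e-8)$root
    ppc <- set_param(pp, "kappa_v", root)
    fps <- mass_fixed_points(ppc)
    R0s <- vapply(fps, function(f) f$state[["R"]], numeric(1))
    ev <- fps[[which.max(R0s)]]$eigenvalues
    omega <- abs(Im(ev[which.max(Re(ev))]))
    out[[length(out) + 1]] <- data.frame(gamma = g, eta0 = e,
                                         kappa_v = root, omega = omega)
  }
  do.call(rbind, out)
}
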