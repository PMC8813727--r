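# Small numerical helpers shared across modules.

# Central-difference Jacobian of a vector-valued function.
num_jacobian <- function(f, x, h = NULL) {
  n <- length(x)
  f0 <- f(x)
  m <- length(f0)
  J <- matrix(0, m, n)
  for (j in seq_len(n)) {
    hj <- if (is.null(h)) 1e-6 * max(1, abs(x[j])) else h
    xp <- x; xp[j] <- xp[j] + hj
    xm <- x; xm[j] <- xm[j] - hj
    J[, j] <- (f(xp) - f(xm)) / (2 * hj)
  }
  J
}

# Indices of strict local maxima of a numeric series.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# Multiply polynomials given as coefficient vectors (constant term first).
poly_mult <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
  }
  out
}

poly_mult_n <- function(...) Reduce(poly_mult, list(...))

# Evaluate a polynomial (constant term first) at complex z.
poly_eval <- function(coef, z) {
  acc <- 0 + 0i
  for (c_ in rev(coef)) acc <- acc * z + c_
  acc
}
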