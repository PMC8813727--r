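#' Post-transient extrema and period of a time series
#'
#' Discards an initial transient, then reports the minimum, maximum and an
#' oscillation period estimated as the mean spacing of local maxima.  The
#' period is `NA` when fewer than 3 peaks are present (e.g. for a series
#' that has settled to a fixed point).
#'
#' @param x Numeric time series.
#' @param transient_fraction Fraction of the series discarded from the
#'   start (in `[0, 0.9]`).
#' @param dt Sampling interval; the period is returned in these units.
#' @return A list with `min`, `max`, `period` (NA if undefined) and
#'   `n_peaks`.
#' @examples
#' t <- seq(0, 50, by = 0.01)
#' oscillation_extrema(sin(t), transient_fraction = 0, dt = 0.01)
#' @export
oscillation_extrema <- function(x, transient_fraction = 0.5, dt = 1) {
  stopifnot(transient_fraction >= 0, transient_fraction <= 0.9)
  n <- length(x)
  if (n < 4) stop("series too short")
  keep <- x[max(1, floor(n * transient_fraction)):n]
  pk <- local_maxima(keep)
  # ignore numerically flat ripples when estimating the period
  amp <- max(keep) - min(keep)
  if (length(pk) > 0 && amp > 0) {
    pk <- pk[keep[pk] > min(keep) + 0.25 * amp]
  }
  period <- if (length(pk) >= 3) mean(diff(pk)) * dt else NA_real_
  list(min = min(keep), max = max(keep), period = period,
       n_peaks = length(pk))
}

#' Morlet-wavelet or short-time-Fourier spectrogram with band power
#'
#' Time-frequency decomposition of a uniformly sampled series, with power
#' averaged over a frequency band per time bin.  The default analysis is a
#' continuous Morlet wavelet transform (6-cycle mother wavelet); the STFT
#' path uses `signal::specgram` with a Hann window and is normalised so
#' that total power integrates to the signal variance (Parseval).
#'
#' @param x Numeric series (mean is removed before analysis).
#' @param dt Sampling step in ms (so frequencies are in Hz via
#'   `1000 / dt`).
#' @param band Frequency band `c(f_lo, f_hi)` in Hz; default beta,
#'   13-30 Hz.
#' @param method `"morlet"` (default) or `"stft"`.
#' @param freqs For the Morlet path, the frequency grid in Hz (default 48
#'   log-spaced points covering `[1, 0.9 * Nyquist]` and the band).
#' @param nfft STFT window length in samples (default chosen to give
#'   roughly 1 Hz resolution).
#' @return A list of class `spectrogram` with `t` (times, ms), `f`
#'   (frequencies, Hz), `power` (matrix `length(f) x length(t)`,
#'   linear units), `band_power` (numeric, per time bin), `band`,
#'   `method`.
#' @examples
#' t <- seq(0, 2000, by = 2)
#' sp <- band_power_spectrogram(sin(2 * pi * 15 * t / 1000), dt = 2)
#' @export
band_power_spectrogram <- function(x, dt, band = c(13, 30),
                                   method = c("morlet", "stft"),
                                   freqs = NULL, nfft = NULL) {
  method <- match.arg(method)
  fs <- 1000 / dt                      # Hz
  nyq <- fs / 2
  if (band[2] >= nyq) stop("band upper edge is above the Nyquist frequency")
  x <- x - mean(x)
  if (method == "morlet") {
    if (is.null(freqs)) {
      freqs <- sort(unique(c(exp(seq(log(1), log(0.9 * nyq), length.out = 40)),
                             seq(band[1], band[2], length.out = 12))))
    }
    cw <- morlet_cwt(x, dt, freqs)
    power <- Mod(cw)^2
    tgrid <- (seq_along(x) - 1) * dt
    fgrid <- freqs
  } else {
    if (is.null(nfft)) nfft <- 2^ceiling(log2(fs))  # ~1 Hz bins
    nfft <- min(nfft, length(x))
    sg <- signal::specgram(x, n = nfft, Fs = fs,
                           window = signal::hanning(nfft),
                           overlap = floor(nfft / 2))
    w <- signal::hanning(nfft)
    # one-sided PSD scaling: sum(psd) * df = variance for stationary input
    scale <- 2 / (fs * sum(w^2))
    power <- Mod(sg$S)^2 * scale
    power[1, ] <- power[1, ] / 2
    if (nfft %% 2 == 0) power[nrow(power), ] <- power[nrow(power), ] / 2
    power <- power * (fs / nfft)       # fold df in: entries integrate to var
    tgrid <- as.numeric(sg$t) * 1000
    fgrid <- as.numeric(sg$f)
  }
  sel <- fgrid >= band[1] & fgrid <= band[2]
  bp <- colMeans(power[sel, , drop = FALSE])
  structure(list(t = tgrid, f = fgrid, power = power, band_power = bp,
                 band = band, method = method), class = "spectrogram")
}

# Continuous Morlet wavelet transform via FFT convolution.
# Normalised so that a unit-amplitude sinusoid at an analysed frequency
# has |W|^2 ~ 1 at that frequency row.
morlet_cwt <- function(x, dt, freqs, omega0 = 6) {
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n))
  xf <- stats::fft(c(x, numeric(nfft - n)))
  ang <- 2 * pi * seq(0, nfft - 1) / nfft / dt      # rad/ms
  ang[ang > pi / dt] <- ang[ang > pi / dt] - 2 * pi / dt
  out <- matrix(0 + 0i, length(freqs), n)
  for (i in seq_along(freqs)) {
    w <- 2 * pi * freqs[i] / 1000                   # rad/ms
    scale <- omega0 / w
    # analytic Morlet in the frequency domain (positive frequencies only)
    H <- ifelse(ang > 0, exp(-0.5 * (scale * ang - omega0)^2), 0)
    wt <- stats::fft(xf * H, inverse = TRUE) / nfft
    out[i, ] <- 2 * wt[1:n]
  }
  out
}

#' Space-time spectrum of a 1D field run
#'
#' Two-dimensional Fourier power of the rate field `R(t, x)` after a
#' transient, with the dominant wavenumber/frequency pair and a drift
#' asymmetry index: for the dominant spatial mode, the normalised power
#' difference between the two temporal senses
#' (`+1`/`-1` = coherently travelling, `~0` = standing or static).
#'
#' @param run A `field_run` from [simulate_field_1d()].
#' @param transient_fraction Fraction of snapshots discarded.
#' @return A list with `k` (nonneg wavenumbers), `omega` (nonneg
#'   frequencies, rad/ms), `power` (matrix `length(omega) x length(k)`,
#'   senses folded), `k_dom`, `omega_dom`, `drift` (in `[-1, 1]`).
#' @export
spacetime_spectrum <- function(run, transient_fraction = 0.5) {
  n_t <- length(run$t)
  keep <- seq(max(1, floor(n_t * transient_fraction)), n_t)
  X <- run$R[keep, , drop = FALSE]
  X <- sweep(X, 2, colMeans(X))       # remove the static profile
  X <- X - mean(X)
  A <- stats::fft(X)                  # dims: (omega index, k index)
  P <- Mod(A)^2
  nt <- nrow(X); nx <- ncol(X)
  dt <- run$t[2] - run$t[1]
  L <- run$params$L
  n_om <- floor(nt / 2); n_k <- floor(nx / 2)
  omega <- 2 * pi * (0:n_om) / (nt * dt)
  k <- 2 * pi * (0:n_k) / L
  # fold the four quadrants onto (omega >= 0, k >= 0); keep senses to
  # measure drift: sense A = (+omega, +k), sense B = (-omega, +k)
  PA <- P[1:(n_om + 1), 1:(n_k + 1), drop = FALSE]
  PB <- P[c(1, nt:(nt - n_om + 1)), 1:(n_k + 1), drop = FALSE]
  Pfold <- PA + PB
  Pfold[1, ] <- PA[1, ]               # omega = 0 row counted once
  mask <- Pfold
  mask[1, 1] <- 0                     # ignore the residual mean
  i_dom <- which(mask == max(mask), arr.ind = TRUE)[1, ]
  k_dom <- k[i_dom[2]]
  omega_dom <- omega[i_dom[1]]
  drift <- if (i_dom[1] > 1 && i_dom[2] > 1) {
    a <- PA[i_dom[1], i_dom[2]]; b <- PB[i_dom[1], i_dom[2]]
    (a - b) / (a + b)
  } else 0
  list(k = k, omega = omega, power = Pfold,
       k_dom = k_dom, omega_dom = omega_dom, drift = drift)
}

#' Movement-related beta-rebound experiment
#'
#' Runs the single-population mass model with a temporally filtered
#' square pulse added to the background drive (mimicking a movement
#' lasting `duration` ms), computes the beta-band power of the synaptic
#' current `kappa_s * U`, and issues three verdicts: whether the
#' unperturbed system oscillates, whether band power drops during the
#' pulse, and whether it overshoots its baseline shortly after pulse
#' offset (the rebound).  Baseline is the mean band power over the 1000 ms
#' preceding onset; the drop/overshoot thresholds are 0.8x and 1.2x
#' baseline, and both verdicts additionally require an oscillatory
#' pre-pulse baseline (without a rhythm there is no band power to lose or
#' to rebound).
#'
#' @param p A [mass_params()] object (the beta-band regime uses
#'   `tau = 15`, `alpha = 0.1`).
#' @param t_on Pulse onset, ms (simulation starts 2000 ms before).
#' @param duration,magnitude,tau_f Pulse shape, see [filtered_pulse()].
#' @param dt Sampling step, ms.
#' @param band Frequency band in Hz.
#' @param method Spectrogram method passed on.
#' @return A list with `oscillates_pre`, `drop_during`, `overshoot_post`
#'   (logicals), `baseline`, `during`, `post_peak` (band powers), the
#'   `spectrogram`, and the model `trajectory`.
#' @examples
#' \donttest{
#' v <- beta_rebound_experiment(mass_params(eta0 = 1, kappa_v = 1,
#'                                          kappa_s = 1, alpha = 0.1))
#' c(v$oscillates_pre, v$drop_during, v$overshoot_post)
#' }
#' @export
beta_rebound_experiment <- function(p, t_on = 2000, duration = 400,
                                    magnitude = 3, tau_f = 50, dt = 1,
                                    band = c(13, 30),
                                    method = c("morlet", "stft")) {
  method <- match.arg(method)
  Tend <- t_on + duration + 1100
  A <- function(t) filtered_pulse(t, t_on = t_on, duration = duration,
                                  magnitude = magnitude, tau_f = tau_f)
  run <- simulate_mass(p, T = Tend, dt = dt, A = A, transient = 0)
  tr <- run$trajectory
  current <- p$kappa_s * tr$U
  # baseline oscillation check on the pre-pulse window
  pre <- tr$R[tr$t >= t_on - 1000 & tr$t < t_on]
  osc <- (max(pre) - min(pre)) > 1e-4
  # the STFT window must resolve the 400 ms drop: ~256 ms windows give
  # ~4 Hz bins, still adequate for the 13-30 Hz band
  nfft <- if (method == "stft") 2^round(log2(0.256 * 1000 / dt)) else NULL
  sp <- band_power_spectrogram(current, dt = dt, band = band,
                               method = method, nfft = nfft)
  bp <- sp$band_power
  bt <- sp$t
  baseline <- mean(bp[bt >= t_on - 1000 & bt < t_on])
  during <- mean(bp[bt >= t_on & bt < t_on + duration])
  post <- bp[bt >= t_on + duration & bt < t_on + duration + 500]
  post_peak <- if (length(post)) max(post) else NA_real_
  # a drop or rebound is only meaningful relative to an oscillatory
  # baseline: with no pre-pulse rhythm there is no beta power to lose
  list(oscillates_pre = osc,
       drop_during = isTRUE(osc && during < 0.8 * baseline),
       overshoot_post = isTRUE(osc && post_peak > 1.2 * baseline),
       baseline = baseline, during = during, post_peak = post_peak,
       spectrogram = sp, trajectory = tr)
}
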