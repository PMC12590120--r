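# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# One-sided frequency grid of an n-point FFT at sampling rate fs.
fft_freqs <- function(n, fs) {
  k <- seq_len(n) - 1L
  f <- k / n * fs
  f[f > fs / 2] <- f[f > fs / 2] - fs
  f
}

# Cosine-tapered spectral mask: 1 inside [lo, hi], raised-cosine roll-off of
# width `trans` on either side, 0 beyond. Operates on |f|.
spectral_mask <- function(f, lo, hi, trans) {
  af <- abs(f)
  m <- numeric(length(f))
  m[af >= lo & af <= hi] <- 1
  if (trans > 0) {
    lo_band <- af >= (lo - trans) & af < lo
    m[lo_band] <- 0.5 * (1 + cos(pi * (lo - af[lo_band]) / trans))
    hi_band <- af > hi & af <= (hi + trans)
    m[hi_band] <- 0.5 * (1 + cos(pi * (af[hi_band] - hi) / trans))
  }
  m
}

# Zero-phase band-pass via FFT with mirror padding against wrap-around.
# lo = 0 gives a low-pass that preserves DC exactly.
fft_bandpass <- function(x, fs, lo, hi, trans = 0.5) {
  n <- length(x)
  pad <- min(n, ceiling(2 * fs / max(trans, 1e-6)))
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[(n - pad + 1L):n]))
  np <- length(xp)
  f <- fft_freqs(np, fs)
  m <- if (lo <= 0) {
    mm <- spectral_mask(f, 0, hi, trans)
    mm[abs(f) <= hi] <- pmax(mm[abs(f) <= hi], 1)  # flat to DC
    mm
  } else {
    spectral_mask(f, lo, hi, trans)
  }
  y <- Re(stats::fft(stats::fft(xp) * m, inverse = TRUE)) / np
  y[(pad + 1L):(pad + n)]
}

# Analytic signal of the band-passed trace, in one spectral pass.
fft_analytic_band <- function(x, fs, lo, hi, trans = 0.5) {
  n <- length(x)
  pad <- min(n, ceiling(2 * fs / max(trans, 1e-6)))
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[(n - pad + 1L):n]))
  np <- length(xp)
  f <- fft_freqs(np, fs)
  m <- spectral_mask(f, lo, hi, trans)
  # analytic: keep positive frequencies doubled, kill negative ones
  m[f < 0] <- 0
  m[f > 0] <- 2 * m[f > 0]
  z <- stats::fft(stats::fft(xp) * m, inverse = TRUE) / np
  z[(pad + 1L):(pad + n)]
}

# Gaussian-profile spectrally shaped noise, unit RMS.
shaped_noise_gaussian <- function(n, fs, center, sd_hz) {
  w <- stats::rnorm(n)
  f <- fft_freqs(n, fs)
  g <- exp(-(abs(f) - center)^2 / (2 * sd_hz^2))
  y <- Re(stats::fft(stats::fft(w) * g, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

# 1/f-shaped background noise with target one-sided PSD
# 10^offset / f^exponent (units^2/Hz); flat below 0.5 Hz to avoid blow-up.
aperiodic_noise <- function(n, fs, offset, exponent) {
  w <- stats::rnorm(n)
  f <- abs(fft_freqs(n, fs))
  f[f < 0.5] <- 0.5
  amp <- sqrt(10^offset / f^exponent)
  # scale so that the realized one-sided PSD matches the target density:
  # white noise has one-sided PSD 2/fs per unit variance
  amp <- amp / sqrt(2 / fs)
  Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / n
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}
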