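# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no data files.

# Small standing-session config with optional overrides.
quick_config <- function(state = "stand", duration_s = 30, seed = 1L, ...) {
  session_config(movement_state = state, duration_s = duration_s,
                 seed = seed, ...)
}

# Construct a power_spectrum object directly from a vector of power values
# (default 1 Hz grid starting at 0).
make_spectrum <- function(power, fs = 500, freqs = seq_along(power) - 1) {
  structure(list(freqs = freqs, power = power, fs = fs,
                 window_s = 1, overlap = 0.5, scaling = "constructed"),
            class = "power_spectrum")
}

# Power-law + optional Gaussian-peak spectrum in linear power units on
# freqs 1..48 (with a 0 Hz bin prepended so the grid matches Welch output).
powerlaw_spectrum <- function(offset = 0, exponent = 1, peaks = NULL,
                              fmax = 60, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- 1:fmax
  logp <- offset - exponent * log10(f)
  if (!is.null(peaks)) {
    for (pk in peaks) {
      logp <- logp + pk$height * exp(-(f - pk$center)^2 / (2 * (pk$width / 2.355)^2))
    }
  }
  if (noise_sd > 0) logp <- logp + rnorm(length(f), sd = noise_sd)
  make_spectrum(c(10^(offset + 0.5), 10^logp))
}

# Synthetic alpha-candidate spectrum, piecewise linear on 0..60 Hz with
# explicit adjacent local minima at `lmin`/`rmin` around a peak at `center`,
# and a controllable 20-50 Hz level (`high`). With the defaults: peak 10 Hz,
# width 13.5 - 6 = 7.5 Hz, peak/high-band ratio = peak/high.
alpha_test_spectrum <- function(center = 10, peak = 10, lmin = 6,
                                rmin = 13.5, high = 1, with_peak = TRUE,
                                step = 0.5) {
  knots_x <- if (with_peak) c(0, lmin, center, rmin, 17, 20, 50, 60)
             else c(0, 6, 17, 20, 50, 60)
  knots_y <- if (with_peak) c(5, 1, peak, 1.05, 1.3, high, high, 0.9 * high)
             else c(5, 1, 1.3, high, high, 0.9 * high)
  f <- seq(0, 60, by = step)
  p <- stats::approx(knots_x, knots_y, xout = f)$y
  make_spectrum(p, freqs = f)
}

# Mixing matrix with named channels where one column peaks occipitally or
# frontally.
topo_matrix <- function(n_comp, occipital_comp = integer(0)) {
  labels <- rownames(ambulassr:::montage_layout()$pos)
  M <- matrix(0.1, length(labels), n_comp, dimnames = list(labels, NULL))
  for (j in seq_len(n_comp)) {
    if (j %in% occipital_comp) M["POz", j] <- 1 else M["Fz", j] <- 1
  }
  M
}
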