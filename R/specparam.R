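# Spectral parameterization: separate the aperiodic (1/f) component from
# periodic Gaussian peaks; "parameterized power" is peak height over and
# above the aperiodic fit, in log10 units.

gaussian_log <- function(f, center, height, sd) {
  height * exp(-(f - center)^2 / (2 * sd^2))
}

# Aperiodic model in log-log space: log10 P = offset - exponent * log10 f.
fit_aperiodic <- function(logf, logp) {
  co <- stats::coef(stats::lm(logp ~ logf))
  c(offset = unname(co[1]), exponent = unname(-co[2]))
}

# Robust initial aperiodic fit: OLS, then refit on the points least above the
# first fit (peaks only push residuals upward).
fit_aperiodic_robust <- function(logf, logp, keep_quantile = 0.5) {
  ap <- fit_aperiodic(logf, logp)
  resid <- logp - (ap["offset"] - ap["exponent"] * logf)
  thr <- stats::quantile(resid, keep_quantile)
  sel <- resid <= thr
  if (sum(sel) >= 3) ap <- fit_aperiodic(logf[sel], logp[sel])
  ap
}

# Guess one Gaussian from the flattened spectrum: center at the maximum bin,
# height there, width from the half-height span (clipped to the bounds).
# Guessing (rather than per-peak least squares) keeps adjacent narrow lines
# from being straddled by a single wide fit; the joint refit sharpens later.
guess_one_peak <- function(f, flat, min_height, width_bounds) {
  i <- which.max(flat)
  h0 <- flat[i]
  if (h0 < min_height) return(NULL)
  above <- flat >= h0 / 2
  run <- rle(above)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  j <- which(run$values & starts <= i & ends >= i)
  span <- f[ends[j]] - f[starts[j]]
  s0 <- min(max(span / 2.355, width_bounds[1] / 2.355),
            width_bounds[2] / 2.355)
  c(center = f[i], height = h0, sd = s0)
}

#' Parameterize a power spectrum into aperiodic and periodic parts
#'
#' Iterative procedure: robust aperiodic fit in log-log space; subtract;
#' extract Gaussian peaks from the flattened spectrum largest-first (up to
#' `max_peaks`, minimum over-aperiodic height `min_height` log10 units, width
#' bounds in Hz); refit the aperiodic component on the peak-removed spectrum;
#' jointly refit the Gaussians on the final flattened spectrum. The aperiodic
#' mode is fixed (no knee), which suits fit ranges ending well below ~100 Hz.
#'
#' @param spec a [welch_psd()] `power_spectrum` (strictly positive on the fit
#'   range).
#' @param fit_range frequency range in Hz, default `c(1, 48)`.
#' @param max_peaks maximum number of Gaussian peaks (6).
#' @param min_height minimum peak height in log10 units over the aperiodic
#'   fit (0.05).
#' @param rel_thresh relative detection threshold: peak extraction stops when
#'   the next candidate falls below `rel_thresh` standard deviations of the
#'   current flattened spectrum (2).
#' @param width_bounds full-width bounds for peaks in Hz (`c(1, 12)`).
#' @return a `parameterized_spectrum`: `aperiodic` (offset, exponent),
#'   `peaks` data.frame (center_hz, height_log10, width_hz), `fit_range`,
#'   `freqs`, `residual_rmse`, and the unit convention in `units`.
#' @export
fit_parameterized <- function(spec, fit_range = c(1, 48), max_peaks = 6,
                              min_height = 0.05, width_bounds = c(1, 12),
                              rel_thresh = 2) {
  sel <- spec$freqs >= fit_range[1] & spec$freqs <= fit_range[2]
  f <- spec$freqs[sel]
  p <- spec$power[sel]
  if (length(f) < 5) stop("fit range outside the spectrum")
  if (any(p <= 0)) stop("spectrum must be strictly positive on the fit range")
  logf <- log10(f)
  logp <- log10(p)

  ap <- fit_aperiodic_robust(logf, logp)
  flat <- logp - (ap["offset"] - ap["exponent"] * logf)

  # guess-and-refine: after each new guess all current Gaussians are refit
  # jointly on the flattened spectrum, so residual shoulders of a coarse
  # width guess are absorbed instead of spawning spurious side peaks
  peaks <- list()
  work <- flat
  for (k in seq_len(max_peaks)) {
    thr <- max(min_height, rel_thresh * stats::sd(work))
    pk <- guess_one_peak(f, pmax(work, 0), thr, width_bounds)
    if (is.null(pk)) break
    peaks[[k]] <- pk
    peaks <- joint_refit_peaks(f, flat, peaks, min_height, width_bounds)
    if (!length(peaks)) break
    model_k <- Reduce(`+`, lapply(peaks, function(q)
      gaussian_log(f, q["center"], q["height"], q["sd"])))
    work <- flat - model_k
    if (length(peaks) < k) break
  }

  if (length(peaks)) {
    peak_model <- Reduce(`+`, lapply(peaks, function(pk)
      gaussian_log(f, pk["center"], pk["height"], pk["sd"])))
    ap <- fit_aperiodic(logf, logp - peak_model)
    flat <- logp - (ap["offset"] - ap["exponent"] * logf)
    # joint refit of all Gaussians on the final flattened spectrum
    peaks <- joint_refit_peaks(f, flat, peaks, min_height, width_bounds)
  }

  model <- ap["offset"] - ap["exponent"] * logf
  if (length(peaks))
    model <- model + Reduce(`+`, lapply(peaks, function(pk)
      gaussian_log(f, pk["center"], pk["height"], pk["sd"])))

  pk_df <- if (length(peaks)) {
    data.frame(center_hz = vapply(peaks, `[[`, 0, "center"),
               height_log10 = vapply(peaks, `[[`, 0, "height"),
               width_hz = vapply(peaks, `[[`, 0, "sd") * 2.355)
  } else {
    data.frame(center_hz = numeric(0), height_log10 = numeric(0),
               width_hz = numeric(0))
  }
  pk_df <- pk_df[order(-pk_df$height_log10), , drop = FALSE]
  rownames(pk_df) <- NULL

  structure(list(aperiodic = ap, peaks = pk_df, fit_range = fit_range,
                 freqs = f, residual_rmse = sqrt(mean((logp - model)^2)),
                 units = "peak heights in log10 power units over the aperiodic fit"),
            class = "parameterized_spectrum")
}

# Joint least-squares refit of all guessed Gaussians on the flattened
# spectrum. Each center is bounded near its guess (± half the guessed FWHM,
# at least ±1 grid step) so neighboring lines cannot be absorbed into one
# broad straddling component.
joint_refit_peaks <- function(f, flat, peaks, min_height, width_bounds) {
  k <- length(peaks)
  start <- unlist(lapply(seq_len(k), function(i)
    stats::setNames(peaks[[i]], paste0(c("c", "h", "s"), i))))
  form <- paste0("y ~ ", paste(sprintf("h%d * exp(-(f - c%d)^2 / (2 * s%d^2))",
                                       seq_len(k), seq_len(k), seq_len(k)),
                               collapse = " + "))
  df <- data.frame(f = f, y = flat)
  step <- stats::median(diff(f))
  slack <- vapply(peaks, function(pk)
    max(step, pk[["sd"]] * 2.355 / 2), 0)
  # a peak's fitted height may not exceed the largest observed flattened
  # value by more than a noise allowance: narrow lines on a coarse grid
  # would otherwise trade width against unbounded height
  h_max <- max(flat) + 0.3
  lower <- unlist(lapply(seq_len(k), function(i)
    c(peaks[[i]][["center"]] - slack[i], min_height / 2,
      width_bounds[1] / 2.355)))
  upper <- unlist(lapply(seq_len(k), function(i)
    c(peaks[[i]][["center"]] + slack[i], h_max, width_bounds[2] / 2.355)))
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    stats::as.formula(form), data = df,
    start = as.list(start), lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 300))),
    silent = TRUE)
  if (inherits(fit, "try-error")) return(peaks)
  co <- stats::coef(fit)
  out <- lapply(seq_len(k), function(i)
    c(center = co[[paste0("c", i)]], height = co[[paste0("h", i)]],
      sd = co[[paste0("s", i)]]))
  out[vapply(out, function(pk) pk["height"] >= min_height, TRUE)]
}

#' @export
print.parameterized_spectrum <- function(x, ...) {
  cat(sprintf("<parameterized_spectrum> [%g, %g] Hz: offset %.3f, exponent %.3f, %d peak(s)\n",
              x$fit_range[1], x$fit_range[2], x$aperiodic["offset"],
              x$aperiodic["exponent"], nrow(x$peaks)))
  if (nrow(x$peaks)) print(round(x$peaks, 3))
  invisible(x)
}

#' Parameterized power at a target frequency
#'
#' Height (log10 units over the aperiodic fit) of the detected peak whose
#' center lies within `tol` of `target_hz`; 0 when none. When two candidate
#' peaks fall within `tol`, the one closer to the target wins. For the alpha
#' band, pass `band = c(8, 14)` to sum the heights of all peaks with centers
#' inside the band instead.
#'
#' @param ps a [fit_parameterized()] result.
#' @param target_hz target frequency (inside the fit range).
#' @param tol matching tolerance in Hz (1).
#' @param band optional length-2 band; overrides target matching.
#' @return nonnegative scalar.
#' @export
parameterized_power <- function(ps, target_hz = NULL, tol = 1, band = NULL) {
  if (!is.null(band)) {
    sel <- ps$peaks$center_hz >= band[1] & ps$peaks$center_hz <= band[2]
    return(sum(ps$peaks$height_log10[sel]))
  }
  if (target_hz < ps$fit_range[1] || target_hz > ps$fit_range[2])
    stop("target outside the fit range")
  if (!nrow(ps$peaks)) return(0)
  d <- abs(ps$peaks$center_hz - target_hz)
  i <- which(d <= tol)
  if (!length(i)) return(0)
  ps$peaks$height_log10[i[which.min(d[i])]]
}
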