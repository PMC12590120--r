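# Preprocessing: rereferencing, zero-phase filtering, Welch spectra,
# PCA + Infomax ICA decomposition and back-projection.

#' Rereference to the average of two earlobe electrodes
#'
#' Subtracts the samplewise mean of the two reference channels from every EEG
#' and reference channel. EOG channels and the event table are untouched.
#'
#' @param rec an [new_recording()].
#' @param ref_labels the two reference channel labels.
#' @return a rereferenced `assr_recording`.
#' @export
rereference <- function(rec, ref_labels = c("A1", "A2")) {
  miss <- setdiff(ref_labels, rec$labels)
  if (length(miss)) stop("missing reference channel(s): ",
                         paste(miss, collapse = ", "))
  refmean <- colMeans(rec$data[ref_labels, , drop = FALSE])
  out <- rec
  idx <- which(rec$roles %in% c("eeg", "ref"))
  out$data[idx, ] <- sweep(rec$data[idx, , drop = FALSE], 2, refmean)
  out
}

#' Filter specification
#'
#' Defaults follow the analysis chain: 1 Hz high-pass, 100 Hz low-pass, and a
#' 49.5–50.5 Hz band-stop against 50 Hz line noise, all applied zero-phase
#' (forward-backward) so ERP latencies are not shifted. Butterworth designs;
#' orders are per pass (attenuation doubles under filtfilt).
#'
#' @param highpass_hz,lowpass_hz,bandstop_hz cutoffs in Hz.
#' @param hp_order,lp_order,bs_order Butterworth orders per pass.
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(highpass_hz = 1, lowpass_hz = 100,
                        bandstop_hz = c(49.5, 50.5),
                        hp_order = 2, lp_order = 4, bs_order = 2) {
  if (highpass_hz >= lowpass_hz) stop("highpass must lie below lowpass")
  if (!is.null(bandstop_hz) &&
      (bandstop_hz[1] <= highpass_hz || bandstop_hz[2] >= lowpass_hz))
    stop("bandstop must lie inside the passband")
  structure(list(highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
                 bandstop_hz = bandstop_hz, hp_order = hp_order,
                 lp_order = lp_order, bs_order = bs_order),
            class = "filter_spec")
}

filtfilt_safe <- function(filt, x) {
  as.numeric(signal::filtfilt(filt, x))
}

#' Apply zero-phase filters to a recording
#'
#' High-pass, low-pass and band-stop filtering of every channel
#' (forward-backward Butterworth). Events are left untouched and aligned.
#'
#' @param rec an `assr_recording`.
#' @param spec a [filter_spec()].
#' @return the filtered recording.
#' @export
apply_filters <- function(rec, spec = filter_spec()) {
  fs <- rec$fs
  if (fs <= 2 * spec$lowpass_hz) stop("sampling rate too low for the low-pass")
  if (ncol(rec$data) < 9 * max(spec$hp_order, spec$lp_order))
    stop("signal shorter than filter warm-up")
  hp <- signal::butter(spec$hp_order, spec$highpass_hz / (fs / 2), type = "high")
  lp <- signal::butter(spec$lp_order, spec$lowpass_hz / (fs / 2), type = "low")
  bs <- if (!is.null(spec$bandstop_hz))
    signal::butter(spec$bs_order, spec$bandstop_hz / (fs / 2), type = "stop")
  out <- rec
  for (i in seq_len(nrow(rec$data))) {
    x <- filtfilt_safe(hp, rec$data[i, ])
    x <- filtfilt_safe(lp, x)
    if (!is.null(bs)) x <- filtfilt_safe(bs, x)
    out$data[i, ] <- x
  }
  out
}

#' Welch power spectral density
#'
#' Hamming-windowed segment averaging: 1 s windows with 50% overlap by
#' default, giving a 1 Hz frequency grid. One-sided density in
#' input-units²/Hz.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param window_s segment length in seconds.
#' @param overlap fractional overlap in `[0, 1)`.
#' @return a `power_spectrum`: list with `freqs`, `power`, `fs`, `window_s`,
#'   `overlap`, `scaling`.
#' @export
welch_psd <- function(x, fs, window_s = 1, overlap = 0.5) {
  nwin <- round(window_s * fs)
  if (length(x) < 2 * nwin * (1 - overlap) + nwin * overlap)
    stop("signal too short for two Welch segments")
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  w <- signal::hamming(nwin)
  u <- sum(w^2)
  nf <- nwin %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1L)] * w
    X <- stats::fft(seg)[seq_len(nf)]
    acc <- acc + (Mod(X)^2) / (fs * u)
  }
  p <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nwin is even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nwin %% 2 == 0) dbl[nf] <- 1
  p <- p * dbl
  structure(list(freqs = (seq_len(nf) - 1L) * fs / nwin, power = p, fs = fs,
                 window_s = window_s, overlap = overlap,
                 scaling = "one-sided density, Hamming, units^2/Hz"),
            class = "power_spectrum")
}

#' Decompose EEG into independent components
#'
#' Dimensionality reduction to `n_dims` principal components followed by
#' extended Infomax ICA (`ica::icaimax`, sign-switching handles sub-Gaussian
#' sources such as sinusoids). Operates on the channels with role `"eeg"`.
#' Deterministic given `seed`. An alternative FastICA backend is available
#' behind the same contract.
#'
#' @param rec an `assr_recording` (filtered).
#' @param n_dims number of retained dimensions (16 for an 18-channel montage).
#' @param seed integer seed (recorded in the output).
#' @param method `"infomax"` (default) or `"fastica"`.
#' @param maxit,tol iteration controls, recorded in the output.
#' @return a `component_decomposition`: `unmixing` (components x channels),
#'   `mixing` (channels x components), `activations` (components x samples),
#'   `channel_labels`, `center`, `n_dims`, `seed`, `method`.
#' @export
decompose <- function(rec, n_dims = 16, seed = 1L, method = c("infomax", "fastica"),
                      maxit = 200, tol = 1e-6) {
  method <- match.arg(method)
  labels <- channels_by_role(rec, "eeg")
  if (length(labels) < n_dims)
    stop("need at least n_dims EEG channels")
  X <- rec$data[labels, , drop = FALSE]           # channels x samples
  if (qr(X)$rank < n_dims) stop("data rank below n_dims")
  center <- rowMeans(X)
  Xc <- X - center
  set.seed(seed)
  fit <- if (method == "infomax") {
    ica::icaimax(t(Xc), nc = n_dims, maxit = maxit, tol = tol,
                 fun = "tanh", signswitch = TRUE)
  } else {
    ica::icafast(t(Xc), nc = n_dims, maxit = maxit, tol = tol)
  }
  mixing <- fit$M                                  # channels x components
  # least-squares unmixing (components x channels)
  unmixing <- solve(crossprod(mixing), t(mixing))
  activations <- unmixing %*% Xc
  dimnames(mixing) <- list(labels, paste0("IC", seq_len(n_dims)))
  dimnames(unmixing) <- list(paste0("IC", seq_len(n_dims)), labels)
  structure(list(unmixing = unmixing, mixing = mixing,
                 activations = activations, channel_labels = labels,
                 center = center, n_dims = n_dims, seed = seed,
                 method = method, maxit = maxit, tol = tol,
                 fs = rec$fs),
            class = "component_decomposition")
}

#' @export
print.component_decomposition <- function(x, ...) {
  cat(sprintf("<component_decomposition> %d components from %d channels (%s, seed %d)\n",
              x$n_dims, length(x$channel_labels), x$method, x$seed))
  invisible(x)
}

#' Welch spectra of every component activation
#'
#' @param decomp a [decompose()] result.
#' @param fs sampling rate; defaults to the one stored in the decomposition.
#' @param window_s,overlap Welch parameters (1 s, 50%).
#' @return list of `power_spectrum`, one per component.
#' @export
component_spectra <- function(decomp, fs = decomp$fs, window_s = 1,
                              overlap = 0.5) {
  lapply(seq_len(nrow(decomp$activations)), function(i)
    welch_psd(decomp$activations[i, ], fs, window_s, overlap))
}

#' Back-project components to sensor space
#'
#' `mixing[, keep] %*% activations[keep, ]` on the decomposition's channels.
#' Backprojecting all retained components reproduces the rank-`n_dims` PCA
#' approximation of the (centered) data; backprojections of disjoint subsets
#' sum to the full one.
#'
#' @param decomp a [decompose()] result.
#' @param keep integer ids of components to retain.
#' @param rec optional original recording; when given, the non-EEG channels
#'   and events are carried through and a full `assr_recording` is returned.
#' @return an `assr_recording` (if `rec` given) or a channels x samples matrix.
#' @export
backproject <- function(decomp, keep, rec = NULL) {
  if (!length(keep)) stop("`keep` must name at least one component")
  if (any(keep < 1 | keep > decomp$n_dims)) stop("invalid component id(s)")
  proj <- decomp$mixing[, keep, drop = FALSE] %*%
    decomp$activations[keep, , drop = FALSE]
  if (is.null(rec)) return(proj)
  out <- rec
  out$data[decomp$channel_labels, ] <- proj
  out
}
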