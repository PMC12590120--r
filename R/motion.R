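# Gait-turn extraction from gyroscope traces and event-locked epoching.

#' Low-pass filter the yaw channel of a motion trace
#'
#' Zero-phase spectral low-pass of the yaw (vertical-axis angular velocity)
#' channel; the other channels pass through unchanged. The default 0.3 Hz
#' cutoff sits between the turn fundamental (~1/12 Hz on a ~12 s lap) and the
#' ~2 Hz gait ripple. DC is preserved exactly.
#'
#' @param motion a [new_motion_trace()].
#' @param cutoff_hz cutoff frequency, below Nyquist.
#' @param trans_hz transition width of the cosine roll-off.
#' @return the motion trace with a low-passed yaw channel.
#' @export
lowpass_yaw <- function(motion, cutoff_hz = 0.3, trans_hz = 0.3) {
  if (cutoff_hz <= 0 || cutoff_hz >= motion$fs / 2)
    stop("cutoff must lie in (0, fs/2)")
  out <- motion
  out$gyro[3L, ] <- fft_bandpass(yaw_channel(motion), motion$fs,
                                 lo = 0, hi = cutoff_hz, trans = trans_hz)
  attr(out, "truth") <- attr(motion, "truth")
  out
}

#' Detect walking turns from a low-passed yaw trace
#'
#' Positive local maxima above the magnitude threshold become left turns and
#' negative local minima below its negative become right turns (sign
#' convention flippable via `left_positive`). Apices closer than
#' `min_separation_s` are merged keeping the larger magnitude. The turn
#' duration is the span over which |yaw| exceeds half the apex magnitude.
#'
#' The default threshold is adaptive — half the median absolute apex
#' magnitude over a calibration pass — but never falls below
#' `floor_dps`, so that a standing recording (noise-only yaw) yields no
#' turns.
#'
#' @param motion a low-passed motion trace.
#' @param min_separation_s minimum apex separation (s).
#' @param magnitude_threshold absolute yaw-rate threshold (deg/s), or `NULL`
#'   for the adaptive default.
#' @param floor_dps lower bound of the adaptive threshold.
#' @param left_positive if `TRUE` (default) positive yaw = left turn.
#' @return data.frame of turn events: `apex_sample` (0-based, motion clock),
#'   `apex_time_s`, `direction`, `duration_s`, `peak_magnitude`.
#' @export
detect_turns <- function(motion, min_separation_s = 3,
                         magnitude_threshold = NULL, floor_dps = 10,
                         left_positive = TRUE) {
  y <- yaw_channel(motion)
  fs <- motion$fs
  ex <- local_extrema(y)
  cand <- c(ex$maxima, ex$minima)
  if (is.null(magnitude_threshold)) {
    mags <- abs(y[cand])
    magnitude_threshold <- max(floor_dps,
                               0.5 * stats::median(mags[mags > 0]))
    if (!length(cand)) magnitude_threshold <- floor_dps
  }
  peaks <- c(ex$maxima[y[ex$maxima] > magnitude_threshold],
             ex$minima[y[ex$minima] < -magnitude_threshold])
  if (!length(peaks))
    return(data.frame(apex_sample = integer(0), apex_time_s = numeric(0),
                      direction = character(0), duration_s = numeric(0),
                      peak_magnitude = numeric(0), stringsAsFactors = FALSE))
  peaks <- sort(peaks)
  # merge apices closer than min_separation_s, keeping the larger magnitude
  keep <- logical(length(peaks))
  i <- 1L
  while (i <= length(peaks)) {
    grp <- i
    while (max(grp) < length(peaks) &&
           (peaks[max(grp) + 1L] - peaks[i]) / fs < min_separation_s)
      grp <- c(grp, max(grp) + 1L)
    keep[grp[which.max(abs(y[peaks[grp]]))]] <- TRUE
    i <- max(grp) + 1L
  }
  peaks <- peaks[keep]

  rows <- lapply(peaks, function(j) {
    mag <- y[j]
    half <- abs(mag) / 2
    sgn <- sign(mag)
    lo <- j; while (lo > 1L && sgn * y[lo - 1L] > half) lo <- lo - 1L
    hi <- j; while (hi < length(y) && sgn * y[hi + 1L] > half) hi <- hi + 1L
    dir <- if ((mag > 0) == left_positive) "left" else "right"
    data.frame(apex_sample = j - 1L, apex_time_s = (j - 1L) / fs,
               direction = dir, duration_s = (hi - lo + 1L) / fs,
               peak_magnitude = abs(mag), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$apex_sample), , drop = FALSE]
}

#' Epoch a recording around event times
#'
#' Cuts trials of exactly `round(2 * half_width_s * fs) + 1` samples centered
#' on each event time (mapped from seconds to the nearest EEG sample, so
#' motion-clock events at 120 Hz land within one EEG sample at 500 Hz).
#' Events whose window would exceed the recording bounds are dropped and
#' counted.
#'
#' @param rec an `assr_recording`.
#' @param times_s event times in seconds.
#' @param half_width_s half window width (2 s giving 4 s trials).
#' @param channels channel subset, default all.
#' @param lock_kind label stored in the epoch set.
#' @return an [new_epoch_set()].
#' @export
epoch_by_events <- function(rec, times_s, half_width_s = 2,
                            channels = rec$labels, lock_kind = "event") {
  mat <- rec$data[channels, , drop = FALSE]
  ep <- epoch_matrix(mat, rec$fs, times_s, half_width_s)
  if (!length(ep$kept)) stop("no usable events (all windows out of bounds)")
  new_epoch_set(ep$data, ep$time, rec$fs, lock_kind = lock_kind,
                trial_ids = ep$kept, n_dropped = ep$n_dropped,
                channels = channels)
}

# Shared epoching core for channel matrices; returns trials x channels x time.
epoch_matrix <- function(mat, fs, times_s, half_width_s) {
  hw <- round(half_width_s * fs)
  centers <- round(times_s * fs) + 1L   # 1-based center sample
  ok <- centers - hw >= 1L & centers + hw <= ncol(mat)
  kept <- which(ok)
  nt <- 2L * hw + 1L
  data <- array(NA_real_, c(length(kept), nrow(mat), nt))
  for (k in seq_along(kept)) {
    c0 <- centers[kept[k]]
    data[k, , ] <- mat[, (c0 - hw):(c0 + hw), drop = FALSE]
  }
  list(data = data, time = (-hw:hw) / fs, kept = kept,
       n_dropped = sum(!ok))
}

#' Epoch a single time series around event times
#'
#' Convenience wrapper of the same trial geometry for one-dimensional series
#' (e.g. a lateralization index): returns a trials x time matrix.
#'
#' @param values numeric vector.
#' @param fs sampling rate (Hz).
#' @param times_s event times (s).
#' @param half_width_s half window (s).
#' @return list with `trials` (matrix), `time`, `kept`, `n_dropped`.
#' @export
epoch_series <- function(values, fs, times_s, half_width_s = 2) {
  ep <- epoch_matrix(matrix(values, 1), fs, times_s, half_width_s)
  tr <- matrix(ep$data[, 1, ], nrow = dim(ep$data)[1])
  list(trials = tr, time = ep$time, kept = ep$kept, n_dropped = ep$n_dropped)
}
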