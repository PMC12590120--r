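# Time-resolved ASSR power, the 39/41 Hz lateralization index, turn-locked
# contrasts, and burst-perturbation responses.

#' Time-resolved narrowband power
#'
#' Squared magnitude of the analytic signal of the band-passed trace
#' (passband `center_hz` ± `bw_hz`, zero-phase spectral filter with a
#' documented cosine transition). Computed on the continuous block before any
#' epoching. For a sinusoid of amplitude A inside the band the value is A².
#' The first and last `edge_trim_s` seconds are contaminated by edge effects
#' and are flagged, not silently dropped.
#'
#' @param x numeric vector (e.g. a frontocentral channel average), or an
#'   `assr_recording` (then `channels` selects and averages).
#' @param fs sampling rate (ignored when `x` is a recording).
#' @param center_hz band center (39/41, or 37/44 for the control).
#' @param bw_hz half bandwidth (0.5).
#' @param trans_hz transition width of the spectral taper (0.5).
#' @param edge_trim_s documented edge-contamination span (0.5).
#' @param channels channel set when `x` is a recording.
#' @return a `power_series`: `values` (µV²), `fs`, `center_hz`, `bw_hz`,
#'   `edge_trim_s`, `valid` (logical index of untrimmed samples).
#' @export
timeresolved_power <- function(x, fs = NULL, center_hz, bw_hz = 0.5,
                               trans_hz = 0.5, edge_trim_s = 0.5,
                               channels = frontocentral_channels()) {
  if (inherits(x, "assr_recording")) {
    fs <- x$fs
    x <- channel_average(x, channels)
  }
  if (is.null(fs)) stop("fs required for plain numeric input")
  if (center_hz + bw_hz >= fs / 2) stop("band outside Nyquist range")
  z <- fft_analytic_band(x, fs, center_hz - bw_hz, center_hz + bw_hz,
                         trans = trans_hz)
  v <- Mod(z)^2
  n <- length(v)
  trim <- round(edge_trim_s * fs)
  valid <- rep(TRUE, n)
  if (trim > 0) {
    valid[seq_len(min(trim, n))] <- FALSE
    valid[seq.int(max(1L, n - trim + 1L), n)] <- FALSE
  }
  structure(list(values = v, fs = fs, center_hz = center_hz, bw_hz = bw_hz,
                 edge_trim_s = edge_trim_s, valid = valid),
            class = "power_series")
}

#' ASSR lateralization index
#'
#' Elementwise `(P39 - P41) / (P39 + P41)`: positive values indicate
#' relatively stronger processing of the left-ear (39 Hz) input, negative of
#' the right-ear (41 Hz) input. Samples where the power sum is zero are
#' returned as `NA` and flagged.
#'
#' @param p39,p41 aligned `power_series` for the two modulation rates.
#' @return a `lateralization_series`: `values` in `[-1, 1]`, `fs`,
#'   `undefined` (indices with zero power sum), `valid`.
#' @export
lateralization_index <- function(p39, p41) {
  if (length(p39$values) != length(p41$values) || p39$fs != p41$fs)
    stop("power series are not aligned")
  s <- p39$values + p41$values
  li <- ifelse(s > 0, (p39$values - p41$values) / s, NA_real_)
  structure(list(values = li, fs = p39$fs,
                 undefined = which(s == 0),
                 valid = p39$valid & p41$valid,
                 constituents = c(p39$center_hz, p41$center_hz)),
            class = "lateralization_series")
}

#' Turn-locked lateralization contrast
#'
#' Epochs a lateralization series by turn apices (±`half_width_s`) per
#' direction and returns trial x time matrices for left and right turns,
#' ready for [cluster_permutation_test()]. Trials overlapping the
#' edge-trimmed block ends are dropped. Left and right trial counts are
#' equalized (the 8-shaped path alternates directions) so the cluster test
#' can pair trials by index.
#'
#' @param lat a [lateralization_index()] series.
#' @param turns data.frame from [detect_turns()].
#' @param half_width_s half window (2 s).
#' @return list: `left`, `right` (trials x time), `time`, `n_dropped`.
#' @export
turn_locked_contrast <- function(lat, turns, half_width_s = 2) {
  if (sum(turns$direction == "left") < 2 || sum(turns$direction == "right") < 2)
    stop("need at least 2 turns per direction")
  fs <- lat$fs
  # exclude apices whose window touches edge-trimmed samples
  first_ok <- (min(which(lat$valid)) - 1L) / fs
  last_ok <- (max(which(lat$valid)) - 1L) / fs
  usable <- turns$apex_time_s - half_width_s >= first_ok &
    turns$apex_time_s + half_width_s <= last_ok
  n_edge <- sum(!usable)
  turns <- turns[usable, , drop = FALSE]
  epl <- epoch_series(lat$values, fs, turns$apex_time_s[turns$direction == "left"],
                      half_width_s)
  epr <- epoch_series(lat$values, fs, turns$apex_time_s[turns$direction == "right"],
                      half_width_s)
  k <- min(nrow(epl$trials), nrow(epr$trials))
  if (k < 2) stop("need at least 2 usable turns per direction")
  list(left = epl$trials[seq_len(k), , drop = FALSE],
       right = epr$trials[seq_len(k), , drop = FALSE],
       time = epl$time,
       n_dropped = n_edge + epl$n_dropped + epr$n_dropped)
}

#' Turn-locked lateralization from a recording
#'
#' Convenience chain: frontocentral average -> time-resolved power at the two
#' band centers -> lateralization index -> turn-locked trial matrices. With
#' `freqs = c(37, 44)` this is the neighboring-frequency control that checks
#' the specificity of the 39/41 Hz effect.
#'
#' @param rec an `assr_recording`.
#' @param turns data.frame from [detect_turns()].
#' @param freqs band centers, `c(39, 41)` or `c(37, 44)`.
#' @param channels sensor set averaged before the band power.
#' @param half_width_s half window (2 s).
#' @return as [turn_locked_contrast()].
#' @export
assr_turn_contrast <- function(rec, turns, freqs = c(39, 41),
                               channels = frontocentral_channels(),
                               half_width_s = 2) {
  avg <- channel_average(rec, channels)
  pa <- timeresolved_power(avg, rec$fs, center_hz = freqs[1])
  pb <- timeresolved_power(avg, rec$fs, center_hz = freqs[2])
  lat <- lateralization_index(pa, pb)
  turn_locked_contrast(lat, turns, half_width_s)
}

#' @rdname assr_turn_contrast
#' @export
control_frequencies <- function(rec, turns, freqs = c(37, 44),
                                channels = frontocentral_channels(),
                                half_width_s = 2) {
  assr_turn_contrast(rec, turns, freqs = freqs, channels = channels,
                     half_width_s = half_width_s)
}

#' Burst-evoked ASSR perturbation response
#'
#' Trials (time-resolved power epoched to burst onsets) are averaged first;
#' the average is baseline-corrected with a log transform against the
#' prestimulus window and the response is the mean over the post-onset
#' window: `value(t) = 10 log10(P(t) / mean P(baseline))`, response = mean
#' over (0, 0.7] s, in dB.
#'
#' @param trials trials x time matrix of narrowband power, locked to burst
#'   onset.
#' @param time time axis in seconds (t = 0 at onset).
#' @param baseline_s baseline window, `c(-0.4, 0)`.
#' @param response_s response window, `c(0, 0.7)`.
#' @return a `perturbation_result`: `value` (mean dB over the response
#'   window), `series` (dB over time), `time`, `n_trials`, windows.
#' @export
perturbation_response <- function(trials, time, baseline_s = c(-0.4, 0),
                                  response_s = c(0, 0.7)) {
  if (!nrow(trials)) stop("empty condition cell")
  avg <- colMeans(trials)
  bl <- time >= baseline_s[1] & time <= baseline_s[2]
  series <- 10 * log10(avg / mean(avg[bl]))
  rs <- time > response_s[1] & time <= response_s[2]
  structure(list(value = mean(series[rs]), series = series, time = time,
                 n_trials = nrow(trials), baseline_s = baseline_s,
                 response_s = response_s),
            class = "perturbation_result")
}

#' Group bursts by the turn they fell into
#'
#' `mode = "direction"` labels each burst with the direction of the turn
#' whose apex ±`half_width_s` window contains it. `mode =
#' "entrainment_phase"` splits each window at the apex: bursts before the
#' apex fall in the half during which the turn-side ear is preferred
#' (`"pre"`), bursts at or after the apex in the opposite-preference half
#' (`"post"`; a burst exactly at the apex goes to `"post"`). Bursts outside
#' every window are `"unassigned"`.
#'
#' @param burst_times_s burst onset times (s).
#' @param turns data.frame from [detect_turns()].
#' @param mode `"direction"` or `"entrainment_phase"`.
#' @param half_width_s half window (2 s).
#' @return character vector of labels, one per burst: direction mode gives
#'   `"left"`/`"right"`/`"unassigned"`; phase mode gives
#'   `"left_preferred"`/`"right_preferred"`/`"unassigned"`.
#' @export
group_bursts_by_turn <- function(burst_times_s, turns,
                                 mode = c("direction", "entrainment_phase"),
                                 half_width_s = 2) {
  mode <- match.arg(mode)
  out <- rep("unassigned", length(burst_times_s))
  for (i in seq_along(burst_times_s)) {
    b <- burst_times_s[i]
    d <- abs(turns$apex_time_s - b)
    j <- which.min(d)
    if (!length(j) || d[j] > half_width_s) next
    if (mode == "direction") {
      out[i] <- turns$direction[j]
    } else {
      pre <- b < turns$apex_time_s[j]      # apex-coincident -> post half
      side <- turns$direction[j]
      pref <- if (pre) side else setdiff(c("left", "right"), side)
      out[i] <- paste0(pref, "_preferred")
    }
  }
  out
}
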