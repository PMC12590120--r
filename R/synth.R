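# Synthetic session generator: stimulus schedules, gyroscope traces, and
# forward-mixed EEG with known ground truth.
#
# The generator emulates the statistical structure the downstream analyses
# assume: cortical sinusoids at the two amplitude-modulation rates (39 Hz left
# ear, 41 Hz right ear) with frontocentral topography, an occipital alpha
# source, 1/f background per channel, burst-evoked ASSR amplitude dips and
# P1/P2 ERP deflections, and a turn-phase-locked antisymmetric gain on the
# 39/41 Hz sources during walking.

#' Stimulus configuration
#'
#' Dichotic amplitude-modulated tones: a 1000 Hz carrier modulated at 39 Hz in
#' the left ear and 41 Hz in the right ear, 100% modulation depth, rendered at
#' 44.1 kHz.
#'
#' @param carrier_hz carrier frequency (Hz).
#' @param mod_left_hz,mod_right_hz modulation rates for left/right ear (Hz).
#' @param depth modulation depth in `[0, 1]`.
#' @param audio_fs audio sampling rate (Hz), must exceed twice the carrier.
#' @return a `stimulus_config` list.
#' @export
stimulus_config <- function(carrier_hz = 1000, mod_left_hz = 39,
                            mod_right_hz = 41, depth = 1, audio_fs = 44100) {
  if (mod_left_hz == mod_right_hz) stop("modulation rates must differ")
  if (depth < 0 || depth > 1) stop("depth must lie in [0, 1]")
  if (audio_fs <= 2 * carrier_hz) stop("audio_fs must exceed 2x carrier")
  structure(list(carrier_hz = carrier_hz, mod_left_hz = mod_left_hz,
                 mod_right_hz = mod_right_hz, depth = depth,
                 audio_fs = audio_fs),
            class = "stimulus_config")
}

#' Generate a sinusoidally amplitude-modulated tone
#'
#' Returns `s(t) = (1 + depth * sin(2 pi f_mod t)) * sin(2 pi f_carrier t)`
#' sampled at the audio rate, with the modulation rate chosen by ear.
#'
#' @param cfg a [stimulus_config()].
#' @param side `"left"` (39 Hz default) or `"right"` (41 Hz default).
#' @param duration length in seconds, > 0.
#' @return list with `samples` (numeric vector) and `fs`.
#' @export
generate_am_tone <- function(cfg, side = c("left", "right"), duration) {
  side <- match.arg(side)
  if (!is.numeric(duration) || duration <= 0) stop("duration must be positive")
  f_mod <- if (side == "left") cfg$mod_left_hz else cfg$mod_right_hz
  t <- seq(0, duration - 1 / cfg$audio_fs, by = 1 / cfg$audio_fs)
  s <- (1 + cfg$depth * sin(2 * pi * f_mod * t)) * sin(2 * pi * cfg$carrier_hz * t)
  list(samples = s, fs = cfg$audio_fs)
}

#' Schedule perturbation bursts
#'
#' Draws, per burst kind, onset times with consecutive gaps uniform in
#' `interval_range` (3–7 s by convention: 8 bursts per kind while standing,
#' 32 while walking). Deterministic given `seed`.
#'
#' @param duration total available time (s).
#' @param n_per_kind number of bursts per kind.
#' @param kinds burst kinds (left/right ear dichotic, central diotic).
#' @param interval_range length-2 numeric, uniform gap bounds (s).
#' @param burst_dur_s burst duration (s), 0.1 by stimulus design.
#' @param seed integer seed.
#' @return a `burst_schedule`: data.frame `events` with `onset_s`, `kind`,
#'   plus `burst_dur_s` and `interval_range_s` fields.
#' @export
schedule_bursts <- function(duration, n_per_kind,
                            kinds = c("left", "right", "central"),
                            interval_range = c(3, 7), burst_dur_s = 0.1,
                            seed = 1L) {
  if (n_per_kind < 1) stop("n_per_kind must be >= 1")
  # feasibility at minimum spacing: first onset >= 1 s in
  if (duration < 1 + (n_per_kind - 1) * interval_range[1] + 1)
    stop("duration too short for requested bursts at minimum spacing")
  set.seed(seed)
  ev <- do.call(rbind, lapply(kinds, function(k) {
    repeat {
      gaps <- stats::runif(n_per_kind - 1, interval_range[1], interval_range[2])
      first <- stats::runif(1, 1, max(1, min(interval_range[2],
                                             duration - sum(gaps) - 1)))
      on <- cumsum(c(first, gaps))
      if (all(on < duration - burst_dur_s)) break
    }
    data.frame(onset_s = on, kind = k, stringsAsFactors = FALSE)
  }))
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  rownames(ev) <- NULL
  structure(list(events = ev, burst_dur_s = burst_dur_s,
                 interval_range_s = interval_range),
            class = "burst_schedule")
}

#' Session configuration for the synthetic generator
#'
#' Defaults mirror the study conditions: EEG at 500 Hz, motion at 120 Hz,
#' ~12 s laps on an 8-shaped path (so turn apices alternate every 6 s), ASSR
#' source amplitude ordered walk > step > stand, occipital alpha amplitude
#' ordered stand > step > walk, a 1/f background, a multiplicative 50% ASSR
#' amplitude dip for 300 ms after each burst, and P1/P2 ERP templates.
#'
#' @param movement_state `"stand"`, `"step"`, or `"walk"`.
#' @param duration_s session length for stand/step (walk length is
#'   `n_laps * lap_duration_s`).
#' @param assr_amp named list per state of c(f39, f41) source amplitudes (µV
#'   at the topography peak).
#' @param alpha_amp named numeric per state, alpha source RMS amplitude (µV).
#' @param aperiodic c(offset, exponent) of the 1/f background
#'   (log10 µV²/Hz at 1 Hz, and spectral slope).
#' @param n_background number of spatially smooth 1/f background sources
#'   mixed to the scalp (EEG background is spatially correlated and
#'   low-dimensional; independent per-channel noise would make blind source
#'   separation ill-posed).
#' @param lateralization_gain multiplicative gain `g` applied to the turn-side
#'   frequency before the apex (and its reciprocal to the other side), flipped
#'   after the apex; 1 disables the modulation.
#' @param erp_templates list of P1/P2 Gaussian templates
#'   (`lat_s`, `sd_s`, `amp_uV` each).
#' @param burst_dip list: fractional amplitude `depth`, hold `dur_s`,
#'   exponential `recovery_s`.
#' @param lap_duration_s,turn_duration_s,n_laps walking-path geometry.
#' @param turn_peak_dps peak yaw rate at a turn apex (deg/s).
#' @param step_ripple_dps 2 Hz gait ripple amplitude on the gyro (deg/s).
#' @param gyro_noise_dps white gyro noise SD (deg/s).
#' @param sensor_noise_uV white EEG sensor-noise SD (µV).
#' @param left_turn_positive yaw sign convention (right-hand rule about the
#'   vertical axis: left turn = positive yaw rate); flippable.
#' @param eeg_fs,motion_fs sampling rates (Hz).
#' @param seed integer seed.
#' @return a `session_config` list.
#' @export
session_config <- function(movement_state = c("walk", "stand", "step"),
                           duration_s = 120,
                           assr_amp = list(stand = c(0.35, 0.35),
                                           step  = c(0.55, 0.55),
                                           walk  = c(0.80, 0.80)),
                           alpha_amp = c(stand = 4, step = 3, walk = 2),
                           aperiodic = c(offset = 0, exponent = 1.2),
                           n_background = 10,
                           lateralization_gain = 1,
                           erp_templates = list(
                             P1 = list(lat_s = 0.165, sd_s = 0.015, amp_uV = 2.5),
                             P2 = list(lat_s = 0.325, sd_s = 0.025, amp_uV = 4.0)),
                           burst_dip = list(depth = 0.5, dur_s = 0.3,
                                            recovery_s = 0.15),
                           lap_duration_s = 12, turn_duration_s = 6.4,
                           n_laps = 10, turn_peak_dps = 45,
                           step_ripple_dps = 8, gyro_noise_dps = 2,
                           sensor_noise_uV = 0.5,
                           left_turn_positive = TRUE,
                           eeg_fs = 500, motion_fs = 120, seed = 1L) {
  movement_state <- match.arg(movement_state)
  stopifnot(all(unlist(assr_amp) >= 0), all(alpha_amp >= 0),
            eeg_fs == 500, motion_fs == 120,
            lap_duration_s > 4)  # must fit a ±2 s epoch per half lap
  structure(as.list(environment()), class = "session_config")
}

session_duration <- function(cfg) {
  if (cfg$movement_state == "walk") cfg$n_laps * cfg$lap_duration_s
  else cfg$duration_s
}

# Analytic apex times for the simulated 8-shaped path: yaw is a sinusoid with
# period lap_duration, so apices sit at lap/4 + k*lap/2, alternating sign.
true_apices <- function(cfg) {
  lap <- cfg$lap_duration_s
  times <- cfg$lap_duration_s / 4 + (seq_len(2 * cfg$n_laps) - 1) * lap / 2
  dir <- rep(c("left", "right"), cfg$n_laps)
  if (!cfg$left_turn_positive) dir <- rep(c("right", "left"), cfg$n_laps)
  data.frame(apex_time_s = times, direction = dir, stringsAsFactors = FALSE)
}

#' Simulate a waist-mounted gyroscope trace
#'
#' During walking the yaw channel holds one positive (left-turn) and one
#' negative (right-turn) smooth excursion per lap (sinusoid with the lap
#' period, apex spacing = half a lap), plus a 2 Hz gait ripple and white
#' noise. Standing yields noise only; stepping adds the ripple.
#'
#' @param cfg a [session_config()].
#' @return a [new_motion_trace()] with ground-truth apices in
#'   `attr(, "truth")`.
#' @export
simulate_gyro <- function(cfg) {
  if (cfg$movement_state == "walk" && cfg$n_laps < 1) stop("n_laps must be >= 1")
  set.seed(cfg$seed + 101L)
  dur <- session_duration(cfg)
  n <- round(dur * cfg$motion_fs)
  t <- (seq_len(n) - 1) / cfg$motion_fs
  yaw <- numeric(n)
  truth <- NULL
  if (cfg$movement_state == "walk") {
    sgn <- if (cfg$left_turn_positive) 1 else -1
    yaw <- sgn * cfg$turn_peak_dps * sin(2 * pi * t / cfg$lap_duration_s)
    truth <- true_apices(cfg)
  }
  ripple <- if (cfg$movement_state %in% c("walk", "step"))
    cfg$step_ripple_dps * sin(2 * pi * 2 * t) else 0
  gyro <- rbind(
    stats::rnorm(n, sd = cfg$gyro_noise_dps) + ripple,
    stats::rnorm(n, sd = cfg$gyro_noise_dps) + ripple,
    yaw + ripple + stats::rnorm(n, sd = cfg$gyro_noise_dps)
  )
  accel <- rbind(stats::rnorm(n, sd = 0.2) + if (is.numeric(ripple)) 0.5 * ripple / max(cfg$step_ripple_dps, 1) else 0,
                 stats::rnorm(n, sd = 0.2),
                 9.81 + stats::rnorm(n, sd = 0.2))
  out <- new_motion_trace(gyro, accel, fs = cfg$motion_fs, sensor = "waist")
  attr(out, "truth") <- truth
  out
}

# Synthetic montage: 18 scalp EEG channels, 2 earlobe references, 6 EOG.
# 2D positions (x = left-right, y = posterior-anterior) for Gaussian
# topography weights.
montage_layout <- function() {
  pos <- rbind(
    AFz = c(0, 0.85), Fz = c(0, 0.6), F3 = c(-0.4, 0.55), F4 = c(0.4, 0.55),
    FC1 = c(-0.2, 0.35), FC2 = c(0.2, 0.35), Cz = c(0, 0), C3 = c(-0.45, 0),
    C4 = c(0.45, 0), T7 = c(-0.9, 0), T8 = c(0.9, 0), Pz = c(0, -0.45),
    P3 = c(-0.4, -0.5), P4 = c(0.4, -0.5), POz = c(0, -0.7),
    O1 = c(-0.3, -0.9), O2 = c(0.3, -0.9), Oz = c(0, -0.95))
  list(pos = pos, eeg = rownames(pos))
}

# Gaussian weight profile over the scalp positions, peak normalized to 1.
topography_weights <- function(center, sd = 0.55) {
  lay <- montage_layout()$pos
  d2 <- (lay[, 1] - center[1])^2 + (lay[, 2] - center[2])^2
  w <- exp(-d2 / (2 * sd^2))
  w / max(w)
}

# Multiplicative amplitude profile from turn-phase lateralization:
# before the apex the turn-side frequency gets gain g and the other 1/g;
# after the apex the assignment flips. Applies within apex ± turn_duration/2.
lateralization_profile <- function(cfg, t, truth) {
  g39 <- rep(1, length(t)); g41 <- rep(1, length(t))
  if (is.null(truth) || cfg$lateralization_gain == 1)
    return(list(g39 = g39, g41 = g41))
  g <- cfg$lateralization_gain
  half <- cfg$turn_duration_s / 2
  for (i in seq_len(nrow(truth))) {
    a <- truth$apex_time_s[i]
    pre <- t >= (a - half) & t < a
    post <- t >= a & t < (a + half)
    if (truth$direction[i] == "left") {
      g39[pre] <- g; g41[pre] <- 1 / g
      g39[post] <- 1 / g; g41[post] <- g
    } else {
      g41[pre] <- g; g39[pre] <- 1 / g
      g41[post] <- 1 / g; g39[post] <- g
    }
  }
  list(g39 = g39, g41 = g41)
}

# Multiplicative burst-dip profile for one modulation frequency: drop to
# (1 - depth) for dur_s after each relevant burst onset, then exponential
# recovery with time constant recovery_s.
burst_dip_profile <- function(t, onsets, dip) {
  gain <- rep(1, length(t))
  if (!length(onsets) || dip$depth <= 0) return(gain)
  for (on in onsets) {
    hold <- t >= on & t < on + dip$dur_s
    gain[hold] <- pmin(gain[hold], 1 - dip$depth)
    rec <- t >= on + dip$dur_s & t < on + dip$dur_s + 6 * dip$recovery_s
    g <- 1 - dip$depth * exp(-(t[rec] - on - dip$dur_s) / dip$recovery_s)
    gain[rec] <- pmin(gain[rec], g)
  }
  gain
}

#' Simulate a forward-mixed EEG session
#'
#' Builds `topographies x sources + noise`: 39 and 41 Hz ASSR sinusoids with
#' frontocentral Gaussian topography (amplitude set by movement state,
#' scaled by the turn-phase lateralization gain when walking, and dipped
#' multiplicatively after bursts), an 8–14 Hz occipital alpha source, burst-
#' locked P1/P2 ERP deflections, a per-channel 1/f background, and white
#' sensor noise. Burst events are embedded in the event table at the nearest
#' EEG sample.
#'
#' @param cfg a [session_config()].
#' @param schedule a [schedule_bursts()] result, or `NULL` for no bursts.
#' @param motion a [simulate_gyro()] trace (required when
#'   `lateralization_gain != 1`); its ground-truth apices drive the gain.
#' @return an [new_recording()] with ground truth in `attr(, "truth")`.
#' @export
simulate_eeg <- function(cfg, schedule = NULL, motion = NULL) {
  if (cfg$lateralization_gain != 1 && cfg$movement_state == "walk" &&
      is.null(motion))
    stop("motion trace required when lateralization modulation is enabled")
  set.seed(cfg$seed)
  dur <- session_duration(cfg)
  fs <- cfg$eeg_fs
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs

  if (!is.null(schedule) && any(schedule$events$onset_s >= dur))
    stop("scheduled bursts exceed session duration")

  lay <- montage_layout()
  eeg_labels <- lay$eeg
  # frontocentral ASSR topographies, slightly lateralized per ear of entry
  # (left-ear 39 Hz source weighted toward the right hemisphere and vice
  # versa, as for auditory generators); occipital alpha
  topo_assr39 <- topography_weights(c(0.15, 0.3))
  topo_assr41 <- topography_weights(c(-0.15, 0.3))
  topo_alpha <- topography_weights(c(0, -0.85), sd = 0.4)
  topo_erp <- topography_weights(c(0, 0.25))

  truth_ap <- if (!is.null(motion)) attr(motion, "truth") else NULL
  lat <- lateralization_profile(cfg, t, truth_ap)

  on_left <- on_right <- numeric(0)
  if (!is.null(schedule)) {
    ev <- schedule$events
    on_left <- ev$onset_s[ev$kind %in% c("left", "central")]
    on_right <- ev$onset_s[ev$kind %in% c("right", "central")]
  }
  dip39 <- burst_dip_profile(t, on_left, cfg$burst_dip)
  dip41 <- burst_dip_profile(t, on_right, cfg$burst_dip)

  amp <- cfg$assr_amp[[cfg$movement_state]]
  ph <- stats::runif(2, 0, 2 * pi)
  src39 <- amp[1] * lat$g39 * dip39 * sin(2 * pi * 39 * t + ph[1])
  src41 <- amp[2] * lat$g41 * dip41 * sin(2 * pi * 41 * t + ph[2])

  # alpha waxes and wanes: narrowband carrier times a slow positive envelope
  # (gives the super-Gaussian amplitude statistics of real alpha bursts)
  a_alpha <- cfg$alpha_amp[[cfg$movement_state]]
  carrier <- shaped_noise_gaussian(n, fs, center = 10, sd_hz = 1.5)
  env <- fft_bandpass(abs(stats::rnorm(n)), fs, lo = 0, hi = 0.5, trans = 0.3)
  env <- pmax(env, 0)
  src_alpha <- carrier * env
  src_alpha <- a_alpha * src_alpha / max(stats::sd(src_alpha), 1e-12)

  # burst-locked ERP source
  src_erp <- numeric(n)
  if (!is.null(schedule) && nrow(schedule$events)) {
    for (on in schedule$events$onset_s) {
      for (tpl in cfg$erp_templates) {
        idx <- which(t >= on & t <= on + tpl$lat_s + 6 * tpl$sd_s)
        src_erp[idx] <- src_erp[idx] +
          tpl$amp_uV * exp(-(t[idx] - on - tpl$lat_s)^2 / (2 * tpl$sd_s^2))
      }
    }
  }

  n_eeg <- length(eeg_labels)
  sig <- rbind(src39, src41, src_alpha, src_erp)
  topo <- cbind(topo_assr39, topo_assr41, topo_alpha, topo_erp)
  data_eeg <- topo %*% sig

  # spatially smooth 1/f background sources (random scalp centers), scaled so
  # the mean per-channel background PSD matches the configured aperiodic fit
  lay_pos <- lay$pos
  centers <- cbind(stats::runif(cfg$n_background, -0.9, 0.9),
                   stats::runif(cfg$n_background, -0.9, 0.9))
  W <- vapply(seq_len(cfg$n_background), function(k)
    topography_weights(centers[k, ], sd = 0.5), numeric(n_eeg))
  W <- W / sqrt(mean(rowSums(W^2)))
  bg <- vapply(seq_len(cfg$n_background), function(k)
    aperiodic_noise(n, fs, cfg$aperiodic[["offset"]], cfg$aperiodic[["exponent"]]),
    numeric(n))
  data_eeg <- data_eeg + W %*% t(bg)
  data_eeg <- data_eeg + matrix(stats::rnorm(n_eeg * n, sd = cfg$sensor_noise_uV),
                                n_eeg, n)

  refs <- rbind(A1 = stats::rnorm(n, sd = cfg$sensor_noise_uV),
                A2 = stats::rnorm(n, sd = cfg$sensor_noise_uV))
  eogs <- matrix(stats::rnorm(6 * n, sd = 3), 6, n,
                 dimnames = list(paste0("EOG", 1:6), NULL))

  data <- rbind(data_eeg, refs, eogs)
  labels <- c(eeg_labels, "A1", "A2", paste0("EOG", 1:6))
  roles <- c(rep("eeg", n_eeg), rep("ref", 2), rep("eog", 6))

  events <- data.frame(sample = integer(0), label = character(0),
                       stringsAsFactors = FALSE)
  if (!is.null(schedule) && nrow(schedule$events)) {
    events <- data.frame(
      sample = as.integer(round(schedule$events$onset_s * fs)),
      label = paste0("burst_", schedule$events$kind),
      stringsAsFactors = FALSE)
  }
  events <- rbind(events,
                  data.frame(sample = 0L,
                             label = paste0("state_", cfg$movement_state),
                             stringsAsFactors = FALSE))
  events <- events[order(events$sample), , drop = FALSE]

  rec <- new_recording(data, labels, roles, fs, events)
  attr(rec, "truth") <- list(
    apices = truth_ap, assr_amp = amp, alpha_amp = a_alpha,
    topo_assr = cbind(f39 = topo_assr39, f41 = topo_assr41),
    topo_alpha = topo_alpha,
    lateralization_gain = cfg$lateralization_gain,
    sources = list(assr39 = src39, assr41 = src41))
  rec
}
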