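# Core data containers: multichannel recordings, motion traces, epoch sets.

#' Construct a multichannel EEG recording
#'
#' A recording is the package's central container: a channels x samples matrix
#' in microvolts, channel labels and roles, the sampling rate, and an event
#' table (0-based sample indices with string labels).
#'
#' @param data numeric matrix, channels x samples (µV).
#' @param labels character vector of unique channel labels.
#' @param roles character vector, one of `"eeg"`, `"eog"`, `"ref"` per channel.
#' @param fs sampling rate in Hz.
#' @param events data.frame with columns `sample` (0-based integer index) and
#'   `label` (character), or `NULL` for none.
#' @return an object of class `"assr_recording"`.
#' @export
new_recording <- function(data, labels, roles, fs, events = NULL) {
  if (!is.matrix(data)) stop("`data` must be a channels x samples matrix")
  if (anyNA(data) || any(!is.finite(data))) stop("recording contains non-finite values")
  if (length(labels) != nrow(data)) stop("one label per channel required")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (length(roles) != nrow(data)) stop("one role per channel required")
  if (!all(roles %in% c("eeg", "eog", "ref"))) stop("roles must be eeg/eog/ref")
  stopifnot_scalar(fs, "fs")
  if (is.null(events)) {
    events <- data.frame(sample = integer(0), label = character(0),
                         stringsAsFactors = FALSE)
  }
  if (!all(c("sample", "label") %in% names(events)))
    stop("`events` needs columns `sample` and `label`")
  if (nrow(events) && (any(events$sample < 0) || any(events$sample >= ncol(data))))
    stop("event sample indices out of range")
  rownames(data) <- labels
  structure(list(data = data, labels = labels, roles = roles, fs = fs,
                 events = events),
            class = "assr_recording")
}

#' @export
print.assr_recording <- function(x, ...) {
  cat(sprintf("<assr_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  roles: %s\n",
              paste(sprintf("%s=%d", names(table(x$roles)), table(x$roles)),
                    collapse = ", ")))
  cat(sprintf("  events: %d\n", nrow(x$events)))
  invisible(x)
}

#' Channels of a recording by role
#' @param rec an `assr_recording`.
#' @param role one of `"eeg"`, `"eog"`, `"ref"`.
#' @return character vector of labels.
#' @export
channels_by_role <- function(rec, role) rec$labels[rec$roles == role]

#' Frontocentral and occipital electrode sets
#'
#' The ASSR analyses use the frontocentral electrodes AFz, Fz, F3, F4, Cz;
#' the alpha analyses use the lateral occipital electrodes O1 and O2.
#' @name electrode_sets
#' @export
frontocentral_channels <- function() c("AFz", "Fz", "F3", "F4", "Cz")

#' @rdname electrode_sets
#' @export
occipital_channels <- function() c("O1", "O2")

#' Average signal over a channel set
#' @param rec an `assr_recording`.
#' @param channels labels to average over (must exist).
#' @return numeric vector, samples long.
#' @export
channel_average <- function(rec, channels = frontocentral_channels()) {
  miss <- setdiff(channels, rec$labels)
  if (length(miss)) stop("missing channels: ", paste(miss, collapse = ", "))
  colMeans(rec$data[channels, , drop = FALSE])
}

#' Construct a motion trace
#'
#' @param gyro 3 x samples angular-velocity matrix (deg/s); row 3 is yaw.
#' @param accel 3 x samples acceleration matrix (m/s^2), or `NULL`.
#' @param fs sampling rate in Hz (120 for the supported hardware).
#' @param sensor one of `"waist"`, `"left_ankle"`, `"right_ankle"`.
#' @return an object of class `"motion_trace"`.
#' @export
new_motion_trace <- function(gyro, accel = NULL, fs = 120,
                             sensor = "waist") {
  if (!is.matrix(gyro) || nrow(gyro) != 3) stop("`gyro` must be 3 x samples")
  if (any(!is.finite(gyro))) stop("non-finite gyroscope values")
  if (is.null(accel)) accel <- matrix(0, 3, ncol(gyro))
  sensor <- match.arg(sensor, c("waist", "left_ankle", "right_ankle"))
  structure(list(gyro = gyro, accel = accel, fs = fs, sensor = sensor),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %s sensor, %d samples @ %g Hz (%.1f s)\n",
              x$sensor, ncol(x$gyro), x$fs, ncol(x$gyro) / x$fs))
  invisible(x)
}

# yaw channel accessor (row 3 by convention)
yaw_channel <- function(motion) motion$gyro[3L, ]

#' Write / read a session fixture
#'
#' Serializes a simulated session (recording + motion + configuration) as
#' plain-text CSV matrices with a JSON sidecar for events and metadata, so a
#' session can be rebuilt exactly elsewhere.
#'
#' @param rec an `assr_recording`.
#' @param motion a `motion_trace` or `NULL`.
#' @param dir output directory (created if needed).
#' @param meta optional list of metadata stored verbatim in the sidecar.
#' @return `dir`, invisibly.
#' @export
write_session <- function(rec, motion = NULL, dir, meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(t(rec$data), file.path(dir, "eeg_uV.csv"), row.names = FALSE)
  if (!is.null(motion)) {
    m <- rbind(motion$gyro, motion$accel)
    rownames(m) <- c("gyro_x", "gyro_y", "gyro_z", "accel_x", "accel_y", "accel_z")
    utils::write.csv(t(m), file.path(dir, "motion.csv"), row.names = FALSE)
  }
  sidecar <- list(
    labels = rec$labels, roles = rec$roles, fs = rec$fs,
    events = rec$events,
    motion = if (!is.null(motion)) list(fs = motion$fs, sensor = motion$sensor),
    meta = meta
  )
  jsonlite::write_json(sidecar, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)
  dat <- t(as.matrix(utils::read.csv(file.path(dir, "eeg_uV.csv"))))
  ev <- side$events
  if (is.null(ev) || !length(ev)) ev <- NULL else ev <- as.data.frame(ev)
  rec <- new_recording(dat, side$labels, side$roles, side$fs, ev)
  motion <- NULL
  mp <- file.path(dir, "motion.csv")
  if (file.exists(mp)) {
    m <- t(as.matrix(utils::read.csv(mp)))
    motion <- new_motion_trace(m[1:3, , drop = FALSE], m[4:6, , drop = FALSE],
                               fs = side$motion$fs, sensor = side$motion$sensor)
  }
  list(recording = rec, motion = motion, meta = side$meta)
}

#' Construct an epoch set
#'
#' Trials x channels x time array time-locked to events, with a symmetric time
#' axis (t = 0 at the lock sample).
#'
#' @param data numeric array, trials x channels x time.
#' @param time numeric vector of times in seconds relative to the lock.
#' @param fs sampling rate (Hz).
#' @param lock_kind label describing the lock (e.g. `"turn_left"`).
#' @param trial_ids provenance identifiers, one per trial.
#' @param n_dropped number of events dropped at recording bounds.
#' @param channels channel labels (dim 2), or `NULL` for single-series epochs.
#' @return an object of class `"epoch_set"`.
#' @export
new_epoch_set <- function(data, time, fs, lock_kind = "event",
                          trial_ids = seq_len(dim(data)[1]), n_dropped = 0L,
                          channels = NULL) {
  stopifnot(length(dim(data)) == 3L, dim(data)[3] == length(time))
  structure(list(data = data, time = time, fs = fs, lock_kind = lock_kind,
                 trial_ids = trial_ids, n_dropped = n_dropped,
                 channels = channels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples, lock=%s, dropped=%d\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$lock_kind,
              x$n_dropped))
  invisible(x)
}
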