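# Selection of ASSR and alpha components from an ICA decomposition.

#' Alpha-component selection criteria
#'
#' Four requirements: (1) a local power peak between 6 and 14 Hz; (2) peak
#' width — the distance between the two adjacent local minima — of at least
#' 4 Hz (the widest local peak is used when several exist); (3) power at the
#' peak at least three times the mean power between 20 and 50 Hz; (4) the
#' maximum absolute topography weight over the occipital sensors (O1, O2,
#' POz) exceeds the maximum over all other sensors.
#'
#' @param peak_band,min_peak_width_hz,ratio_band,min_ratio,occipital_labels
#'   the stated constants, overridable.
#' @return an `alpha_criteria` list.
#' @export
alpha_criteria <- function(peak_band = c(6, 14), min_peak_width_hz = 4,
                           ratio_band = c(20, 50), min_ratio = 3,
                           occipital_labels = c("O1", "O2", "POz")) {
  structure(list(peak_band = peak_band, min_peak_width_hz = min_peak_width_hz,
                 ratio_band = ratio_band, min_ratio = min_ratio,
                 occipital_labels = occipital_labels),
            class = "alpha_criteria")
}

# Strict local maxima / minima on a grid, plateau ties broken toward the
# lower frequency (first sample of the plateau).
local_extrema <- function(y) {
  n <- length(y)
  d <- diff(y)
  s <- sign(d)
  # collapse zero slopes onto the previous nonzero slope (plateau -> lower f)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  flips <- which(diff(s) != 0) + 1L
  maxima <- flips[s[flips - 1L] > 0 & s[flips] < 0]
  minima <- flips[s[flips - 1L] < 0 & s[flips] > 0]
  list(maxima = maxima, minima = minima)
}

# Width of the local peak at index i: distance between the adjacent local
# minima (spectrum edges count as minima).
peak_width_bounds <- function(freqs, minima, i, n) {
  lo <- minima[minima < i]
  hi <- minima[minima > i]
  lo <- if (length(lo)) max(lo) else 1L
  hi <- if (length(hi)) min(hi) else n
  c(lo = lo, hi = hi)
}

#' Select ASSR components
#'
#' A component is accepted iff its parameterized spectrum contains a peak
#' whose center lies within `tol` of one of the target modulation rates
#' (39/41 Hz), whose over-aperiodic height exceeds `height_thresh`, and
#' whose fitted width does not exceed `max_width_hz` — steady-state
#' responses are spectral lines, so a broad bump straddling the target is
#' not a "clear ASSR signal" (operationalization recorded in the report).
#'
#' @param spectra list of `power_spectrum`, one per component (covering
#'   1–48 Hz).
#' @param target_hzs target frequencies, `c(39, 41)`.
#' @param height_thresh minimum over-aperiodic peak height (log10 units).
#' @param max_width_hz maximum fitted peak FWHM counted as a line (4 Hz).
#' @param tol center matching tolerance in Hz (0.5).
#' @param fit_range parameterization range.
#' @return data.frame, one row per component: `component`, `accepted`,
#'   `peak_center_hz`, `peak_height_log10`, `matched_target_hz`,
#'   `height_thresh`.
#' @export
select_assr_components <- function(spectra, target_hzs = c(39, 41),
                                   height_thresh = 0.10, max_width_hz = 4,
                                   tol = 0.5, fit_range = c(1, 48)) {
  if (!length(spectra)) stop("no spectra supplied")
  rows <- lapply(seq_along(spectra), function(i) {
    ps <- fit_parameterized(spectra[[i]], fit_range = fit_range)
    best <- data.frame(center = NA_real_, height = NA_real_,
                       width = NA_real_, target = NA_real_)
    if (nrow(ps$peaks)) {
      for (tg in target_hzs) {
        d <- abs(ps$peaks$center_hz - tg)
        j <- which(d <= tol & ps$peaks$width_hz <= max_width_hz)
        if (length(j)) {
          j <- j[which.min(d[j])]
          if (is.na(best$height) || ps$peaks$height_log10[j] > best$height)
            best <- data.frame(center = ps$peaks$center_hz[j],
                               height = ps$peaks$height_log10[j],
                               width = ps$peaks$width_hz[j], target = tg)
        }
      }
    }
    data.frame(component = i,
               accepted = !is.na(best$height) && best$height > height_thresh,
               peak_center_hz = best$center, peak_height_log10 = best$height,
               peak_width_hz = best$width, matched_target_hz = best$target,
               height_thresh = height_thresh, max_width_hz = max_width_hz)
  })
  do.call(rbind, rows)
}

#' Select alpha components
#'
#' Applies the four alpha criteria (see [alpha_criteria()]) to each
#' component's Welch spectrum and ICA topography. Acceptance requires all
#' four; the report carries every per-criterion verdict and the measured
#' peak center, width and ratio. All accepted components are meant to be
#' back-projected jointly (multiplicity is allowed).
#'
#' @param decomp a [decompose()] result (for topography weights), or a
#'   channels x components mixing matrix with rownames.
#' @param spectra list of `power_spectrum`, one per component.
#' @param crit an [alpha_criteria()].
#' @return data.frame, one row per component: `component`, `accepted`,
#'   `has_peak`, `width_ok`, `ratio_ok`, `topo_ok`, `peak_center_hz`,
#'   `peak_width_hz`, `peak_ratio`, `winning_sensor`.
#' @export
select_alpha_components <- function(decomp, spectra, crit = alpha_criteria()) {
  mixing <- if (inherits(decomp, "component_decomposition")) decomp$mixing
            else decomp
  labels <- rownames(mixing)
  if (is.null(labels)) stop("topography weights need channel labels")
  miss <- setdiff(crit$occipital_labels, labels)
  if (length(miss)) stop("missing occipital sensors: ", paste(miss, collapse = ", "))
  rows <- lapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]
    if (max(sp$freqs) < crit$ratio_band[2])
      stop("spectrum does not cover the ratio band")
    ex <- local_extrema(sp$power)
    in_band <- ex$maxima[sp$freqs[ex$maxima] >= crit$peak_band[1] &
                         sp$freqs[ex$maxima] <= crit$peak_band[2]]
    has_peak <- length(in_band) > 0
    center <- width <- ratio <- NA_real_
    width_ok <- ratio_ok <- FALSE
    if (has_peak) {
      widths <- vapply(in_band, function(j) {
        b <- peak_width_bounds(sp$freqs, ex$minima, j, length(sp$power))
        sp$freqs[b["hi"]] - sp$freqs[b["lo"]]
      }, 0)
      j <- in_band[which.max(widths)]   # widest local peak
      center <- sp$freqs[j]
      width <- max(widths)
      width_ok <- width >= crit$min_peak_width_hz
      hi_sel <- sp$freqs >= crit$ratio_band[1] & sp$freqs <= crit$ratio_band[2]
      ratio <- sp$power[j] / mean(sp$power[hi_sel])
      ratio_ok <- ratio >= crit$min_ratio
    }
    w <- abs(mixing[, i])
    occ <- max(w[crit$occipital_labels])
    oth <- max(w[setdiff(labels, crit$occipital_labels)])
    topo_ok <- occ > oth
    data.frame(component = i,
               accepted = has_peak && width_ok && ratio_ok && topo_ok,
               has_peak = has_peak, width_ok = width_ok, ratio_ok = ratio_ok,
               topo_ok = topo_ok, peak_center_hz = center,
               peak_width_hz = width, peak_ratio = ratio,
               winning_sensor = names(which.max(w)))
  })
  do.call(rbind, rows)
}
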