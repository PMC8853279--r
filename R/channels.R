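# Channel separation and onset extraction: the recording-side half of the
# pipeline.  A mono free-field recording mixes the filtered stimulus, the
# marker sounds and the participant's tap sounds; band-pass filtering pulls
# these apart because each element was designed to occupy its own band.

#' Zero-phase band-pass filter
#'
#' Applies a Butterworth band-pass forward and backward ([signal::filtfilt])
#' so the net group delay is zero and onset times are not shifted.  The
#' default order (2, i.e. 4 poles per pass) gives roughly 48 dB/octave of
#' stopband rejection after the two passes while staying numerically stable
#' for the narrow low-frequency bands used here.
#'
#' @param wave a [waveform].
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low < high < sample_rate / 2`.
#' @param order Butterworth order per pass.
#' @return filtered [waveform] of identical length.
#' @export
bandpass <- function(wave, low_hz, high_hz, order = 2) {
  stopifnot(inherits(wave, "waveform"))
  nyq <- wave$sample_rate / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    input_error(sprintf("invalid band %g-%g Hz (Nyquist %g Hz)", low_hz, high_hz, nyq))
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  waveform(signal::filtfilt(bf, wave$samples), wave$sample_rate)
}

#' Split a recording into tapping, marker and test channels
#'
#' @param recording mono [waveform] of a full trial.
#' @param config a [tapsync_config]; if the recording's sample rate differs
#'   it is linearly resampled first.
#' @return list of class `tapsync_channels` with elements `tap_channel`,
#'   `marker_channel`, `test_channel` and `enhanced_marker_channel`, all the
#'   same length as the (resampled) input.
#' @export
split_channels <- function(recording, config = tapsync_config()) {
  stopifnot(inherits(recording, "waveform"))
  if (recording$sample_rate != config$sample_rate) {
    recording <- resample_linear(recording, config$sample_rate)
  }
  block_ms <- marker_block_duration_ms(config)
  if (duration_ms(recording) < block_ms) {
    quality_error(sprintf(
      "recording (%.0f ms) shorter than one marker block (%.0f ms)",
      duration_ms(recording), block_ms), reason = "markers_missing")
  }
  tap <- bandpass(recording, config$tap_band[1], config$tap_band[2])
  marker <- bandpass(recording, config$marker_band[1], config$marker_band[2])
  test <- bandpass(recording, config$test_band[1], config$test_band[2])
  enhanced <- enhance_markers(marker, test, config)
  structure(list(tap_channel = tap, marker_channel = marker,
                 test_channel = test, enhanced_marker_channel = enhanced),
            class = "tapsync_channels")
}

resample_linear <- function(wave, new_rate) {
  n_new <- max(1L, as.integer(round(length(wave$samples) * new_rate / wave$sample_rate)))
  old_t <- seq(0, length(wave$samples) - 1) / wave$sample_rate
  new_t <- seq(0, n_new - 1) / new_rate
  waveform(stats::approx(old_t, wave$samples, xout = new_t, rule = 2)$y, new_rate)
}

#' Boost the marker signal where it dominates the test band
#'
#' Sliding-window (trailing) energies are computed in the marker and test
#' channels and normalised by bandwidth (energy density per Hz), so that broadband sounds
#' such as finger taps — which deposit similar energy density in both bands —
#' are never boosted, while the narrow-band markers, which leave the test
#' band essentially empty, are.  The marker channel is multiplied by
#' `boost_gain` wherever the marker density exceeds `ratio_threshold` times
#' the test density, and by `attenuation_gain` elsewhere.
#'
#' @param marker_channel,test_channel equal-length [waveform]s.
#' @param config a [tapsync_config].
#' @return enhanced marker [waveform].
#' @export
enhance_markers <- function(marker_channel, test_channel, config = tapsync_config()) {
  stopifnot(length(marker_channel$samples) == length(test_channel$samples))
  fs <- marker_channel$sample_rate
  w <- ms_to_samples(config$enhance_window, fs)
  e_m <- moving_average(marker_channel$samples^2, w) / diff(config$marker_band)
  e_t <- moving_average(test_channel$samples^2, w) / diff(config$test_band)
  gain <- ifelse(e_m > config$ratio_threshold * e_t,
                 config$boost_gain, config$attenuation_gain)
  waveform(marker_channel$samples * gain, fs)
}

#' Extract onsets by relative-threshold envelope crossing
#'
#' The signal is rectified and smoothed with a trailing moving average of
#' width `envelope_window` (trailing, so smoothing can never advance the
#' detected onset ahead of the physical signal start); the threshold is
#' `onset_threshold_frac` times the envelope maximum, so detection is
#' invariant to overall recording gain.  Each supra-threshold excursion
#' contributes one onset at its first sample; excursions starting within
#' `min_onset_gap` of the previous onset are merged into it.
#'
#' @param wave a [waveform].
#' @param config a [tapsync_config].
#' @return numeric vector of onset times in ms (possibly empty).
#' @export
extract_onsets <- function(wave, config = tapsync_config()) {
  stopifnot(inherits(wave, "waveform"))
  fs <- wave$sample_rate
  env <- moving_average(abs(wave$samples), ms_to_samples(config$envelope_window, fs))
  peak <- max(env)
  if (peak <= 0) return(numeric(0))
  above <- env > config$onset_threshold_frac * peak
  n <- length(above)
  starts <- which(above & !c(FALSE, above[-n]))
  if (length(starts) == 0) return(numeric(0))
  ends <- which(above & !c(above[-1], FALSE))

  # Excursions must also rise clearly above the noise floor (median
  # envelope): a windowed relative threshold alone cannot tell a floor of
  # stationary background noise from genuine events.
  floor_env <- stats::median(env)
  if (floor_env > 0) {
    peaks <- vapply(seq_along(starts),
                    function(i) max(env[starts[i]:ends[i]]), numeric(1))
    starts <- starts[peaks > config$min_peak_floor_ratio * floor_env]
    if (length(starts) == 0) return(numeric(0))
  }

  gap <- ms_to_samples(config$min_onset_gap, fs)
  keep <- starts[1]
  last <- starts[1]
  for (s in starts[-1]) {
    if (s - last >= gap) {
      keep <- c(keep, s)
      last <- s
    }
  }
  index_to_ms(keep, fs)
}

#' Detect the marker onsets in a recording
#'
#' Extracts candidate onsets from the enhanced marker channel and matches
#' them against the known inter-marker interval pattern of the prepared
#' stimulus, anchored at the earliest candidate that explains the most
#' markers.  Matching tolerates `marker_match_tol` ms per marker, which
#' makes the detector robust to spurious bursts before the first marker.
#'
#' @param recording a [waveform] or a `tapsync_channels` object from
#'   [split_channels()].
#' @param prepared a [prepare_stimulus()] result carrying the known marker
#'   onsets.
#' @param config a [tapsync_config].
#' @return list with `onsets` (detected marker times, ms, `NA` where a
#'   marker was not found), `n_detected`, and `marker_error_ms` (mean
#'   absolute deviation of detected inter-marker intervals from the known
#'   intervals, anchored at the first detected marker).
#' @export
detect_markers <- function(recording, prepared, config = tapsync_config()) {
  channels <- if (inherits(recording, "tapsync_channels")) recording
              else split_channels(recording, config)
  cand <- extract_onsets(channels$enhanced_marker_channel, config)
  known <- prepared$marker_onsets
  rel <- known - known[1]
  n_exp <- length(known)
  tol <- config$marker_match_tol

  best <- NULL
  for (anchor in cand) {
    pred <- anchor + rel
    det <- rep(NA_real_, n_exp)
    for (k in seq_len(n_exp)) {
      d <- abs(cand - pred[k])
      j <- which.min(d)
      if (length(j) && d[j] <= tol) det[k] <- cand[j]
    }
    score <- sum(!is.na(det))
    if (is.null(best) || score > best$score) best <- list(det = det, score = score)
    if (score == n_exp) break   # earliest full match wins
  }
  if (is.null(best)) best <- list(det = rep(NA_real_, n_exp), score = 0L)

  det <- best$det
  n_det <- sum(!is.na(det))
  min_req <- config$min_markers_detected_frac * n_exp
  err <- if (n_det >= 2) {
    first <- det[which(!is.na(det))[1]]
    first_rel <- rel[which(!is.na(det))[1]]
    mean(abs((det - first) - (rel - first_rel)), na.rm = TRUE)
  } else NA_real_
  if (n_det < min_req) {
    quality_error(sprintf(
      "markers undetected: %d of %d found (need %.0f); incompatible hardware or muted markers",
      n_det, n_exp, ceiling(min_req)), reason = "markers_missing")
  }
  list(onsets = det, n_detected = n_det, marker_error_ms = err)
}
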