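# Onset alignment and per-trial performance analysis.  The recording's
# absolute start time is unknowable (sound-card and OS latency), but every
# event within it is sample-accurate, so the first detected marker serves
# as the single frame of reference that maps the known stimulus timeline
# onto the recording timeline.

#' Realign the known stimulus onsets to the recording timeline
#'
#' @param prepared a `prepared_stimulus` (known onset lists).
#' @param detected_markers numeric, detected marker times in ms on the
#'   recording timeline (`NA` allowed for missed markers; the first
#'   detected one anchors the alignment).
#' @param detected_taps numeric, detected tap times in ms on the recording
#'   timeline (already in the right frame; passed through).
#' @return list with `realigned_stim_onsets`, `realigned_tap_onsets`,
#'   `offset_ms` (recording time of the prepared-stimulus origin).
#' @export
realign <- function(prepared, detected_markers, detected_taps = numeric(0)) {
  ok <- which(!is.na(detected_markers))
  if (length(ok) == 0) {
    quality_error("no detected markers: alignment impossible", reason = "markers_missing")
  }
  offset <- detected_markers[ok[1]] - prepared$marker_onsets[ok[1]]
  list(realigned_stim_onsets = prepared$stim_onsets + offset,
       realigned_tap_onsets = as.numeric(detected_taps),
       offset_ms = offset)
}

#' Pair taps with stimulus onsets
#'
#' Greedy nearest-neighbour matching: all (stimulus, tap) pairs closer than
#' `match_window` are ranked by absolute asynchrony (ties go to the earlier
#' tap) and accepted greedily, each onset used at most once.
#'
#' @param stim_onsets,tap_onsets sorted numeric vectors, ms.
#' @param match_window half-width of the pairing window, ms.
#' @return data frame with columns `stim_index`, `tap_index`, `stim_onset`,
#'   `tap_onset`, `asynchrony` (tap minus stimulus), sorted by `stim_index`.
#' @export
match_taps <- function(stim_onsets, tap_onsets, match_window = 250) {
  empty <- data.frame(stim_index = integer(0), tap_index = integer(0),
                      stim_onset = numeric(0), tap_onset = numeric(0),
                      asynchrony = numeric(0))
  if (length(stim_onsets) == 0 || length(tap_onsets) == 0) return(empty)
  pairs <- expand.grid(stim_index = seq_along(stim_onsets),
                       tap_index = seq_along(tap_onsets))
  pairs$asynchrony <- tap_onsets[pairs$tap_index] - stim_onsets[pairs$stim_index]
  pairs <- pairs[abs(pairs$asynchrony) <= match_window, , drop = FALSE]
  if (nrow(pairs) == 0) return(empty)
  pairs <- pairs[order(abs(pairs$asynchrony), pairs$tap_index), , drop = FALSE]
  used_s <- logical(length(stim_onsets))
  used_t <- logical(length(tap_onsets))
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    s <- pairs$stim_index[i]; t <- pairs$tap_index[i]
    if (!used_s[s] && !used_t[t]) {
      keep[i] <- TRUE
      used_s[s] <- TRUE
      used_t[t] <- TRUE
    }
  }
  out <- pairs[keep, , drop = FALSE]
  out <- out[order(out$stim_index), , drop = FALSE]
  out$stim_onset <- stim_onsets[out$stim_index]
  out$tap_onset <- tap_onsets[out$tap_index]
  rownames(out) <- NULL
  out[, c("stim_index", "tap_index", "stim_onset", "tap_onset", "asynchrony")]
}

# Per-trial pairing window: explicit config value, else min(250, IOI/2).
effective_match_window <- function(config, stim_onsets) {
  if (!is.null(config$match_window)) return(config$match_window)
  if (length(stim_onsets) >= 2) {
    min(250, stats::median(diff(stim_onsets)) / 2)
  } else 250
}

#' Apply the per-trial failing criteria
#'
#' A trial fails when the recording or the behaviour make asynchronies
#' untrustworthy: markers missing (incompatible hardware, noise
#' cancellation), marker timing error too large, or a tap count far from
#' the stimulus onset count (non-tappers, spurious tapping).
#'
#' @param n_markers_detected,n_markers_expected marker counts.
#' @param marker_error_ms mean absolute marker interval error, ms (`NA`
#'   when fewer than two markers were found).
#' @param n_matched_taps number of taps matched to a stimulus onset.
#' @param n_stim_onsets number of stimulus onsets.
#' @param config a [tapsync_config].
#' @return object of class `trial_diagnostics`: list with the counts,
#'   `pct_detected_taps`, `pct_detected_markers`, `passed`, `fail_reasons`.
#' @export
evaluate_trial <- function(n_markers_detected, n_markers_expected,
                           marker_error_ms, n_matched_taps, n_stim_onsets,
                           config = tapsync_config()) {
  reasons <- character(0)
  if (n_markers_detected < config$min_markers_detected_frac * n_markers_expected) {
    reasons <- c(reasons, "markers_missing")
  }
  if (!is.na(marker_error_ms) && marker_error_ms > config$max_marker_error_ms) {
    reasons <- c(reasons, "marker_error")
  }
  ratio <- if (n_stim_onsets > 0) n_matched_taps / n_stim_onsets else NA_real_
  if (!is.na(ratio)) {
    if (ratio < config$min_tap_ratio) reasons <- c(reasons, "too_few_taps")
    if (ratio > config$max_tap_ratio) reasons <- c(reasons, "too_many_taps")
  }
  structure(list(
    n_markers_detected = n_markers_detected,
    n_markers_expected = n_markers_expected,
    marker_error_ms = marker_error_ms,
    n_matched_taps = n_matched_taps,
    n_stim_onsets = n_stim_onsets,
    pct_detected_taps = if (n_stim_onsets > 0) 100 * n_matched_taps / n_stim_onsets else NA_real_,
    pct_detected_markers = 100 * n_markers_detected / n_markers_expected,
    passed = length(reasons) == 0,
    fail_reasons = reasons
  ), class = "trial_diagnostics")
}

#' @export
print.trial_diagnostics <- function(x, ...) {
  cat(sprintf("trial %s\n", if (x$passed) "PASSED" else
    paste0("FAILED (", paste(x$fail_reasons, collapse = ", "), ")")))
  cat(sprintf("  markers: %d/%d detected, timing error %.2f ms\n",
              x$n_markers_detected, x$n_markers_expected, x$marker_error_ms))
  cat(sprintf("  taps: %d matched of %d stimulus onsets (%.0f%%)\n",
              x$n_matched_taps, x$n_stim_onsets, x$pct_detected_taps))
  invisible(x)
}

#' Analyze a full trial recording
#'
#' Runs the complete pipeline on one mono recording: channel separation,
#' marker detection, tap onset extraction, realignment of the known
#' stimulus onsets via the first detected marker, tap-stimulus pairing,
#' failing criteria, and tapping statistics.  Tap onsets are only accepted
#' inside the window between the two marker blocks, and never within
#' `marker_duration` of a detected marker, so marker energy leaking into
#' the (overlapping) tap band cannot masquerade as taps.
#'
#' @param recording mono [waveform] of the trial.
#' @param prepared the `prepared_stimulus` that was played.
#' @param config a [tapsync_config].
#' @return object of class `trial_analysis`: list with `aligned`
#'   (realigned onsets, matches, `asynchronies`), `diagnostics`
#'   (a `trial_diagnostics`; always present, even when the trial fails),
#'   and `metrics` (an `sms_metrics`, `NULL` when alignment failed).
#' @export
analyze_recording <- function(recording, prepared, config = prepared$config) {
  diag_fail <- function(reason, n_det = 0, err = NA_real_) {
    evaluate_trial(n_det, length(prepared$marker_onsets), err, 0,
                   length(prepared$stim_onsets), config)
  }
  result <- tryCatch({
    channels <- split_channels(recording, config)
    mk <- detect_markers(channels, prepared, config)

    # Extract taps only from the window between the marker blocks: marker
    # energy falls inside the (overlapping) tap band, so cropping both
    # keeps markers from masquerading as taps and keeps the relative
    # threshold tied to the taps rather than to the much louder markers.
    k <- config$markers_per_block
    det <- mk$onsets
    rel <- prepared$marker_onsets - prepared$marker_onsets[1]
    anchor <- det[which(!is.na(det))[1]] - rel[which(!is.na(det))[1]]
    # Margins: 50 ms after the begin block (marker decay and post-ring),
    # but only 5 ms before the end block (only the short zero-phase
    # pre-ring matters there) so taps arriving late in the trial --
    # e.g. anti-phase taps after the last stimulus onset -- still count.
    lo <- anchor + rel[k] + config$marker_duration + 50
    hi <- anchor + rel[k + 1] - 5
    fs <- config$sample_rate
    i_lo <- max(1L, ms_to_index(lo, fs))
    i_hi <- min(length(channels$tap_channel$samples), ms_to_index(hi, fs))
    tap_window <- waveform(channels$tap_channel$samples[i_lo:i_hi], fs)
    taps <- extract_onsets(tap_window, config) + index_to_ms(i_lo, fs)

    aligned <- realign(prepared, mk$onsets, taps)
    aligned$detected_markers <- mk$onsets
    win <- effective_match_window(config, aligned$realigned_stim_onsets)
    matches <- match_taps(aligned$realigned_stim_onsets, taps, win)
    aligned$matches <- matches
    aligned$asynchronies <- matches$asynchrony

    diagnostics <- evaluate_trial(mk$n_detected, length(prepared$marker_onsets),
                                  mk$marker_error_ms, nrow(matches),
                                  length(prepared$stim_onsets), config)
    metrics <- sms_metrics(aligned)
    list(aligned = aligned, diagnostics = diagnostics, metrics = metrics)
  }, tapsync_quality_error = function(e) {
    list(aligned = NULL,
         diagnostics = diag_fail(e$reason),
         metrics = NULL, error = conditionMessage(e))
  })
  structure(result, class = "trial_analysis")
}

#' @export
print.trial_analysis <- function(x, ...) {
  print(x$diagnostics)
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Write a trial analysis as JSON (and optionally a per-tap CSV)
#'
#' @param analysis a `trial_analysis`.
#' @param path JSON output path.
#' @param csv_path optional path for a per-tap table
#'   (`stim_onset, tap_onset, asynchrony`).
#' @export
write_trial <- function(analysis, path, csv_path = NULL) {
  out <- list(
    diagnostics = unclass(analysis$diagnostics),
    metrics = if (!is.null(analysis$metrics)) unclass(analysis$metrics),
    aligned = if (!is.null(analysis$aligned)) list(
      realigned_stim_onsets = analysis$aligned$realigned_stim_onsets,
      realigned_tap_onsets = analysis$aligned$realigned_tap_onsets,
      offset_ms = analysis$aligned$offset_ms,
      asynchronies = analysis$aligned$asynchronies
    ),
    error = analysis$error
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(csv_path) && !is.null(analysis$aligned)) {
    utils::write.csv(analysis$aligned$matches[, c("stim_onset", "tap_onset", "asynchrony")],
                     csv_path, row.names = FALSE)
  }
  invisible(path)
}
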