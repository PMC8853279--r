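#' Pipeline configuration
#'
#' Builds the configuration object shared by every stage of the pipeline:
#' the frequency bands used to separate stimulus, tapping, marker and test
#' channels; the marker block layout; onset-extraction parameters; and the
#' per-trial failing criteria.
#'
#' The defaults encode the standard free-field tapping setup: participants
#' tap on the laptop surface, producing a crisp sound with most of its
#' energy between 80 and 500 Hz, so the stimulus is filtered to vacate
#' 50-500 Hz and the markers occupy the narrow 200-340 Hz band.  The test
#' band sits exactly one octave below the marker band (100-170 Hz) and is
#' used to tell genuinely narrow-band markers apart from broadband taps.
#'
#' @param sample_rate audio sample rate in Hz.
#' @param stim_stopband numeric length-2, Hz; band removed from the stimulus
#'   so that it cannot mask tapping sounds.
#' @param tap_band numeric length-2, Hz; band-pass applied to obtain the
#'   tapping channel.
#' @param marker_band numeric length-2, Hz; band occupied by the marker
#'   sounds and used to filter the marker channel.
#' @param test_band numeric length-2, Hz; comparison band (one octave below
#'   `marker_band`) used during marker enhancement.
#' @param markers_per_block number of marker sounds per block; one block is
#'   placed before and one after the stimulus.
#' @param marker_duration duration of one marker sound, ms.
#' @param marker_gap silent gap between consecutive markers in a block, ms.
#' @param marker_amplitude peak amplitude of the marker sound, fraction of
#'   full scale.
#' @param stim_padding silence between a marker block and the stimulus, ms.
#' @param onset_threshold_frac relative onset threshold, as a fraction of
#'   the maximum of the smoothed envelope.
#' @param min_onset_gap refractory period of the onset extractor, ms:
#'   supra-threshold excursions closer than this are merged.
#' @param min_peak_floor_ratio onset extraction: an excursion only counts
#'   as an event if its envelope peak exceeds this multiple of the median
#'   envelope (the noise floor).
#' @param envelope_window width of the envelope smoothing window, ms.
#' @param enhance_window width of the energy window used when comparing the
#'   marker and test channels for marker enhancement, ms.
#' @param boost_gain gain applied to the marker channel where marker-band
#'   energy dominates the test band.
#' @param attenuation_gain gain applied elsewhere.
#' @param ratio_threshold marker/test energy-density ratio above which a
#'   region is considered marker-bearing.
#' @param marker_match_tol tolerance when matching detected marker onsets to
#'   the known inter-marker interval pattern, ms.
#' @param match_window half-width of the tap-to-stimulus pairing window, ms,
#'   or `NULL` to use `min(250, median IOI / 2)` per trial.
#' @param min_markers_detected_frac failing criterion: minimum fraction of
#'   expected markers that must be detected.
#' @param max_marker_error_ms failing criterion: maximum tolerated mean
#'   absolute marker timing error, ms.
#' @param min_tap_ratio,max_tap_ratio failing criteria: allowed range of
#'   (detected taps) / (stimulus onsets).
#'
#' @return an object of class `tapsync_config` (a named list).
#' @export
#' @examples
#' cfg <- tapsync_config()
#' cfg$marker_band
tapsync_config <- function(sample_rate = 44100,
                           stim_stopband = c(50, 500),
                           tap_band = c(80, 500),
                           marker_band = c(200, 340),
                           test_band = c(100, 170),
                           markers_per_block = 3,
                           marker_duration = 250,
                           marker_gap = 500,
                           marker_amplitude = 0.95,
                           stim_padding = 500,
                           onset_threshold_frac = 0.1,
                           min_onset_gap = 100,
                           min_peak_floor_ratio = 4,
                           envelope_window = 5,
                           enhance_window = 25,
                           boost_gain = 4,
                           attenuation_gain = 1,
                           ratio_threshold = 2,
                           marker_match_tol = 50,
                           match_window = NULL,
                           min_markers_detected_frac = 1.0,
                           max_marker_error_ms = 10,
                           min_tap_ratio = 0.5,
                           max_tap_ratio = 2.0) {
  cfg <- list(
    sample_rate = as.numeric(sample_rate),
    stim_stopband = as.numeric(stim_stopband),
    tap_band = as.numeric(tap_band),
    marker_band = as.numeric(marker_band),
    test_band = as.numeric(test_band),
    markers_per_block = as.integer(markers_per_block),
    marker_duration = as.numeric(marker_duration),
    marker_gap = as.numeric(marker_gap),
    marker_amplitude = as.numeric(marker_amplitude),
    stim_padding = as.numeric(stim_padding),
    onset_threshold_frac = as.numeric(onset_threshold_frac),
    min_onset_gap = as.numeric(min_onset_gap),
    min_peak_floor_ratio = as.numeric(min_peak_floor_ratio),
    envelope_window = as.numeric(envelope_window),
    enhance_window = as.numeric(enhance_window),
    boost_gain = as.numeric(boost_gain),
    attenuation_gain = as.numeric(attenuation_gain),
    ratio_threshold = as.numeric(ratio_threshold),
    marker_match_tol = as.numeric(marker_match_tol),
    match_window = if (is.null(match_window)) NULL else as.numeric(match_window),
    min_markers_detected_frac = as.numeric(min_markers_detected_frac),
    max_marker_error_ms = as.numeric(max_marker_error_ms),
    min_tap_ratio = as.numeric(min_tap_ratio),
    max_tap_ratio = as.numeric(max_tap_ratio)
  )
  class(cfg) <- "tapsync_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  nyq <- cfg$sample_rate / 2
  check_band <- function(b, name) {
    if (length(b) != 2 || !all(is.finite(b)) || b[1] <= 0 || b[1] >= b[2] || b[2] >= nyq) {
      input_error(sprintf("invalid %s: need 0 < low < high < %g Hz", name, nyq))
    }
  }
  check_band(cfg$stim_stopband, "stim_stopband")
  check_band(cfg$tap_band, "tap_band")
  check_band(cfg$marker_band, "marker_band")
  check_band(cfg$test_band, "test_band")
  if (cfg$stim_stopband[1] > cfg$tap_band[1] || cfg$stim_stopband[2] < cfg$tap_band[2]) {
    input_error("stim_stopband must cover tap_band")
  }
  if (cfg$marker_amplitude <= 0 || cfg$marker_amplitude > 1) {
    input_error("marker_amplitude must lie in (0, 1]")
  }
  for (f in c("marker_duration", "marker_gap", "stim_padding", "min_onset_gap",
              "envelope_window", "enhance_window", "marker_match_tol")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      input_error(sprintf("%s must be a positive number of ms", f))
    }
  }
  if (cfg$markers_per_block < 1) input_error("markers_per_block must be >= 1")
  if (cfg$onset_threshold_frac <= 0 || cfg$onset_threshold_frac >= 1) {
    input_error("onset_threshold_frac must lie in (0, 1)")
  }
  invisible(cfg)
}

#' Read or write a configuration as JSON
#'
#' Field names in the JSON file are exactly the argument names of
#' [tapsync_config()]; absent fields take their defaults.
#'
#' @param path file path.
#' @param cfg a `tapsync_config`.
#' @return `read_config` returns a `tapsync_config`; `write_config`
#'   (invisibly) the path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) input_error(sprintf("config file not found: %s", path))
  raw <- jsonlite::fromJSON(path)
  known <- names(formals(tapsync_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) warning("ignoring unknown config fields: ",
                             paste(extra, collapse = ", "))
  do.call(tapsync_config, raw[intersect(names(raw), known)])
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "tapsync_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.tapsync_config <- function(x, ...) {
  cat("tapsync configuration\n")
  cat(sprintf("  sample_rate : %g Hz\n", x$sample_rate))
  cat(sprintf("  stimulus stopband : %g-%g Hz\n", x$stim_stopband[1], x$stim_stopband[2]))
  cat(sprintf("  tap band    : %g-%g Hz\n", x$tap_band[1], x$tap_band[2]))
  cat(sprintf("  marker band : %g-%g Hz   test band : %g-%g Hz\n",
              x$marker_band[1], x$marker_band[2], x$test_band[1], x$test_band[2]))
  cat(sprintf("  markers     : %d per block, %g ms + %g ms gap, amp %.2f\n",
              x$markers_per_block, x$marker_duration, x$marker_gap, x$marker_amplitude))
  invisible(x)
}
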