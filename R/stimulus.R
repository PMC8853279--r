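# Stimulus preparation: band-limit the stimulus away from the tapping
# range, then frame it with marker blocks whose onsets are known exactly.

# One block = markers_per_block marker sounds separated by marker_gap.
marker_block_duration_ms <- function(config) {
  config$markers_per_block * config$marker_duration +
    (config$markers_per_block - 1) * config$marker_gap
}

#' Synthesize one marker sound
#'
#' The marker is an equal mix of band-filtered white noise and a pure tone
#' at the geometric centre of `marker_band`, both confined to the marker
#' band, with a sharp attack (the onset is the first sample) and a short
#' fade-out.  Peak amplitude is `marker_amplitude` — markers are played near
#' full scale so they survive attenuation by consumer hardware.
#'
#' @param config a [tapsync_config].
#' @param seed integer; fixes the noise realization so the same seed yields
#'   a bit-identical waveform.
#' @return [waveform] of length `marker_duration` ms.
#' @export
generate_marker_sound <- function(config = tapsync_config(), seed = 1L) {
  fs <- config$sample_rate
  band <- config$marker_band
  if (band[2] >= fs / 2) input_error("marker_band exceeds Nyquist frequency")
  n <- ms_to_samples(config$marker_duration, fs)
  n_syn <- n + ms_to_samples(20, fs)        # headroom for attack trimming
  t <- (seq_len(n_syn) - 1) / fs
  f0 <- sqrt(band[1] * band[2])
  tone <- sin(2 * pi * f0 * t)
  noise <- with_seed(seed, stats::rnorm(n_syn))
  noise <- bandpass(waveform(noise, fs), band[1], band[2])$samples
  noise <- noise / max(abs(noise))
  x <- trim_to_attack(0.5 * tone + 0.5 * noise)[seq_len(n)]
  fade_n <- min(n, ms_to_samples(5, fs))            # avoid an offset click
  x[(n - fade_n + 1):n] <- x[(n - fade_n + 1):n] * seq(1, 0, length.out = fade_n)
  x <- x / max(abs(x)) * config$marker_amplitude
  waveform(x, fs)
}

#' Remove the tapping frequency range from a stimulus
#'
#' Zero-phase high-pass that clears the stimulus out of `stim_stopband`
#' (by default 50-500 Hz) so that tap sounds can later be recovered from
#' that band without interference.  The cutoff is placed half an octave
#' above the stopband edge and the forward-backward pass is applied twice
#' (two cascaded order-5 stages, numerically stabler than one order-10
#' design at so low a normalized cutoff): the stopband edge is attenuated
#' by more than 40 dB while content one octave above it is preserved
#' within 1 dB.  Zero phase means stated stimulus onset times remain valid
#' after filtering.
#'
#' @param wave stimulus [waveform] at the configured sample rate.
#' @param config a [tapsync_config].
#' @return filtered [waveform], same length.
#' @export
filter_stimulus <- function(wave, config = tapsync_config()) {
  stopifnot(inherits(wave, "waveform"))
  if (wave$sample_rate != config$sample_rate) {
    input_error("stimulus sample rate does not match config$sample_rate")
  }
  nyq <- config$sample_rate / 2
  cutoff <- config$stim_stopband[2] * sqrt(2)
  hf <- signal::butter(5, cutoff / nyq, type = "high")
  waveform(signal::filtfilt(hf, signal::filtfilt(hf, wave$samples)),
           wave$sample_rate)
}

#' Prepare a stimulus for a free-field trial
#'
#' Produces the playback waveform
#' `[marker block] [padding] [filtered stimulus] [padding] [marker block]`
#' together with the stimulus onsets shifted onto the new timeline and the
#' exact onset times of every marker sound.  The marker blocks at both ends
#' are what later anchors the recording to this known timeline.
#'
#' @param stim stimulus [waveform].
#' @param onsets numeric vector, stimulus onset times in ms from the start
#'   of `stim` (may be "virtual" onsets with no physical energy).
#' @param config a [tapsync_config].
#' @param seed seed for the marker noise component.
#' @return object of class `prepared_stimulus`: list with `waveform`,
#'   `stim_onsets`, `marker_onsets`, `config`.
#' @export
prepare_stimulus <- function(stim, onsets, config = tapsync_config(), seed = 1L) {
  stopifnot(inherits(stim, "waveform"))
  onsets <- as.numeric(onsets)
  dur <- duration_ms(stim)
  bad <- onsets[onsets < 0 | onsets > dur]
  if (length(bad)) {
    input_error(sprintf("onsets outside the stimulus [0, %.1f] ms: %s",
                        dur, paste(round(bad, 1), collapse = ", ")))
  }
  fs <- config$sample_rate
  marker <- generate_marker_sound(config, seed = seed)
  gap_n <- ms_to_samples(config$marker_gap, fs)
  pad_n <- ms_to_samples(config$stim_padding, fs)
  k <- config$markers_per_block

  block <- numeric(0)
  rel_onsets <- numeric(k)
  for (i in seq_len(k)) {
    rel_onsets[i] <- index_to_ms(length(block) + 1L, fs)
    block <- c(block, marker$samples)
    if (i < k) block <- c(block, numeric(gap_n))
  }
  filtered <- filter_stimulus(stim, config)

  out <- c(block, numeric(pad_n), filtered$samples, numeric(pad_n), block)
  peak <- max(abs(out))
  if (peak > 1) out <- out / peak

  shift <- index_to_ms(length(block) + pad_n + 1L, fs)
  end_block_start <- index_to_ms(length(block) + pad_n + length(filtered$samples) +
                                   pad_n + 1L, fs)
  marker_onsets <- c(rel_onsets, end_block_start + rel_onsets)

  structure(list(waveform = waveform(out, fs),
                 stim_onsets = onsets + shift,
                 marker_onsets = marker_onsets,
                 config = config),
            class = "prepared_stimulus")
}

#' @export
print.prepared_stimulus <- function(x, ...) {
  cat(sprintf("prepared stimulus: %.1f ms, %d stimulus onsets, %d markers\n",
              duration_ms(x$waveform), length(x$stim_onsets), length(x$marker_onsets)))
  invisible(x)
}

#' Serialize prepared-stimulus metadata
#'
#' Writes (or reads back) the onset lists of a prepared stimulus as JSON so
#' that recording analysis can run without re-generating the stimulus.  The
#' waveform itself travels separately as WAV.
#'
#' @param prepared a `prepared_stimulus`.
#' @param path JSON path.
#' @export
write_prepared <- function(prepared, path) {
  jsonlite::write_json(list(stim_onsets = prepared$stim_onsets,
                            marker_onsets = prepared$marker_onsets,
                            config = unclass(prepared$config)),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_prepared
#' @export
read_prepared <- function(path) {
  raw <- jsonlite::fromJSON(path)
  cfg <- do.call(tapsync_config,
                 raw$config[intersect(names(raw$config), names(formals(tapsync_config)))])
  structure(list(waveform = NULL,
                 stim_onsets = as.numeric(raw$stim_onsets),
                 marker_onsets = as.numeric(raw$marker_onsets),
                 config = cfg),
            class = "prepared_stimulus")
}

#' Isochronous metronome stimulus
#'
#' A train of short clicks at a fixed inter-onset interval.  The click is a
#' 10 ms 3 kHz burst with an exponentially decaying envelope: well above
#' the stimulus stopband, so it passes [filter_stimulus()] unchanged, and
#' sharp-attacked so its physical onset is its first sample.
#'
#' @param ioi_ms inter-onset interval in ms.
#' @param n_clicks number of clicks (>= 1).
#' @param config a [tapsync_config].
#' @param click_freq click carrier frequency, Hz.
#' @param click_dur click duration, ms.
#' @param amplitude click peak amplitude.
#' @return list with `waveform` and `onsets` (ms; `0, ioi, 2*ioi, ...`).
#' @export
make_isochronous_stimulus <- function(ioi_ms, n_clicks, config = tapsync_config(),
                                      click_freq = 3000, click_dur = 10,
                                      amplitude = 0.8) {
  if (ioi_ms <= 0) input_error("ioi_ms must be positive")
  if (n_clicks < 1) input_error("n_clicks must be >= 1")
  if (ioi_ms <= click_dur) input_error("ioi_ms must exceed the click duration")
  fs <- config$sample_rate
  nc <- ms_to_samples(click_dur, fs)
  t <- (seq_len(nc) - 1) / fs
  click <- sin(2 * pi * click_freq * t) * exp(-t / 0.003)
  click <- click / max(abs(click)) * amplitude
  onsets <- (seq_len(n_clicks) - 1) * ioi_ms
  total_n <- ms_to_index(onsets[n_clicks], fs) - 1L + nc
  x <- numeric(total_n)
  for (on in onsets) {
    i <- ms_to_index(on, fs)
    x[i:(i + nc - 1L)] <- x[i:(i + nc - 1L)] + click
  }
  list(waveform = waveform(x, fs), onsets = onsets)
}
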