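# Shared fixtures and independent oracles.  Fixtures are synthesized in
# code; oracles are deliberately naive re-derivations (per-sample loops,
# periodograms) independent of the implementation they check.

default_cfg <- tapsync_config()

# Fraction of spectral power inside [low, high] Hz, via the raw periodogram.
band_energy_fraction <- function(x, fs, low, high) {
  p <- Mod(stats::fft(x))^2
  n <- length(x)
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  p <- p[half]; freqs <- freqs[half]
  sum(p[freqs >= low & freqs <= high]) / sum(p)
}

# Attenuation of a pure tone by `filter_fun`, in dB (positive = attenuated).
tone_attenuation_db <- function(freq, filter_fun, fs = 44100, dur_s = 1) {
  t <- seq(0, dur_s, by = 1 / fs)
  x <- sin(2 * pi * freq * t)
  y <- filter_fun(waveform(x, fs))$samples
  # interior only: skip filter edge transients
  core <- seq(round(length(x) * 0.25), round(length(x) * 0.75))
  20 * log10(sqrt(mean(x[core]^2)) / sqrt(mean(y[core]^2)))
}

# Naive per-sample re-implementation of the onset-extraction contract:
# trailing-window mean of |x|, relative threshold, first supra-threshold
# sample per excursion, refractory merge.  (Valid for clean fixtures whose
# median envelope is zero, where the noise-floor rule never engages.)
oracle_onsets <- function(x, fs, cfg = default_cfg) {
  w <- as.integer(round(cfg$envelope_window / 1000 * fs))
  n <- length(x)
  env <- numeric(n)
  for (i in seq_len(n)) env[i] <- mean(abs(x[max(1, i - w + 1):i]))
  thr <- cfg$onset_threshold_frac * max(env)
  gap <- as.integer(round(cfg$min_onset_gap / 1000 * fs))
  onsets <- integer(0); last <- -Inf; prev <- FALSE
  for (i in seq_len(n)) {
    above <- env[i] > thr
    if (above && !prev && i - last >= gap) { onsets <- c(onsets, i); last <- i }
    prev <- above
  }
  (onsets - 1) / fs * 1000
}

# A silent waveform with unit-amplitude white-noise bursts at given times.
burst_fixture <- function(times_ms, dur_s = NULL, fs = 44100, burst_ms = 10,
                          amp = 1, seed = 42) {
  if (is.null(dur_s)) dur_s <- (max(times_ms) + 500) / 1000
  x <- numeric(round(dur_s * fs))
  nb <- round(burst_ms / 1000 * fs)
  burst <- withr::with_seed(seed, stats::runif(nb, -1, 1)) * amp
  for (tm in times_ms) {
    i <- round(tm / 1000 * fs) + 1
    x[i:(i + nb - 1)] <- x[i:(i + nb - 1)] + burst
  }
  waveform(x, fs)
}

# One fully simulated trial: isochronous stimulus, virtual tapper, virtual
# device, analyzed end to end.
simulated_trial <- function(ioi = 500, n_clicks = 12, seed = 101,
                            start_delay = 270, snr_db = 25,
                            participant = virtual_participant(seed = seed),
                            device = virtual_device(start_delay = start_delay,
                                                    snr_db = snr_db,
                                                    seed = seed + 1),
                            cfg = default_cfg) {
  stim <- make_isochronous_stimulus(ioi, n_clicks, cfg)
  prep <- prepare_stimulus(stim$waveform, stim$onsets, cfg, seed = seed)
  taps <- simulate_taps(prep$stim_onsets, participant)
  sim <- render_recording(prep, taps$tap_times, device, cfg)
  an <- analyze_recording(sim$recording, prep, cfg)
  list(prep = prep, taps = taps, sim = sim, an = an)
}
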