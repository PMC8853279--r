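# Virtual participant and virtual device: synthetic free-field trials with
# exact ground truth, standing in for human recordings in every test.  The
# participant is a generative linear phase-correction tapper; the device
# adds the recording-chain pathologies that motivate marker-based
# alignment: an uncontrollable start delay, background noise, and (for the
# failure path) marker attenuation by noise cancellation.

#' Virtual participant
#'
#' A generative tapper following the linear phase-correction model (see
#' [fit_vorberg_wing()]) with a constant mean asynchrony.  Human tappers
#' typically anticipate the beat, so `mean_async` defaults to -30 ms; the
#' noise defaults (`sigma_t` 15 ms, `sigma_m` 8 ms, `alpha` 0.5) produce an
#' asynchrony SD in the 20-30 ms range typical of isochronous tapping.
#'
#' @param mean_async constant asynchrony offset, ms.
#' @param alpha error-correction gain in \[0, 2).
#' @param sigma_t timekeeper noise SD, ms.
#' @param sigma_m motor noise SD, ms.
#' @param miss_prob probability any tap is omitted, in \[0, 1).
#' @param seed RNG seed for this participant.
#' @return object of class `virtual_participant`.
#' @export
virtual_participant <- function(mean_async = -30, alpha = 0.5, sigma_t = 15,
                                sigma_m = 8, miss_prob = 0, seed = 1L) {
  stopifnot(sigma_t >= 0, sigma_m >= 0, alpha >= 0, alpha < 2,
            miss_prob >= 0, miss_prob < 1)
  structure(list(mean_async = mean_async, alpha = alpha, sigma_t = sigma_t,
                 sigma_m = sigma_m, miss_prob = miss_prob, seed = seed),
            class = "virtual_participant")
}

#' Virtual recording device
#'
#' @param start_delay leading silence before playback reaches the
#'   microphone, ms (sound-card/OS latency stand-in).
#' @param snr_db signal-to-noise ratio of added white Gaussian noise, dB
#'   (`Inf` for a noise-free recording).
#' @param marker_attenuation multiplicative gain applied to the marker
#'   segments only, in \[0, 1\] (noise-cancellation stand-in).
#' @param tap_gain amplitude of rendered tap sounds.
#' @param seed RNG seed for the device noise and tap sound.
#' @return object of class `virtual_device`.
#' @export
virtual_device <- function(start_delay = 0, snr_db = Inf,
                           marker_attenuation = 1, tap_gain = 0.3, seed = 1L) {
  stopifnot(start_delay >= 0, marker_attenuation >= 0, marker_attenuation <= 1)
  structure(list(start_delay = start_delay, snr_db = snr_db,
                 marker_attenuation = marker_attenuation,
                 tap_gain = tap_gain, seed = seed),
            class = "virtual_device")
}

#' Generate tap times from a virtual participant
#'
#' Centred asynchronies follow
#' `A_[n+1] = (1 - alpha) A_n + T_n + M_[n+1] - M_n`, initialised from the
#' model's stationary distribution; tap times are
#' `stim_onsets + mean_async + A_n`.  Taps are then dropped independently
#' with probability `miss_prob`.
#'
#' @param stim_onsets numeric, stimulus onset times, ms (length >= 2).
#' @param participant a [virtual_participant].
#' @return list with `tap_times` (rendered taps, ms), `true_asynchronies`
#'   (the asynchrony of every rendered tap, ms), `stim_index` (which
#'   stimulus onset each rendered tap belongs to).
#' @export
simulate_taps <- function(stim_onsets, participant) {
  n <- length(stim_onsets)
  stopifnot(n >= 2)
  p <- participant
  beta <- 1 - p$alpha
  with_seed(p$seed, {
    Tn <- stats::rnorm(n, 0, p$sigma_t)
    Mn <- stats::rnorm(n + 1, 0, p$sigma_m)
    A <- numeric(n)
    if (abs(beta) < 1) {
      g0 <- (p$sigma_t^2 + 2 * (1 - beta) * p$sigma_m^2) / (1 - beta^2)
      A[1] <- stats::rnorm(1, 0, sqrt(g0))
    } else {
      A[1] <- Tn[1] + Mn[2] - Mn[1]
    }
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        A[i + 1] <- beta * A[i] + Tn[i] + Mn[i + 2] - Mn[i + 1]
      }
    }
    kept <- stats::runif(n) >= p$miss_prob
  })
  asyn <- p$mean_async + A
  list(tap_times = (stim_onsets + asyn)[kept],
       true_asynchronies = asyn[kept],
       stim_index = which(kept))
}

#' Synthesize a finger-tap sound
#'
#' A short (15 ms) exponentially decaying broadband burst band-limited to
#' `tap_band`, imitating the crisp sound of a fingertip striking the laptop
#' surface; most of its energy lies in 80-500 Hz.  The onset is the first
#' sample.
#'
#' @param config a [tapsync_config].
#' @param seed RNG seed; same seed, same waveform.
#' @return [waveform] with unit peak amplitude.
#' @export
render_tap_sound <- function(config = tapsync_config(), seed = 1L) {
  fs <- config$sample_rate
  n <- ms_to_samples(15, fs)
  n_syn <- n + ms_to_samples(10, fs)        # headroom for attack trimming
  t <- (seq_len(n_syn) - 1) / fs
  x <- with_seed(seed, stats::rnorm(n_syn)) * exp(-t / 0.006)
  x <- bandpass(waveform(x, fs), config$tap_band[1], config$tap_band[2])$samples
  x <- trim_to_attack(x)[seq_len(n)]
  waveform(x / max(abs(x)), fs)
}

#' Render a simulated free-field trial recording
#'
#' Assembles the mono recording a laptop microphone would capture:
#' `start_delay` of silence, then the prepared stimulus with its marker
#' segments scaled by `marker_attenuation`, with tap sounds mixed in at
#' `tap_gain` and white noise added at `snr_db` relative to the signal RMS.
#' Samples are hard-limited to \[-1, 1\].
#'
#' @param prepared a `prepared_stimulus` (with its waveform).
#' @param tap_times numeric, tap times on the prepared-stimulus timeline,
#'   ms; must lie within the prepared waveform.
#' @param device a [virtual_device].
#' @param config a [tapsync_config].
#' @return list with `recording` ([waveform]) and `ground_truth`: marker,
#'   stimulus and tap times on the recording timeline (all shifted by
#'   `start_delay`), plus `clip_fraction`.
#' @export
render_recording <- function(prepared, tap_times = numeric(0),
                             device = virtual_device(),
                             config = prepared$config) {
  stopifnot(inherits(prepared, "prepared_stimulus"), !is.null(prepared$waveform))
  fs <- config$sample_rate
  span <- duration_ms(prepared$waveform)
  if (length(tap_times) && (any(tap_times < 0) || any(tap_times > span))) {
    input_error("tap times outside the prepared stimulus span")
  }
  delay_n <- ms_to_samples(device$start_delay, fs)
  tail_n <- ms_to_samples(500, fs)
  sig <- prepared$waveform$samples

  # Noise cancellation suppresses exactly the loud narrow-band markers.
  if (device$marker_attenuation < 1) {
    dur_n <- ms_to_samples(config$marker_duration, fs)
    for (on in prepared$marker_onsets) {
      i <- ms_to_index(on, fs)
      j <- min(length(sig), i + dur_n - 1L)
      sig[i:j] <- sig[i:j] * device$marker_attenuation
    }
  }

  x <- c(numeric(delay_n), sig, numeric(tail_n))
  tap <- render_tap_sound(config, seed = device$seed)
  for (tt in tap_times) {
    i <- delay_n + ms_to_index(tt, fs)
    j <- min(length(x), i + length(tap$samples) - 1L)
    x[i:j] <- x[i:j] + device$tap_gain * tap$samples[seq_len(j - i + 1L)]
  }
  if (is.finite(device$snr_db)) {
    sigma <- rms(x) * 10^(-device$snr_db / 20)
    x <- x + with_seed(device$seed + 1L, stats::rnorm(length(x), 0, sigma))
  }
  clip_fraction <- mean(abs(x) > 1)
  x[x > 1] <- 1; x[x < -1] <- -1

  list(recording = waveform(x, fs),
       ground_truth = list(
         marker_times = prepared$marker_onsets + device$start_delay,
         stim_times = prepared$stim_onsets + device$start_delay,
         tap_times = tap_times + device$start_delay,
         start_delay = device$start_delay,
         clip_fraction = clip_fraction))
}

# ---------------------------------------------------------------------------
# Ground-truth comparison helpers shared by the validation studies.

# Count / measure detected times against true times: each true time is
# matched to the nearest detected time; matches within `tol` ms count.
match_to_truth <- function(detected, truth, tol = 5) {
  if (length(truth) == 0) return(list(n = 0L, errors = numeric(0)))
  err <- vapply(truth, function(tt) {
    if (length(detected) == 0) return(NA_real_)
    d <- detected[which.min(abs(detected - tt))] - tt
    d
  }, numeric(1))
  ok <- !is.na(err) & abs(err) <= tol
  list(n = sum(ok), errors = err[ok])
}

#' Simulated timing-accuracy study
#'
#' Renders `n_trials` simulated trials of an isochronous stimulus with a
#' virtual tapper, each through a virtual device with a random start delay
#' (uniform 0-1000 ms) and white noise at `snr_db`, runs the full analysis
#' pipeline, and pools the absolute timing error of every recovered marker,
#' realigned stimulus onset, and detected tap against its ground-truth
#' time.
#'
#' @param n_trials number of simulated trials.
#' @param seed master seed; per-trial seeds are derived from it.
#' @param config a [tapsync_config].
#' @param n_clicks,ioi_ms stimulus layout per trial.
#' @param snr_db device noise level, dB.
#' @param tol_ms matching tolerance when pairing recovered with true times.
#' @return list with `mean_abs_error_ms`, `sd_error_ms`, `n_onsets`
#'   (onsets compared), `n_trials`, and the per-component errors.
#' @export
timing_accuracy_study <- function(n_trials = 50, seed = 1L,
                                  config = tapsync_config(),
                                  n_clicks = 20, ioi_ms = 500,
                                  snr_db = 25, tol_ms = 20) {
  stim <- make_isochronous_stimulus(ioi_ms, n_clicks, config)
  prepared <- prepare_stimulus(stim$waveform, stim$onsets, config, seed = seed)
  delays <- with_seed(seed, stats::runif(n_trials, 0, 1000))
  errors <- list(marker = numeric(0), stim = numeric(0), tap = numeric(0))
  for (i in seq_len(n_trials)) {
    p <- virtual_participant(seed = seed + 1000L + i)
    d <- virtual_device(start_delay = delays[i], snr_db = snr_db,
                        seed = seed + 2000L + i)
    taps <- simulate_taps(prepared$stim_onsets, p)
    sim <- render_recording(prepared, taps$tap_times, d, config)
    an <- analyze_recording(sim$recording, prepared, config)
    if (is.null(an$aligned)) next
    det_m <- an$aligned$detected_markers
    errors$marker <- c(errors$marker,
      match_to_truth(det_m[!is.na(det_m)],
                     sim$ground_truth$marker_times, tol_ms)$errors)
    errors$stim <- c(errors$stim,
      match_to_truth(an$aligned$realigned_stim_onsets,
                     sim$ground_truth$stim_times, tol_ms)$errors)
    errors$tap <- c(errors$tap,
      match_to_truth(an$aligned$realigned_tap_onsets,
                     sim$ground_truth$tap_times, tol_ms)$errors)
  }
  all_err <- c(errors$marker, errors$stim, errors$tap)
  list(mean_abs_error_ms = mean(abs(all_err)),
       sd_error_ms = stats::sd(all_err),
       n_onsets = length(all_err),
       n_trials = n_trials,
       errors = errors)
}

#' Simulated validation suite (three parts)
#'
#' Re-creates the three-part timing-accuracy validation in simulation:
#' \describe{
#'   \item{part 1}{four trials of 100 metronome clicks at IOIs 250, 500,
#'     750 and 1000 ms, no taps; counts realigned stimulus onsets within
#'     `tol_ms` of their ground-truth click times.}
#'   \item{part 2}{the same four trials with a synchronized virtual tapper
#'     (one tap per click, no misses); counts detected taps within `tol_ms`
#'     of ground truth.}
#'   \item{part 3}{two trials of 20 clicks (IOIs 500 and 1000 ms) with taps
#'     placed in anti-phase (`click + IOI/2`), so clicks, markers and taps
#'     share one recording; counts detected taps.}
#' }
#'
#' @param config a [tapsync_config].
#' @param seed master seed.
#' @param snr_db device noise level for all rendered recordings, dB.
#' @param tol_ms tolerance for counting an onset as recovered, ms.
#' @return nested list `part1`, `part2`, `part3`, each with per-trial and
#'   total counts plus pooled error summaries.
#' @export
run_validation_suite <- function(config = tapsync_config(), seed = 1L,
                                 snr_db = 25, tol_ms = 5) {
  iois <- c(250, 500, 750, 1000)
  run_trial <- function(ioi, n_clicks, tap_mode, trial_seed) {
    stim <- make_isochronous_stimulus(ioi, n_clicks, config)
    prepared <- prepare_stimulus(stim$waveform, stim$onsets, config,
                                 seed = trial_seed)
    taps <- switch(tap_mode,
      none = numeric(0),
      sync = simulate_taps(prepared$stim_onsets,
                           virtual_participant(seed = trial_seed))$tap_times,
      antiphase = prepared$stim_onsets + ioi / 2)
    delay <- with_seed(trial_seed + 500L, stats::runif(1, 100, 600))
    dev <- virtual_device(start_delay = delay, snr_db = snr_db,
                          seed = trial_seed + 900L)
    sim <- render_recording(prepared, taps, dev, config)
    an <- analyze_recording(sim$recording, prepared, config)
    stim_m <- if (!is.null(an$aligned)) {
      match_to_truth(an$aligned$realigned_stim_onsets,
                     sim$ground_truth$stim_times, tol_ms)
    } else list(n = 0L, errors = numeric(0))
    tap_m <- if (!is.null(an$aligned)) {
      match_to_truth(an$aligned$realigned_tap_onsets,
                     sim$ground_truth$tap_times, tol_ms)
    } else list(n = 0L, errors = numeric(0))
    list(ioi = ioi, n_clicks = n_clicks,
         n_stim_recovered = stim_m$n, stim_errors = stim_m$errors,
         n_taps_recovered = tap_m$n, tap_errors = tap_m$errors,
         n_taps_true = length(taps),
         diagnostics = an$diagnostics)
  }
  summarize_part <- function(trials, field_n, field_e) {
    errs <- unlist(lapply(trials, `[[`, field_e))
    list(trials = trials,
         total = sum(vapply(trials, `[[`, integer(1), field_n)),
         latency_mean = if (length(errs)) mean(errs) else NA_real_,
         latency_sd = if (length(errs) > 1) stats::sd(errs) else NA_real_)
  }
  part1 <- summarize_part(
    lapply(seq_along(iois), function(i)
      run_trial(iois[i], 100, "none", seed + i)),
    "n_stim_recovered", "stim_errors")
  part2 <- summarize_part(
    lapply(seq_along(iois), function(i)
      run_trial(iois[i], 100, "sync", seed + 10L + i)),
    "n_taps_recovered", "tap_errors")
  part3 <- summarize_part(
    lapply(seq_along(c(500, 1000)), function(i)
      run_trial(c(500, 1000)[i], 20, "antiphase", seed + 20L + i)),
    "n_taps_recovered", "tap_errors")
  list(part1 = part1, part2 = part2, part3 = part3)
}
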