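test_that("realignment shifts the known onsets by the first-marker offset", {
  prep <- list(stim_onsets = c(2250, 2750, 3250),
               marker_onsets = c(0, 750, 1500, 4000, 4750, 5500))
  class(prep) <- "prepared_stimulus"

  al <- realign(prep, detected_markers = prep$marker_onsets + 270,
                detected_taps = c(2500, 3000))
  expect_equal(al$offset_ms, 270)
  expect_equal(al$realigned_stim_onsets, prep$stim_onsets + 270)
  expect_equal(al$realigned_tap_onsets, c(2500, 3000))

  # zero delay: identity
  al0 <- realign(prep, prep$marker_onsets, numeric(0))
  expect_equal(al0$offset_ms, 0)
  expect_equal(al0$realigned_stim_onsets, prep$stim_onsets)

  # a missed first marker anchors on the first detected one
  det <- c(NA, prep$marker_onsets[-1] + 100)
  al2 <- realign(prep, det, numeric(0))
  expect_equal(al2$offset_ms, 100)

  expect_error(realign(prep, rep(NA_real_, 6), numeric(0)),
               class = "tapsync_quality_error")
})

test_that("tap matching follows the asynchrony definition and uses each onset once", {
  m <- match_taps(c(0, 500, 1000), c(-20, 510, 990), match_window = 250)
  expect_equal(nrow(m), 3)
  expect_equal(m$asynchrony, c(-20, 10, -10))
  expect_equal(m$stim_index, 1:3)

  # no taps
  expect_equal(nrow(match_taps(c(0, 500), numeric(0), 250)), 0)

  # two taps near one onset: exactly one match, the nearer tap wins
  m2 <- match_taps(500, c(480, 530), 250)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$tap_onset, 480)

  # equidistant taps resolve to the earlier tap
  m3 <- match_taps(500, c(490, 510), 250)
  expect_equal(m3$tap_onset, 490)

  # taps outside the window never match
  m4 <- match_taps(c(0, 1000), c(400, 600), match_window = 250)
  expect_equal(nrow(m4), 0)
})

test_that("failing criteria code the documented reasons", {
  cfg <- default_cfg
  ok <- evaluate_trial(6, 6, 0.5, 20, 20, cfg)
  expect_true(ok$passed)
  expect_length(ok$fail_reasons, 0)
  expect_equal(ok$pct_detected_taps, 100)

  non_tapper <- evaluate_trial(6, 6, 0.5, 0, 20, cfg)
  expect_false(non_tapper$passed)
  expect_true("too_few_taps" %in% non_tapper$fail_reasons)

  bad_markers <- evaluate_trial(4, 6, 0.5, 20, 20, cfg)
  expect_true("markers_missing" %in% bad_markers$fail_reasons)

  drifted <- evaluate_trial(6, 6, 50, 20, 20, cfg)
  expect_true("marker_error" %in% drifted$fail_reasons)

  over <- evaluate_trial(6, 6, 0.5, 45, 20, cfg)
  expect_true("too_many_taps" %in% over$fail_reasons)
  expect_false(over$passed)
})

test_that("a clean simulated trial round-trips asynchronies within 2 ms", {
  tr <- simulated_trial(ioi = 500, n_clicks = 12, seed = 51, start_delay = 270)
  an <- tr$an
  expect_true(an$diagnostics$passed)
  expect_equal(an$diagnostics$n_matched_taps, 12)
  truth <- tr$taps$true_asynchronies[match(an$aligned$matches$stim_index,
                                           tr$taps$stim_index)]
  expect_lt(max(abs(an$aligned$asynchronies - truth)), 2)
})

test_that("taps placed exactly on the clicks give asynchronies within 2 ms of zero", {
  tr <- simulated_trial(
    ioi = 500, n_clicks = 10, seed = 53, start_delay = 150,
    participant = virtual_participant(mean_async = 0, alpha = 0, sigma_t = 0,
                                      sigma_m = 0, seed = 53))
  expect_true(tr$an$diagnostics$passed)
  expect_equal(length(tr$an$aligned$asynchronies), 10)
  expect_lt(max(abs(tr$an$aligned$asynchronies)), 2)
})

test_that("analysis is invariant to leading silence and to recording gain", {
  cfg <- default_cfg
  tr <- simulated_trial(ioi = 500, n_clicks = 8, seed = 57, start_delay = 120)
  base <- tr$an$aligned$asynchronies
  fs <- cfg$sample_rate

  shifted <- waveform(c(numeric(round(0.4 * fs)), tr$sim$recording$samples), fs)
  a_shift <- analyze_recording(shifted, tr$prep, cfg)$aligned$asynchronies
  expect_equal(a_shift, base, tolerance = 0.1)

  scaled <- waveform(tr$sim$recording$samples * 0.25, fs)
  a_scale <- analyze_recording(scaled, tr$prep, cfg)$aligned$asynchronies
  expect_lt(max(abs(a_scale - base)), 1)
})

test_that("tap and marker detections never cross-contaminate", {
  # anti-phase taps: every tap sits maximally far from every click
  cfg <- default_cfg
  stim <- make_isochronous_stimulus(500, 10, cfg)
  prep <- prepare_stimulus(stim$waveform, stim$onsets, cfg, seed = 61)
  taps <- prep$stim_onsets + 250
  sim <- render_recording(prep, taps, virtual_device(start_delay = 180, snr_db = 25,
                                                     seed = 62), cfg)
  an <- analyze_recording(sim$recording, prep, cfg)
  det_taps <- an$aligned$realigned_tap_onsets
  det_mk <- an$aligned$detected_markers
  expect_equal(length(det_taps), 10)
  for (m in det_mk) expect_true(all(abs(det_taps - m) > 50))
  for (tp in sim$ground_truth$tap_times) {
    expect_true(any(abs(det_taps - tp) <= 5))
    expect_true(all(abs(det_mk - tp) > 50))
  }
})

test_that("silence and markerless recordings fail gracefully with diagnostics", {
  cfg <- default_cfg
  stim <- make_isochronous_stimulus(500, 4, cfg)
  prep <- prepare_stimulus(stim$waveform, stim$onsets, cfg, seed = 63)
  silence <- waveform(numeric(6 * cfg$sample_rate), cfg$sample_rate)
  an <- analyze_recording(silence, prep, cfg)
  expect_false(an$diagnostics$passed)
  expect_true("markers_missing" %in% an$diagnostics$fail_reasons)
  expect_null(an$metrics)
})
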