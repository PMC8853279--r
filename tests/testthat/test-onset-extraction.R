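test_that("bandpass passes the band centre, rejects one octave out, and is zero-phase", {
  cfg <- default_cfg
  centre <- sqrt(200 * 340)
  expect_lt(abs(tone_attenuation_db(centre, function(w) bandpass(w, 200, 340))), 1)
  expect_gte(tone_attenuation_db(680, function(w) bandpass(w, 200, 340)), 40)
  expect_gte(tone_attenuation_db(100, function(w) bandpass(w, 200, 340)), 40)

  # impulse response symmetric about the impulse => zero phase
  fs <- 44100
  x <- numeric(fs); x[fs / 2] <- 1
  y <- bandpass(waveform(x, fs), 200, 340)$samples
  left <- y[(fs / 2 - 1):(fs / 2 - 2000)]
  right <- y[(fs / 2 + 1):(fs / 2 + 2000)]
  expect_lt(max(abs(left - right)), 1e-6)

  expect_error(bandpass(waveform(x, fs), 340, 200), class = "tapsync_input_error")
  expect_error(bandpass(waveform(x, fs), 200, 30000), class = "tapsync_input_error")
})

test_that("channel splitting separates taps from markers and keeps silence silent", {
  cfg <- default_cfg
  z <- split_channels(waveform(numeric(3 * 44100), 44100), cfg)
  expect_lt(max(abs(z$tap_channel$samples)), 1e-9)
  expect_lt(max(abs(z$enhanced_marker_channel$samples)), 1e-9)
  expect_equal(length(z$test_channel$samples), 3 * 44100)

  # a too-short recording cannot carry a marker block
  expect_error(split_channels(waveform(numeric(4410), 44100), cfg),
               "marker block", class = "tapsync_quality_error")
})

test_that("marker enhancement boosts markers but not broadband bursts", {
  cfg <- default_cfg
  fs <- cfg$sample_rate
  marker <- generate_marker_sound(cfg, seed = 1)
  n <- 2 * fs
  x <- numeric(n)
  i <- fs %/% 2
  x[i:(i + length(marker$samples) - 1)] <- marker$samples
  w <- waveform(x, fs)
  mc <- bandpass(w, cfg$marker_band[1], cfg$marker_band[2])
  tc <- bandpass(w, cfg$test_band[1], cfg$test_band[2])
  enh <- enhance_markers(mc, tc, cfg)
  gain <- enh$samples / ifelse(abs(mc$samples) > 1e-9, mc$samples, NA)
  burst_idx <- seq(i + 500, i + length(marker$samples) - 500)
  expect_gt(mean(gain[burst_idx] == cfg$boost_gain, na.rm = TRUE), 0.9)

  # flat broadband burst: similar energy density in both bands => no boost
  xb <- numeric(n)
  xb[i:(i + 660)] <- withr::with_seed(8, stats::runif(661, -1, 1))
  wb <- waveform(xb, fs)
  mcb <- bandpass(wb, cfg$marker_band[1], cfg$marker_band[2])
  tcb <- bandpass(wb, cfg$test_band[1], cfg$test_band[2])
  enhb <- enhance_markers(mcb, tcb, cfg)
  gb <- enhb$samples / ifelse(abs(mcb$samples) > 1e-9, mcb$samples, NA)
  expect_lt(mean(gb == cfg$boost_gain, na.rm = TRUE), 0.05)

  # silence in, silence out
  zs <- enhance_markers(waveform(numeric(100), fs), waveform(numeric(100), fs), cfg)
  expect_identical(zs$samples, numeric(100))
})

test_that("onset extraction equals the naive per-sample oracle on clean fixtures", {
  cfg <- default_cfg
  fix1 <- burst_fixture(1000)
  got <- extract_onsets(fix1, cfg)
  expect_identical(got, oracle_onsets(fix1$samples, fix1$sample_rate, cfg))
  expect_length(got, 1)
  expect_gte(got, 999); expect_lte(got, 1002)

  fix2 <- burst_fixture(c(500, 1000, 1350))
  got2 <- extract_onsets(fix2, cfg)
  expect_identical(got2, oracle_onsets(fix2$samples, fix2$sample_rate, cfg))
  expect_length(got2, 3)
  expect_equal(diff(got2), c(500, 350), tolerance = 2)
})

test_that("onset extraction merges echoes within the refractory period", {
  cfg <- default_cfg
  fix <- burst_fixture(c(1000, 1005))   # click + echo 5 ms later
  got <- extract_onsets(fix, cfg)
  expect_length(got, 1)
  expect_lt(abs(got - 1000), 2)
})

test_that("onset extraction is shift-equivariant and amplitude-invariant", {
  cfg <- default_cfg
  fix <- burst_fixture(c(600, 1400))
  base <- extract_onsets(fix, cfg)
  fs <- fix$sample_rate
  for (delta in c(100, 730)) {
    shifted <- waveform(c(numeric(round(delta / 1000 * fs)), fix$samples), fs)
    expect_equal(extract_onsets(shifted, cfg), base + delta, tolerance = 0.05)
  }
  for (s in c(0.1, 0.25, 1)) {
    scaled <- waveform(fix$samples * s, fs)
    expect_equal(extract_onsets(scaled, cfg), base, tolerance = 1)
  }
  expect_length(extract_onsets(waveform(numeric(1000), fs), cfg), 0)
})

test_that("markers are detected with small timing error and survive a recording shift", {
  cfg <- default_cfg
  tr <- simulated_trial(ioi = 500, n_clicks = 6, seed = 31, start_delay = 250)
  ch <- split_channels(tr$sim$recording, cfg)
  mk <- detect_markers(ch, tr$prep, cfg)
  expect_equal(mk$n_detected, 6)
  expect_lte(mk$marker_error_ms, 2)
  expect_lt(max(abs(mk$onsets - tr$sim$ground_truth$marker_times)), 2)

  # prepending silence shifts detections, not the interval error
  fs <- cfg$sample_rate
  shifted <- waveform(c(numeric(round(0.3 * fs)), tr$sim$recording$samples), fs)
  mk2 <- detect_markers(shifted, tr$prep, cfg)
  expect_equal(mk2$onsets, mk$onsets + 300, tolerance = 0.5)
  expect_equal(mk2$marker_error_ms, mk$marker_error_ms, tolerance = 0.5)
})

test_that("suppressed markers raise a quality error, as with noise-cancelling hardware", {
  cfg <- default_cfg
  tr <- simulated_trial(ioi = 500, n_clicks = 6, seed = 37,
                        device = virtual_device(start_delay = 250, snr_db = 25,
                                                marker_attenuation = 0,
                                                seed = 38))
  expect_error(detect_markers(tr$sim$recording, tr$prep, cfg),
               "markers undetected", class = "tapsync_quality_error")
})
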