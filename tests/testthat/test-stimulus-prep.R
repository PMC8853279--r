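test_that("marker sound has the right length, determinism, and in-band energy", {
  cfg <- default_cfg
  m <- generate_marker_sound(cfg, seed = 5)
  expect_equal(length(m$samples), round(cfg$marker_duration / 1000 * cfg$sample_rate))
  expect_equal(max(abs(m$samples)), cfg$marker_amplitude, tolerance = 1e-12)

  # periodogram oracle: >= 95% of power inside the marker band
  frac <- band_energy_fraction(m$samples, cfg$sample_rate,
                               cfg$marker_band[1], cfg$marker_band[2])
  expect_gte(frac, 0.95)

  expect_identical(generate_marker_sound(cfg, seed = 5)$samples, m$samples)
  expect_false(identical(generate_marker_sound(cfg, seed = 6)$samples, m$samples))
})

test_that("stimulus filtering clears the stopband, keeps the passband, and adds no delay", {
  cfg <- default_cfg
  # passband: 1 kHz within 1 dB
  expect_lt(abs(tone_attenuation_db(1000, function(w) filter_stimulus(w, cfg))), 1)
  # stopband: 200 Hz down by >= 40 dB; stopband edge too
  expect_gte(tone_attenuation_db(200, function(w) filter_stimulus(w, cfg)), 40)
  expect_gte(tone_attenuation_db(500, function(w) filter_stimulus(w, cfg)), 40)
  # silence maps to silence
  z <- filter_stimulus(waveform(numeric(1000), cfg$sample_rate), cfg)
  expect_lt(max(abs(z$samples)), 1e-12)
  # zero phase: a high-frequency click's energy centroid does not move
  fs <- cfg$sample_rate
  click <- make_isochronous_stimulus(500, 1, cfg)$waveform
  pad <- waveform(c(numeric(fs %/% 2), click$samples, numeric(fs %/% 2)), fs)
  filt <- filter_stimulus(pad, cfg)
  cent <- function(x) sum(seq_along(x) * x^2) / sum(x^2)
  expect_lt(abs(cent(filt$samples) - cent(pad$samples)) / fs * 1000, 0.5)
})

test_that("prepared stimulus has the documented layout and shifted onsets", {
  cfg <- default_cfg
  stim <- make_isochronous_stimulus(500, 3, cfg)
  prep <- prepare_stimulus(stim$waveform, stim$onsets, cfg, seed = 2)

  k <- cfg$markers_per_block
  expect_length(prep$marker_onsets, 2 * k)
  block_ms <- k * cfg$marker_duration + (k - 1) * cfg$marker_gap
  shift <- block_ms + cfg$stim_padding
  expect_equal(prep$stim_onsets, stim$onsets + shift, tolerance = 0.05)

  # total duration = 2 blocks + 2 paddings + stimulus
  expect_equal(duration_ms(prep$waveform),
               2 * block_ms + 2 * cfg$stim_padding + duration_ms(stim$waveform),
               tolerance = 0.1)
  # begin-block markers at 0, d+g, 2(d+g); end block mirrors
  step <- cfg$marker_duration + cfg$marker_gap
  expect_equal(prep$marker_onsets[1:k], (0:(k - 1)) * step, tolerance = 0.05)
  # every stimulus onset lies strictly between the blocks
  expect_true(all(prep$stim_onsets > prep$marker_onsets[k] + cfg$marker_duration))
  expect_true(all(prep$stim_onsets < prep$marker_onsets[k + 1]))

  # onsets outside the stimulus are rejected, listing the offender
  expect_error(prepare_stimulus(stim$waveform, c(0, 99999), cfg),
               "99999", class = "tapsync_input_error")
})

test_that("preparation is onset-shift equivariant", {
  cfg <- default_cfg
  stim <- make_isochronous_stimulus(500, 3, cfg)
  fs <- cfg$sample_rate
  delta_ms <- 200
  delayed <- waveform(c(numeric(round(delta_ms / 1000 * fs)), stim$waveform$samples), fs)
  p1 <- prepare_stimulus(stim$waveform, stim$onsets, cfg, seed = 3)
  p2 <- prepare_stimulus(delayed, stim$onsets + delta_ms, cfg, seed = 3)
  expect_equal(p2$stim_onsets, p1$stim_onsets + delta_ms, tolerance = 0.05)
  expect_equal(p2$marker_onsets[1:3], p1$marker_onsets[1:3], tolerance = 1e-9)
})

test_that("a lone marker block is recovered by its own extraction chain", {
  cfg <- default_cfg
  stim <- make_isochronous_stimulus(500, 2, cfg)
  prep <- prepare_stimulus(stim$waveform, stim$onsets, cfg, seed = 4)
  fs <- cfg$sample_rate
  k <- cfg$markers_per_block
  block_ms <- k * cfg$marker_duration + (k - 1) * cfg$marker_gap
  block <- waveform(prep$waveform$samples[seq_len(round((block_ms + 100) / 1000 * fs))], fs)
  channels <- list(
    marker = bandpass(block, cfg$marker_band[1], cfg$marker_band[2]),
    test = bandpass(block, cfg$test_band[1], cfg$test_band[2]))
  enhanced <- enhance_markers(channels$marker, channels$test, cfg)
  got <- extract_onsets(enhanced, cfg)
  expect_length(got, k)
  expect_lt(max(abs(got - prep$marker_onsets[1:k])), 2)
})

test_that("the filtered stimulus leaks almost nothing into the tap channel", {
  cfg <- default_cfg
  stim <- make_isochronous_stimulus(500, 10, cfg)
  prep <- prepare_stimulus(stim$waveform, stim$onsets, cfg, seed = 5)
  fs <- cfg$sample_rate
  # interior segment: stimulus only, no markers
  i0 <- round((prep$stim_onsets[1]) / 1000 * fs)
  i1 <- round((prep$stim_onsets[10] + 100) / 1000 * fs)
  seg <- waveform(prep$waveform$samples[i0:i1], fs)
  tapped <- bandpass(seg, cfg$tap_band[1], cfg$tap_band[2])
  expect_lt(sqrt(mean(tapped$samples^2)), 0.01 * sqrt(mean(seg$samples^2)))
})

test_that("isochronous stimulus onsets are exactly the requested grid", {
  cfg <- default_cfg
  s <- make_isochronous_stimulus(500, 100, cfg)
  expect_length(s$onsets, 100)
  expect_equal(s$onsets[1], 0)
  expect_equal(max(s$onsets), 49500)
  expect_true(all(abs(diff(s$onsets) - 500) < 1e-12))
  expect_equal(make_isochronous_stimulus(300, 1, cfg)$onsets, 0)
  expect_error(make_isochronous_stimulus(-5, 10, cfg), class = "tapsync_input_error")
  expect_error(make_isochronous_stimulus(5, 10, cfg), "click",
               class = "tapsync_input_error")
})
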