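Package: tapsync
Title: Millisecond-Accurate Tap-Stimulus Asynchronies from Free-Field Audio
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Signal-processing pipeline for sensorimotor synchronization
    experiments that run on ordinary laptops. A band-limited auditory
    stimulus framed by loud narrow-band marker sounds is played through the
    speakers while the microphone records stimulus and finger taps in one
    mono channel; band-pass filtering separates tapping, marker and test
    channels, a relative-threshold extractor recovers onset times, and the
    first detected marker anchors the known stimulus timeline to the
    recording so tap-stimulus asynchronies can be measured to within a few
    milliseconds despite uncontrolled playback and recording latency.
    Includes tapping-performance statistics (mean/SD asynchrony, circular
    vector length, linear phase-correction model decomposition, lag-1
    autocorrelations), per-trial quality criteria, and a virtual
    participant/virtual device simulator that generates recordings with
    exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
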