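---
title: "Measuring tap–stimulus asynchronies from free-field recordings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring tap-stimulus asynchronies from free-field recordings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

A sensorimotor-synchronization (SMS) trial produces one asynchrony per
tap, `A_n = R_n − S_n`, where `R_n` is the tap onset and `S_n` the
stimulus onset, both in milliseconds. Human asynchronies have a mean of a
few tens of milliseconds (typically negative: anticipation) and an SD of
20–50 ms, so the measurement chain must be accurate to a couple of
milliseconds. On consumer hardware neither playback start nor input
time-stamps are controllable at that precision, but a single audio
recording is internally sample-accurate: once the sound card starts
recording, every event within the file is timed exactly relative to every
other. `tapsync` therefore measures nothing against the wall clock.
Everything is measured inside one mono free-field recording that captures
the played stimulus and the participant's tap sounds together, and the
only absolute anchor needed — where the known stimulus timeline sits in
the recording — is provided by marker sounds at known positions.

## Frequency-domain layout

Every audio element gets its own band:

| element   | band (Hz) | why |
|-----------|-----------|-----|
| tapping   | 80–500    | the spectrum of a fingertip striking a laptop chassis |
| stimulus  | above 500 | band-stop filtered out of 50–500 so it cannot mask taps |
| markers   | 200–340   | narrow, loud, low enough to survive cheap speakers |
| test      | 100–170   | one octave below the marker band; see below |

The stimulus filter is a zero-phase Butterworth high-pass (order 5,
cutoff at √2 × 500 ≈ 707 Hz, applied forward–backward twice): ≥ 40 dB of
attenuation at the 500 Hz stopband edge, < 1 dB of loss one octave above
it, and — because it is zero-phase — no onset displacement, so the
pre-registered stimulus onset list stays valid after filtering. Two
cascaded order-5 stages are used instead of one order-10 design because
the normalized cutoff (707 Hz at 44.1 kHz) is small enough to make high
single-stage orders numerically fragile.

The marker band and the tap band overlap deliberately — the marker must be
audible *and* recordable on weak hardware, which confines it to the low
hundreds of Hz. Two consequences shape the design:

* **Markers versus taps in the marker channel.** A tap deposits energy in
  the marker band too. The *test channel* disambiguates: sliding-window
  energies of the marker and test channels are compared as per-Hz
  densities, and the marker channel is multiplied by `boost_gain` (4)
  wherever the marker density exceeds `ratio_threshold` (2) times the
  test density. A narrow-band marker leaves the test band empty and is
  boosted; a broadband tap or background noise has similar density in
  both bands and is not. Densities rather than raw band energies matter
  here: the marker band is twice as wide as the test band, so raw
  energies of a spectrally flat sound would sit exactly at ratio 2.
* **Taps are only extracted between the marker blocks.** Within the
  window bounded by the two blocks the tap channel contains taps alone,
  so the relative threshold adapts to the taps themselves rather than to
  the much louder markers. The window margins are asymmetric: 50 ms after
  the beginning block (marker decay), 5 ms before the end block (only the
  short zero-phase pre-ring matters on that side) so that taps arriving
  late — e.g. anti-phase taps landing half an IOI after the last click —
  still count.

## Onset extraction

The extractor is deliberately simple and parameter-transparent: rectify,
smooth with a trailing moving average (`envelope_window`, 5 ms), threshold
at `onset_threshold_frac` (0.1) of the envelope maximum, and report the
first sample of each supra-threshold excursion; excursions starting within
`min_onset_gap` (100 ms) of the last reported onset are merged into it.
Two details matter for millisecond accuracy:

* **Trailing, not centered, smoothing.** A centered window advances the
  threshold crossing by up to half the window before the physical onset;
  a trailing window cannot, by construction, report energy before it
  arrives. The same choice is applied to the enhancement energies.
* **Attack-trimmed synthesis.** The synthesized marker and tap sounds are
  generated with headroom and then cut so that their first sample already
  carries ≥ 50% of peak amplitude. Band-limited sounds otherwise ramp up
  over one to two cycles, and a slow in-band attack delays the threshold
  crossing by exactly that ramp. With both choices the residual detection
  bias is ≈ +0.2 ms for markers and within about ±1.5 ms for taps.

One rule was added on top of the classic relative threshold: an excursion
only counts if its envelope peak exceeds `min_peak_floor_ratio` (4) times
the *median* envelope. Within the tap analysis window, a relative
threshold alone turns a stationary noise floor into spurious onsets (the
threshold ends up below the floor and every dip-and-rise crosses it),
which would make a participant who never taps look like a regular tapper
to the tap-count criterion. The median envelope estimates the floor
robustly because genuine taps occupy a tiny fraction of the window; clean
signals with silent backgrounds have median zero and are unaffected.

The enhancement energy window (`enhance_window`, 25 ms) is longer than the
envelope window because a 5 ms window is shorter than a single cycle of
the 100–170 Hz test band, which would make the marker/test density ratio
oscillate within each cycle.

## Marker layout, detection and alignment

A marker block is `markers_per_block` (3) sounds of `marker_duration`
(250 ms) separated by `marker_gap` (500 ms); one block precedes and one
follows the stimulus, with `stim_padding` (500 ms) of silence in between.
The marker sound itself is an equal mix of band-filtered white noise and a
pure tone at the geometric centre of the marker band (≈ 261 Hz), played at
`marker_amplitude` (0.95) of full scale. Each marker carries its own
timing; three per block give redundancy against transient masking, and
distinctive inter-marker intervals make the pattern identifiable.

Detection extracts candidate onsets from the enhanced marker channel and
matches them against the known inter-marker interval pattern: every
candidate is tried as the anchor, each predicted marker position accepts
the nearest candidate within `marker_match_tol` (50 ms), and the earliest
anchor explaining the most markers wins. This is robust to spurious
bursts before the trial and to individual missing markers. The trial's
`marker_error_ms` is the mean absolute deviation of the detected
inter-marker intervals from the known ones, anchored at the first
detected marker — a per-trial self-diagnosis of timing integrity.

Alignment is a single offset: `first detected marker − first known marker
onset`. Realigned stimulus onsets are the known (shifted) onsets plus
this offset; they are never re-extracted from audio, which is what makes
"virtual" onsets (beat positions in music, with no physical energy at the
beat) possible.

Tap–stimulus pairing is greedy nearest-neighbour within `match_window`
(by default `min(250 ms, half the median IOI)`, unambiguous both for slow
isochrony and for 250 ms click trains), each onset used at most once,
equidistant ties resolved to the earlier tap. Asynchronies are computed
for matched pairs only; unmatched stimulus onsets count as missed taps in
the detected-tap percentage.

## Failing criteria

A trial fails when (a) fewer than `min_markers_detected_frac` (1.0) of the
expected markers are found — incompatible hardware, muted speakers, noise
cancellation; (b) `marker_error_ms` exceeds `max_marker_error_ms` (10 ms)
— the recording cannot be trusted at millisecond scale; or (c) the
matched-tap ratio falls outside [`min_tap_ratio`, `max_tap_ratio`]
([0.5, 2.0]) — non-tappers or spurious tapping. Reasons are coded
(`markers_missing`, `marker_error`, `too_few_taps`, `too_many_taps`) so
that batch harnesses can distinguish hardware exclusions from behavioural
ones. All thresholds are configuration fields; the defaults are the
package's own choices.

## Tapping statistics

Beyond mean and sample SD of asynchrony (n−1 denominator):

* **Vector length.** Each asynchrony maps to a phase `2π A_n / IOI_n`
  using the IOI local to its stimulus onset (successive differences of
  the realigned onsets; the last onset reuses the previous IOI, which
  extends cleanly to variable-IOI stimuli such as music). `R` is the
  modulus of the mean unit phasor: 1 for perfectly locked tapping, 0 for
  uniform phase.
* **Linear phase correction.** Centred asynchronies are modelled as
  `A_{n+1} = (1−α) A_n + T_n + M_{n+1} − M_n` with timekeeper noise
  `T ~ N(0, σ_T²)` and motor noise `M ~ N(0, σ_M²)`. The stationary
  autocovariances identify all three parameters in closed form
  (`β = γ(2)/γ(1)`, `α = 1−β`, `σ_M² = βγ(0) − γ(1)`,
  `σ_T² = (1−β²)γ(0) − 2(1−β)σ_M²`). Method-of-moments was chosen because
  it is deterministic, closed-form, and directly verifiable by simulation
  against the package's own generative tapper; a bounded
  generalized-least-squares estimator could be slotted in behind the same
  interface. Negative variance estimates are clipped to zero and flagged;
  fits from fewer than 30 taps are flagged invalid (the moment estimates
  are then too noisy to interpret — α can stray outside (0, 2)); a
  near-zero γ(1) (no serial dependence, the α → 1, σ_M → 0 corner) makes
  β unidentifiable and is flagged rather than reported.
* **Lag-1 autocorrelations** of the asynchronies and of the inter-tap
  intervals, classical alternative indices of error correction (i.i.d.
  timing jitter drives the ITI lag-1 value to −1/2).

Participant-level scores average per-trial metrics over passing trials
(mean of per-trial SDs, not pooled variance — the per-trial statistic is
the behaviourally meaningful unit here).

## The simulator: what it does and does not emulate

The virtual participant generates asynchronies from the same linear
phase-correction model the statistics estimate (initialized at the
stationary distribution), with a constant mean asynchrony (default
−30 ms, anticipation), defaults σ_T = 15 ms, σ_M = 8 ms, α = 0.5 —
an asynchrony SD around 25 ms, mid-range for isochronous tapping — and
independent tap omissions with `miss_prob`. The virtual device prepends
`start_delay` of silence (the uncontrollable sound-card/OS latency),
scales the marker segments by `marker_attenuation` (noise-cancellation
stand-in), mixes tap sounds at `tap_gain` (0.3, a realistic level well
below the near-full-scale markers) and adds stationary white Gaussian
noise at `snr_db`; samples are hard-limited to [−1, 1] with the clipped
fraction reported.

What the simulator deliberately does **not** model: room reverberation,
microphone and speaker transfer functions, non-stationary background
noise (speech, music), clock drift between playback and recording, and
mechanical key-travel variability of real fingers. Passing the simulated
validation therefore demonstrates that the *signal-processing pipeline*
is unbiased and robust to start latency, gain, noise and marker
attenuation — it does not certify behaviour on any specific laptop model,
which can only be established against independent calibration hardware.

Determinism is strict: the same participant seed, device seed and
configuration produce a bit-identical recording, and all seeded functions
restore the caller's RNG state.

## Validation studies and problem sizes

The package validates itself with two simulation studies (also recomputed
by `scripts/acceptance.R`):

* **Timing accuracy:** 50 trials of 20 clicks at 500 ms IOI, start delays
  drawn uniformly from 0–1000 ms, 25 dB SNR. Recovered marker, realigned
  stimulus and detected tap times are pooled against ground truth; the
  mean absolute error is ~0.5 ms (the design target is ≤ 2 ms).
* **Three-part suite:** (1) 4 trials × 100 clicks at IOIs
  250/500/750/1000 ms with no tapping — all 400 realigned stimulus onsets
  within ±5 ms of truth; (2) the same with a synchronized virtual tapper —
  all 400 taps recovered; (3) 2 trials × 20 clicks (500/1000 ms IOI) with
  anti-phase taps (`click + IOI/2`, the configuration in which stimulus
  and taps are maximally interleaved in one recording) — all 40 taps
  recovered.

These sizes keep a full run in the minutes range on one CPU while giving
count-exact targets; the trial layout for the timing study (20 clicks at
500 ms) is the package's choice.

## Known limitations

* The free-field approach requires the markers to be recordable: strong
  noise cancellation that fully suppresses them fails the trial by
  design (`markers_missing`) rather than degrading silently. Partial
  attenuation degrades gracefully — in simulation, markers attenuated to
  1% of amplitude are still detected, at slightly worse timing error.
* Onset timing of band-limited sounds has an intrinsic floor set by the
  channel bandwidth; tap-onset bias varies within roughly ±1.5 ms with
  the noise realization. Applications needing sub-millisecond absolute
  tap timing need wider tap bands or calibrated hardware.
* Stimulus filtering removes content below ~700 Hz, which audibly thins
  complex stimuli such as music; the trade-off buys a clean tap channel.
* The analysis assumes one participant, one tapping mode, and taps
  sparser than `min_onset_gap` (100 ms, i.e. < 10 taps/s).
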