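# tapsync

Millisecond-accurate tap–stimulus asynchronies from a single free-field
audio recording.

## The problem

Sensorimotor synchronization (SMS) experiments ask a participant to tap a
finger in time with a metronome or a musical beat, and live or die by one
number per tap: the **asynchrony** `A_n = R_n − S_n` between the tap onset
`R_n` and its stimulus onset `S_n`, typically a few tens of milliseconds
and negative (people anticipate the beat). Measuring `A_n` outside the
laboratory is hard: consumer playback and recording chains add tens of
milliseconds of latency and jitter that swamp the signal.

`tapsync` implements the free-field recording solution for ordinary
laptops. The insight is that while the *start* of a recording is at the
mercy of the sound card and operating system, every event *within* one
recording is sample-accurate relative to every other. So:

1. **Stimulus preparation** — the stimulus is band-stop filtered out of
   the tapping frequency range (50–500 Hz by default) and framed by blocks
   of loud, narrow-band (200–340 Hz) **marker sounds** at known positions;
   the stimulus onset list is shifted onto this new timeline.
2. **Recording** — stimulus plays through the speakers; the microphone
   records stimulus and finger taps in one mono channel. (This package
   simulates this step; it does not capture audio.)
3. **Onset extraction** — zero-phase band-pass filters split the recording
   into tapping (80–500 Hz), marker (200–340 Hz) and test (100–170 Hz)
   channels. The marker channel is boosted wherever its energy density
   beats the test channel (markers are narrow-band; taps are broadband, so
   only markers are boosted). A relative-threshold envelope detector
   extracts onset times.
4. **Onset alignment** — the first detected marker anchors the known
   stimulus timeline onto the recording timeline. Stimulus onsets are
   *never* re-extracted from audio, so "virtual" onsets (music beats) work
   too. The remaining markers quantify the trial's timing error.
5. **Performance analysis** — taps are paired with stimulus onsets,
   asynchronies computed, per-trial failing criteria applied (markers
   found, marker timing error, tap-count ratio), and tapping statistics
   reported: mean/SD asynchrony, circular mean resultant vector length,
   the Vorberg–Wing linear phase-correction decomposition
   `A_{n+1} = (1−α) A_n + T_n + M_{n+1} − M_n` (error-correction gain α,
   timekeeper noise σ_T, motor noise σ_M, estimated from the lag-0/1/2
   autocovariances), and lag-1 autocorrelations of asynchronies and
   inter-tap intervals.

A **virtual participant** (a generative phase-correction tapper) and a
**virtual device** (start delay, background noise, marker attenuation,
i.e. noise cancellation) let the whole pipeline be exercised and validated
with exact ground truth and no human data.

## Worked example

Simulate a trial — 10 metronome clicks at 500 ms IOI, an anticipating
virtual tapper, a device that starts recording 270 ms late and adds noise
at 25 dB SNR — then analyze the resulting mono recording:

```r
library(tapsync)
cfg <- tapsync_config()

stim <- make_isochronous_stimulus(ioi_ms = 500, n_clicks = 10, config = cfg)
prep <- prepare_stimulus(stim$waveform, stim$onsets, cfg, seed = 1)

taps  <- simulate_taps(prep$stim_onsets, virtual_participant(mean_async = -30, seed = 1))
trial <- render_recording(prep, taps$tap_times,
                          virtual_device(start_delay = 270, snr_db = 25, seed = 2), cfg)

analysis <- analyze_recording(trial$recording, prep, cfg)
print(analysis)
#> trial PASSED
#>   markers: 6/6 detected, timing error 0.06 ms
#>   taps: 10 matched of 10 stimulus onsets (100%)
#> tapping metrics over 10 matched taps
#>   asynchrony: mean -23.21 ms, SD 11.43 ms, vector length 0.991
#>   lag-1 autocorrelation: asynchrony 0.29, ITI 0.17
```

All 6 markers were found despite the unknown 270 ms recording delay, the
trial's internal timing error is 0.06 ms, and every tap was recovered. The
recovered asynchronies sit within ~0.3 ms of the simulator's ground truth:

```r
round(taps$true_asynchronies, 1)
#> -14.6 -39.8 -44.9 -23.3 -12.1 -15.9 -27.6 -22.4 -17.0 -12.2
round(analysis$aligned$asynchronies, 1)
#> -14.9 -40.0 -45.1 -23.5 -12.3 -16.1 -27.8 -22.7 -17.2 -12.5
```

(The phase-correction decomposition is reported for series of 30+ taps;
10 taps is too short for stable moment estimates.)

A command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "tapsync", package = "tapsync"))')
Rscript $CLI simulate --ioi 500 --clicks 8 --seed 3 --out rec.wav --meta prep.json
Rscript $CLI analyze  --recording rec.wav --meta prep.json --out trial.json --csv taps.csv
```

`analyze` exits 0 on a passing trial, 2 when the trial fails the quality
criteria (diagnostics are still written), 1 on usage errors.

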