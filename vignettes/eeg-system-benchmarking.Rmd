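---
title: "Benchmarking EEG systems with an auditory oddball task: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking EEG systems with an auditory oddball task: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mobile EEG systems -- wet or dry electrodes, wireless amplifiers -- are
marketed for recording brain activity during whole-body motion, but there is
no agreed way to quantify how much signal quality a given system loses when
the subject walks. `eegbench` implements a benchmark built around the
auditory P300 oddball task: the same subject performs the task seated and
walking, and a fixed metric suite quantifies the damage. The package covers
the full path from continuous multi-channel data to test-retest reliability,
plus a synthetic session generator so that every stage is testable without
access to recorded data.

## The benchmark pipeline

1. **Conditioning.** Continuous data are zero-phase high-pass filtered at
   1 Hz (4th-order Butterworth, forward-backward) and notch filtered at the
   mains frequency (biquad, 2 Hz width, first harmonic included). Zero-phase
   application matters: a causal filter would delay the P300 peak.
   Channels marked bad are replaced by an inverse-distance-weighted (power 2)
   average of the good channels on unit-sphere 10-20 positions. With only
   12 electrodes, spherical-spline interpolation is ill-conditioned, so
   distance weighting is used; the weighting function is isolated and
   swappable.
2. **Montage.** Analysis runs on the 12-channel subset common to the
   benchmarked systems: Fpz, F3, Fz, F4, C3, Cz, C4, P3, Pz, P4, O1, O2.
   Label matching is case-insensitive because vendor capitalizations differ.
3. **Epoching.** Trials are cut from -0.3 s to 0.8 s around each stimulus
   onset (half-open in samples; the onset sample belongs to the
   post-stimulus side; at 500 Hz this yields 550 samples with the onset at
   0-based index 150). Epoching is pure slicing -- bit-exact.
4. **Behavioral rejection.** Non-targets followed by a button press (false
   positives) and targets without a press (false negatives) are dropped. A
   press is attributed to an event when it falls within 1.4 s of its onset;
   the protocol's minimum stimulus onset asynchrony is 1.82 s, so
   attribution is unambiguous. The 1.4 s value is configuration, not ground
   truth.
5. **Amplitude rejection.** The per-trial statistic is the sliding-window
   peak-to-peak amplitude: 200 ms windows advanced by 100 ms (i.e. 100 ms
   overlap), range within window, maximized over windows and channels. An
   epoch is rejected when *any* montage channel exceeds the threshold,
   matching common ERP-toolbox flag semantics. Partial tail windows are
   evaluated (conservative). The canonical threshold is 75 uV; sweeps run
   75-400 uV in 25 uV steps, and rejection-rate curves are non-increasing in
   the threshold by construction.
6. **Matched-count rejection.** Comparing seated against walking is only
   fair if both conditions keep the same trial count, so extra trials are
   removed from the less-rejected condition -- highest peak-to-peak first,
   later index first on ties (deterministic) -- until rejected counts match.

## The metric suite

* **PSN** (pre-stimulus noise): RMS of each trial over -300 to 0 ms, per
  channel, averaged over trials. Units uV.
* **Band power**: segment-averaged periodogram per epoch (128-sample Hamming
  segments zero-padded to a 256-point FFT, non-overlapping -- the EEGLAB
  `spectopo` convention), averaged over epochs then channels; band power is
  the mean density over bins in each half-open band. Default bands: delta
  1-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-80 Hz. Note the
  resolution implied by 128 samples at 500 Hz is ~4 Hz: a pure 10 Hz tone
  leaks measurably into theta with these defaults (the test suite checks
  concentration with a longer window). **Ratio W/S** is the per-band
  walking/seated ratio on *linear* power -- a ratio of decibel values would
  not be a power ratio.
* **SNR**: per channel, the signed maximum of the averaged target ERP within
  300-500 ms divided by the channel's trial-averaged PSN of the same target
  epochs. The signed maximum is used because the P300 is by definition a
  positive deflection.
* **CV_ERP**: per trial, the coefficient of variation (sample sd / mean) of
  the samples within 300-500 ms, averaged over trials. The defining ratio is
  taken with the standard deviation; a variance variant exists behind
  `use_variance = TRUE` because the two readings circulate. Trials whose
  window mean is exactly zero are excluded as undefined and counted.
* **Scalar-product similarity**: ERPs from two conditions are mean-centered,
  unit-normalized and dotted, which is exactly Pearson r over time; values
  are averaged in the Fisher-z domain (`tanh(mean(atanh(r)))`). An
  uncentered variant (`center = FALSE`, cosine similarity) is available.
* **Reliability**: test-retest agreement uses the single-measure,
  absolute-agreement ICC from the two-way model (McGraw-Wong ICC(A,1)),
  which penalizes systematic session shifts; the consistency form is a
  flag away. Classification: poor < 0.4, good > 0.7, both boundaries fall
  in "moderate" (the bands are stated as strict inequalities). Negative
  estimates are reported as computed. Cohen's d uses the pooled sd with
  n1 + n2 - 2 degrees of freedom.

## The synthetic session generator

`session_design()` defaults encode the benchmark protocol: 4 blocks of
160 trials, target probability 0.25, 400 ms stimuli, 1420-1580 ms ISI,
500 Hz. Targets are assigned per block by exact count (40 of 160), not
i.i.d. draws, so the 0.25 fraction is exact and tests are deterministic --
the standard oddball implementation.

`signal_model()` controls what `simulate_session()` injects, all in uV:

* 1/f background (spectrally shaped seeded white noise, exponent 1, scaled
  to `noise_sd` in the time domain). Default 9 uV, a plausible broadband
  background for a clean wet-electrode recording.
* 10 Hz alpha sinusoid (default 4 uV, random phase per channel).
* P300: Gaussian bump (default peak 10 uV, latency 400 ms, sd 55 ms) added
  to target trials with a central-parietal topography (Pz 1.0, Cz 0.9,
  frontal 0.5, occipital 0.4). The peak value is exact at the latency
  sample, which the noiseless-reconstruction test exploits.
* Gait artifact (walking only): 1.2 Hz fundamental -- the typical treadmill
  stride rate -- plus two harmonics at half and quarter amplitude, random
  phases, amplitude growing toward the occiput (cable/strap mechanics).
* Optional stereotyped blinks (frontal-weighted biphasic 400 ms transients),
  disabled by default: the pipeline deliberately has no ICA stage and
  expects blink-cleaned input.
* Button presses: targets are answered with probability 0.98 at a 300-700 ms
  reaction time; non-targets draw spurious presses at 1/10 of the lapse
  rate.

### Fixture calibration

The dry-electrode study data were never deposited, so the `dry_*` presets
are calibrated to reproduce *qualitative* outcomes, not the study's exact
distributions: `dry_walking` (noise 22 uV, gait 120 uV) loses essentially
every epoch at the 75 uV threshold after 1 Hz high-pass filtering, while
`dry_seated` (noise 17 uV) is degraded but survivable (~50-70% rejection
depending on seed). The wet presets (noise 16 uV; walking adds a 10 uV gait
component) sit in the ~20-50% range. The rejection rate is very steep in the
background amplitude -- a property of taking the max over 12 channels and
~10 windows -- so these preset amplitudes were chosen once, against the
pipeline, and are part of the stated test world.

### What a green test does not establish

The generator emulates stationary Gaussian 1/f noise, a deterministic
evoked bump, and phase-random sinusoidal artifacts. Real mobile EEG adds
non-stationary EMG, electrode micro-movements, sweat drift, telemetry
dropouts and genuine single-trial ERP variability. Green tests therefore
establish that the *estimators* are correct on their stated models, not
that any particular hardware would earn these numbers.

## Numerical choices

* Filters are designed from first principles (no filter-design dependency
  exists in the target environment): Butterworth via bilinear transform of
  the analog prototype (coefficients agree with reference implementations to
  ~1e-15), notch as a constrained biquad. Zero-phase application uses
  odd-reflection padding plus constant-history initial conditions; the
  high-pass pads by two time constants of the cutoff so edge transients stay
  out of the analysis window.
* EDF/BDF files are written with 1 s records; the true sample count is
  stored in a reserved header field so padding is trimmed on read.
  Round-trips are exact to one quantization step of the 16/24-bit encoding.
* FFT lengths for noise synthesis are padded to 2-3-5-smooth numbers
  (R's mixed-radix FFT is quadratic in the largest prime factor of the
  length, and session lengths are essentially arbitrary integers).
* Fisher averaging clips |r| = 1 to 1 - 1e-7 with a warning; correlations of
  identical synthetic sessions do reach exactly 1.
* Ties in matched-count rejection drop the later trial first, making reports
  byte-reproducible.

## Open design points resolved here

* The displayed definition of the single-trial CV circulates in both an
  "sd/mean" and a "var/mean" form; the prose definition (sd) is the default,
  the variance form is a switch.
* Theta/alpha band edges circulate as 5-8/9-13 and 4-8/8-13; the latter
  (contiguous) reading is the default and `band_set()` reproduces either.
* The notch frequency (60 Hz) and the response-attribution window (1.4 s)
  are not protocol constants; both are configuration keys.
* Whether amplitude rejection ran on all recorded channels or the 12-channel
  subset is unspecified in the source protocol; this package defines it on
  the benchmark montage.
* ICC is computed as the single-measure form; average-measure ICC would be
  systematically higher and is intentionally not the default.

## Limitations

No ICA or artifact-component removal is included (out of scope by design);
group-level inference (ANOVA, post-hoc tests) is not implemented -- the
package stops at per-session metric tables, effect sizes and ICC; plotting
is left to the caller (all outputs are long-format data frames).
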