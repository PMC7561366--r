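---
title: "Methods: cry acoustics, gaze scoring, and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cry acoustics, gaze scoring, and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crygaze)
```

This vignette documents the models and procedures the package implements,
the parameters that matter and their defaults, what the synthetic
generators do and do not emulate, and the design choices made where the
methodology left room for them.

## The acoustic arm

### Signal model

A cry bout alternates expiratory vocalizations (the analyzed unit) with
inspiratory sounds and pauses; recordings made in clinical settings also
contain extraneous sounds ("residual"). An expiratory cry is quasi-periodic
with a fundamental frequency (F0) typically between 200 and 700 Hz and a
rich harmonic stack. The participant-level features are

* **F0** — the mean over phases of the per-phase mean frame-level F0 (Hz);
* **F0var** — the mean over phases of the per-phase frame-level F0 sample
  standard deviation (Hz), a within-phase pitch-instability measure.

### Segmentation

The segmenter (`segment_recording()`) is a frame-level classifier followed
by label smoothing — a deliberately transparent design whose contract is
the extraction of expiratory regions:

1. **Activity.** A frame (25 ms / 12.5-ms hop) is active when its energy
   exceeds both an absolute floor (−65 dBFS) and the recording's adaptive
   noise floor (5th percentile of frame energy) by 8 dB. Pure silence
   therefore yields no segments.
2. **Harmonicity.** Active frames whose cumulative-mean-normalized
   difference function dips to ≤ 0.45 inside the F0 lag band are
   expiratory. The 0.45 gate is looser than the 0.3 analysis threshold on
   purpose: segmentation must tolerate frames that the per-frame filter
   will later discard.
3. **Spectral slope.** Remaining active frames are split by the OLS slope
   of the dB periodogram against frequency over 0.3–10 kHz:
   high-frequency-emphasized frames (> 1 dB/kHz) are inspiratory (whistly
   inhalation), the rest residual. Broadband noise has a near-zero slope
   and lands in residual.
4. **Smoothing.** Labels pass a 5-frame mode filter; each frame then owns
   the hop-length tile around its center (so segments never overlap), and
   segments shorter than 100 ms are dropped.

On the synthetic material the recovered expiratory boundaries sit within
one or two hops (≤ 25 ms) of the generator truth; the tests require
± 50 ms. An HMM smoother over the same three features would be a drop-in
alternative; the mode filter keeps the behavior fully inspectable.

### Pitch estimation

`estimate_pitch_frame()` implements YIN: the frame difference function with
a fixed integration window (frame length minus the maximum lag), its
cumulative-mean-normalized form d′(τ) with d′(0) = 1, an absolute-threshold
first-dip search restricted to the 200–700 Hz lag band (falling back to the
in-band global minimum when nothing passes), and parabolic refinement of
the selected lag. The aperiodicity Ap of a frame is d′ at the chosen
(refined) lag — the standard reading of the normalized difference as the
aperiodic-to-periodic power ratio. The estimate is reported only when
Ap ≤ 0.3; a zero-variance frame reports Ap = ∞ and no estimate. Restricting
the search band and thresholding Ap are what keep octave errors out: on
clean harmonic sweeps across 250–650 Hz the estimate is never within 2 % of
half or double the true F0 (a property the test suite checks).

### Filtering and aggregation

Per phase, frames with Ap > 0.3 are discarded and the phase mean/SD are
computed over the survivors (sample SD, n − 1). Phase-level filters, with
strict comparisons as stated: duration > 500 ms, inharmonic-frame fraction
≤ 70 % (evaluated against all frames of the segmented phase). The first
five filtered survivors in temporal order enter the participant features —
filtering first and then capping at five maximizes usable data and matches
the "available scorable phases" convention; at least three are required,
otherwise the recording is flagged unusable with the survivor count. The
per-phase SD is computed after the Ap-based frame discard: the discarded
frames are the ones the tracker itself marks unreliable, so including them
would conflate tracking failure with pitch instability.

## The attention arm

Gaze is scored in degrees of visual angle, screen-centered, at a nominal
300 Hz. Two saccade-time readings coexist by design: the orienting SRT is
the time of the *first* sample inside the target AOI after target onset
(the latency of arrival), while the disengagement saccade time x is the
time of the *last* sample inside the central AOI before the first lateral
sample (the moment of leaving). Each matches the convention of its task.

Validity rules, in the order tested:

* **Fixation.** Strictly more than 70 % of *valid* samples between trial
  start and the shift (or the window end when no shift occurred) must lie
  in the central AOI. Computing the fraction over valid samples rather than
  wall-clock time avoids double-penalizing gaps, which have their own rule.
  The interval starts at the central-stimulus onset (trial time 0).
* **Gaps.** Any missing/invalid run longer than 200 ms in the analysis
  period invalidates the trial; run length is measured between the
  timestamps bracketing the run, so edge gaps are bounded correctly.
* **Shift in gap.** Any invalid sample strictly between the last-central
  and first-lateral samples makes the transition time unverifiable.
* **Off-screen.** A valid excursion beyond the calibrated screen rectangle
  (default ± 13.5° × ± 10.5°, configurable) before the lateral AOI is
  reached excludes the trial.
* **Window.** Saccade times outside 150–1000 ms after lateral onset are
  excluded (`too_early` / `too_late`).

The dwell-time index maps x linearly onto [0, 1]:
`1 − (window_end − x) / norm_range`, i.e. `1 − (1000 − x)/850` at the
defaults, with no-shift trials entered at x = 1000. Per condition it is the
mean over scorable trials (≥ 3 required); the participant index is the
unweighted mean of the three condition indices — conditions, not trials,
are the unit, so unequal trial counts cannot tilt the score. The window
parameters are configuration, not constants, so task variants with a
different lateral-availability period can be scored by overriding
`scoring_config()`; the 1000/850 window is the default normalization.

## Cohort statistics

* t-tests are Student's pooled-variance tests (df = n₁ + n₂ − 2) — the
  convention consistent with the degrees of freedom such studies print —
  with two-tailed p.
* Cohen's d uses the total-sample pooled SD (denominator n₁ + n₂) by
  default, with `d_denominator = "df"` as the switch to the n₁ + n₂ − 2
  convention. `summary_t_test()` applies identical formulas to published
  group summaries, and the suite verifies it coincides with the raw-data
  route to 10⁻¹⁰.
* Pearson r uses the product-moment formula with p from
  t = r·√((n−2)/(1−r²)); missing outcomes are dropped pairwise per
  analysis, so per-cell n's differ. α = 0.05, no multiple-comparison
  correction. The KS normality check (against a normal with the sample's
  own moments) is reported for diagnostics and gates nothing.
* The correlation report crosses cohort × subset (all; beginning-of-bout
  within the first cohort; SSRI-unexposed within the second) × feature
  (F0, F0var) × outcome (orienting, disengagement), carrying per-cell n and
  marking cells with < 3 complete pairs as not computable.

## The synthetic generators

`synth_cry()` uses harmonic additive synthesis — a sum of harmonics with
1/k amplitude decay following an instantaneous-F0 contour, raised-cosine
edge ramps, optional high-pass inspiratory noise bursts, and white noise at
a configurable SNR. The within-phase contour is base + A·sin(2πft) with
A = √2 · (target SD), so the contour's long-run SD equals the target
exactly and F0var recovery is quantitative; truth tables record the contour
statistics on the analysis frame grid. A physiological vocal-fold model is
unnecessary: the analysis consumes only F0 structure. What the generator
does **not** emulate — formants and timbre, amplitude-modulated phonation
(fry/subharmonics), reverberant rooms, competing speech — means passing
tests demonstrate correctness of the measurement chain, not robustness to
every clinical recording condition.

`synth_gaze()` emulates fixation scatter (Gaussian, default 0.8°),
step-like saccades at truncated-normal latencies, no-shift trials, and
injected missing-data runs. It does not model saccade kinematics (velocity
profiles, undershoot), smooth pursuit, or blinking dynamics beyond the
validity flag — adequate for testing a scorer that consumes raw positions
and validity.

`synth_cohort()` draws latent multivariate-normal vectors with a prescribed
correlation matrix and normal marginals at the published descriptive
parameters, clipping the dwell index to [0, 1]. Defaults keep the dwell
mean ≥ 3 SDs from the bounds, so clipping bias is negligible except under
extreme parameterizations. Cohort sizes default to 54 and 59: the printed
total (113) is fixed by the degrees of freedom of the published F0
comparison, and the split allocates the remainder after the documented cry
exclusions; it is a package choice where no split was published.

## Numerical choices and degenerate inputs

* Trailing partial frames are discarded, never zero-padded (no edge bias).
* Stereo recordings are mixed to mono by channel mean before analysis.
* Parabolic lag refinement is clamped to ± 1 lag and skipped at band edges
  or non-convex triples; refined F0 is clipped into the search band.
* Zero-variance frames: Ap = ∞, no F0. Zero surviving frames: phase
  statistics NA, phase unusable. A phase with a single retained frame has
  SD 0 by convention (it contributes no spread evidence).
* Degenerate t-test input (zero pooled variance, unequal means) and
  zero-variance correlation input raise errors rather than returning
  ±∞/NaN.
* Generators restore the caller's RNG state; all randomness is governed by
  the spec seed, and equal seeds give bit-identical output.

## Problem sizes

The shipped analysis scripts and tests run entirely on simulated material:
six full measurement-arm participants (five-phase bouts, ~6 s of audio
each; 80-trial gaze sessions), cohort tables of 54 + 59 participants at the
published descriptive parameters, a 10 000-participant cohort for
correlation recovery, and 500 null replicates at n = 50 for the type-I
error check. These sizes make every documented property measurable with
comfortable margins while keeping a full run in well under a minute for the
statistics arm and a few seconds per recording for the acoustic arm.

## Known limitations

* The segmenter is a documented stand-in with the same contract as trained
  in-house segmenters used in this literature, not a reimplementation of
  any of them; on heavily corrupted clinical audio a trained model will
  out-perform it.
* Aperiodicity is a YIN-internal quantity; its 0.3 cut is not comparable
  across different pitch trackers.
* The dwell index is linear in saccade time by construction; it carries no
  information about gaze behavior after the shift.
* Pairwise deletion assumes outcomes are missing unrelated to their values;
  the package reports per-cell n so users can judge attrition.
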