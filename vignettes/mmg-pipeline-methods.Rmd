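---
title: "Analysing pelvic floor magnetomyography: methods and design choices"
author: "mmglam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing pelvic floor magnetomyography: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmglam)
```

## The measurement problem

Magnetomyography (MMG) passively records the magnetic fields generated by
muscle depolarisation. Recorded over the pelvis with a 151-sensor SQUID
array, it offers a non-invasive functional view of the levator ani muscles
(LAM) — the pelvic floor complex that is stretched far beyond ordinary
skeletal-muscle limits during vaginal birth. The analysis this package
implements characterises voluntary LAM contractions (Kegels) with amplitude
and spectral parameters, and compares each subject's third-trimester
recording with an early-postpartum recording in a paired design.

A session interleaves 10 s contractions with 10 s rest: small, moderate and
strong Kegels (SmK/MK/StK), plus isolated abdominal (A) and thigh (T)
contractions used to document accessory-muscle interference. Only
moderate-Kegel (MK) epochs enter the analysis: small Kegels are too close
to the noise floor and strong Kegels recruit accessory muscles. Surface EMG
on perineum, abdomen and thigh and one maternal ECG lead are recorded
alongside; sampling is 1200 Hz.

## Processing chain

Stages run in this order (each is a separate, individually testable
function):

1. **Reference subtraction (SUBTR)** — `fitSubtr()` / `applySubtr()`.
   Thigh-muscle activity couples most strongly onto the outermost ring of
   array sensors. For every STFT frequency bin (1 s Hann window, 50% hop)
   the complex regression of each target channel on the edge-reference
   channels is estimated as the cross-spectral density times the
   regularised inverse of the reference auto-spectral matrix (diagonal
   loading `1e-3` x mean reference power). The predicted
   reference-coherent component is reconstructed by weighted overlap-add
   and subtracted. The same machinery with the ECG lead as sole reference
   removes the cardiac artifact from the EMG channels
   (`removeCardiacEmg()`).
2. **Band-pass and notch filtering** — `bandpassNotch()`. 4th-order
   Butterworth 20–200 Hz plus a 60 Hz notch (2nd-order IIR, Q = 30, a
   standard biquad design; no specific notch design is prescribed by the
   protocol). Both are applied forward–backward: epoch-locked amplitude
   analysis must not suffer phase distortion, so the effective magnitude
   response is the squared single-pass response. `filterGain()` exposes
   the designed zero-phase response for verification.
3. **ICA denoising** — `icaDenoise()`. Fixed-point negentropy-maximising
   ICA (FastICA) on the MMG channels with a seeded random orthogonal
   initialisation. Components are rejected when their time course
   correlates with the ECG lead (|Pearson| > 0.8) or when more than 80% of
   their mixing-weight energy sits on the edge-reference sensors; both
   thresholds are configurable and the stage can be disabled. Rejected
   components are *subtracted* from the data, so signal outside the
   decomposed subspace is never altered, and with nothing rejected the
   stage is exactly the identity.

Epochs are then cut from −3 s to +10 s around each exercise-onset trigger
(15600 samples at 1200 Hz), the pre-trigger 3 s mean is subtracted per
channel (baseline correction), and a quality gate discards epochs whose
SNR falls below 1 dB.

### SNR definition and the quality gate

SNR is the square of the ratio of signal-interval RMS to baseline-interval
RMS, in dB: `20 log10(RMS_sig / RMS_base)`. RMS is pooled over the
`mmg_lower` channel subset (the sensors closest to the muscles of
interest); a best-single-channel variant is available
(`perChannel = TRUE`) since pooling-vs-best-channel is not prescribed —
pooled is the default because the lower sensors are the stated analysis
subset. The gate reads "exclude epochs *below* 1 dB" literally: an epoch
at exactly 1.0 dB is kept (a small numeric tolerance protects the boundary
from floating-point rounding). Any (subject, session) cell left with no
surviving epochs cannot contribute a parameter pair, so that subject is
excluded from the paired analysis entirely — with ten recorded subjects
and one all-subthreshold postpartum session this reproduces the
ten-recorded / nine-analysed bookkeeping of the original cohort.

## Parameters

From each kept MK epoch's signal interval, averaged over the `mmg_lower`
channels:

- **RMS amplitude** (fT): sliding-window RMS, 200 ms window with 199 ms
  overlap. At 1200 Hz the nominal 1 ms hop is 1.2 samples; the realised
  hop is 1 sample (window 240 samples), the closest realizable value —
  slightly denser than nominal, which only smooths the envelope further.
  The series is smoothed with a 100-point centred moving average
  (shrinking windows at the edges keep output length equal to input
  length) and reduced to a scalar by its mean over the signal interval
  (`reduce = "max"` is available; the reduction to one number per epoch
  is not prescribed).
- **Total power**: Welch PSD (1 s Hann segments, 50% overlap, so 1 Hz
  resolution), summed over the 20–200 Hz bins. The stated convention
  "sum of PSD content" is followed literally — density bins are summed,
  not integrated against bin width.
- **Relative PSD** (rPSD): band sums of the density normalised by total
  power, over low 20–80 Hz, middle 80–140 Hz, high 140–200 Hz. The shared
  edges are assigned half-open — [20, 80), [80, 140), [140, 200] — so
  every bin counts exactly once and the three fractions sum to 1 by
  construction.

Per-sensor total power over the array (`powerMap()`) gives the spatial
topography used to confirm that contraction power localises over the
lower sensors.

Parameters are grand-averaged per subject across kept MK epochs, and each
parameter is compared between sessions with a paired Student t-test
(two-sided, alpha 0.05, no multiple-testing correction across the five
parameters — matching the original per-parameter analysis). Shapiro–Wilk
on the paired differences accompanies every test; when it fails (p <
0.05) a warning is raised and a Wilcoxon signed-rank p-value is reported
as a supplementary column, but the t-test remains the primary result —
this reproduces the published analysis while surfacing the assumption
check.

## The synthetic-data generator

No raw recordings from the study are deposited, so the package ships a
generator (`simulateSession()`, `simulatePairedStudy()`) that emulates the
protocol: the full exercise schedule at 1200 Hz (onsets exactly at
10 + 20k s), a curved-array channel layout with lower and edge-reference
subsets, and known ground truth for every burst.

Design choices, made once:

- **Bursts** are Gaussian noise filtered into the three analysis bands and
  mixed with amplitude weights `sqrt(w)`, so the power fractions equal the
  specified profile. The synthesis filters are 6th-order zero-phase
  Butterworth with edges pulled 3 Hz inside the nominal band: a design
  with half-power points exactly at the band edges would leak 2–3% of the
  energy outside the band the weight refers to, making the generator's
  own ground truth ambiguous.
- **Envelope**: 0.5 s raised-cosine ramps at contraction on/offset (the
  contraction dynamics are not described in the protocol; ramps avoid
  spectral splatter).
- **Spatial projection**: exponential falloff, `exp(-d / 0.05 m)`, from a
  role-specific source point (below the lower-sensor centroid for the
  pelvic floor). This produces localised power maps without a
  magnetostatic forward model, which is deliberately out of scope.
- **Interference**: thigh and abdominal coloured noise projected from
  their anatomical sides (hence concentrated on edge/upper sensors), a
  QRS-like cardiac template (three Gaussians, 70 bpm with 5% beat
  jitter) coupled to every channel and the ECG lead, a common-phase 60 Hz
  line component, and white sensor noise. Default levels (fT on the most
  affected channel): thigh 100, abdominal 60, cardiac 30, line 20, white
  15; moderate-Kegel amplitude defaults to 80 fT with SmK/StK at
  0.5x/1.6x. These are choices of plausible magnitude ordering
  (interference > signal > post-filter noise floor), not measured values.
- **Paired effect**: postpartum amplitude multiplied by 0.75 and band
  weights shifted by −0.10 (low) / +0.10 (middle), the directions the
  study reports; between-subject SD 0.05 on band weights and 0.2 (log
  scale) on amplitude; 3 Kegel cycles per intensity per session.

`simulateFeatureTable()` is the signal-free counterpart used for
statistical calibration: it draws the same per-subject ground truth and
adds epoch-level measurement noise (RMS coefficient of variation 0.15,
band-weight SD 0.02) directly on the parameter scale, so that
1000-replicate null calibrations and power checks of the paired analysis
run in seconds instead of re-rendering thousands of 151-channel sessions.

What the generator does **not** emulate: volume-conductor physics, fetal
signals, sensor dropouts, motion artifacts, or non-stationary muscle
fatigue. Band-limited Gaussian bursts are also nearly Gaussian
marginally — real electromyographic interference is spikier, which makes
ICA separation *easier* on real data than on the synthetic sessions. A
passing suite therefore demonstrates correctness of the implementations
and calibration of the statistics under the stated model, not clinical
validity on real recordings.

## Numerical choices and degenerate inputs

- Zero baseline RMS makes the SNR ratio infinite; it is reported as a
  capped sentinel (300 dB) with a warning rather than `Inf`.
- Zero total power makes rPSD undefined; it is reported as `NA` with a
  warning, never silently renormalised.
- Zero variance of paired differences makes the t-test degenerate; the
  result is flagged (`degenerate = TRUE`, `t = NA`) rather than reported
  as `t = 0` or an error.
- The SUBTR per-bin solve uses diagonal loading `1e-3` x mean reference
  power, so a spectrally sparse reference cannot produce a singular
  auto-spectral matrix.
- FastICA component count defaults to the number of covariance
  eigenvalues above 1.5x the white-noise floor (estimated as the mean of
  the lower half of the spectrum). Fixed-point ICA does not converge on
  directions that are merely Gaussian noise, so restricting the
  decomposition to the structured subspace is what makes the stage
  deterministic and convergent; the unmixing is estimated on temporally
  decimated samples (about 40000) and applied to the full data.
  Non-convergence triggers re-initialisation with a fresh seeded rotation
  and, after the retries are exhausted, an explicit error.
- Events whose epoch window would cross the recording boundary are
  dropped with a warning, not zero-padded — padding would bias the
  baseline statistics.

## Problem sizes used by the tests and the acceptance script

Unit and property tests exercise the full-signal path on reduced arrays
(10–40 MMG sensors) and single-cycle sessions, which preserve every
code path at a few percent of the full-array cost; generator defaults
remain the study conditions (151 sensors, 3 cycles per intensity,
1200 Hz). Statistical calibration uses 1000 null replicates and 100
effect replicates of nine-subject studies at the parameter level. The
acceptance script recomputes filter gains, subtraction and ICA
performance on planted mixtures, band-profile recovery over 50 bursts on
a simplex grid, the 10-to-9 subject QC bookkeeping, and the calibration
rates, from scratch at the seed it is given.

## Known limitations

- The SUBTR coefficients are estimated from the same recording they are
  applied to; with very short recordings (< 10 STFT windows, refused) the
  per-bin regressions would overfit and begin to remove genuine signal.
- The ICA rejection criteria (ECG correlation, edge concentration) are
  this package's policy; the original analysis reviewed components
  manually, which cannot be reproduced programmatically.
- Features are averaged over the `mmg_lower` subset; per-channel outputs
  exist, but no spatial statistics beyond the power map are implemented.
- The paired comparison assumes both sessions share the preprocessing
  configuration; mixing configurations across sessions is not prevented
  but is not meaningful.
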