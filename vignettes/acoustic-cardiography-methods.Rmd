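---
title: "Acoustic cardiography in acgtools: signal model, pipeline and diagnostic statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic cardiography in acgtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acgtools)
```

# What the package computes

Acoustic cardiography pairs an ECG with a phonocardiogram (PCG) on a common
clock. The QRS complex gives the electrical reference; the first and second
heart sounds (S1: mitral/tricuspid closure; S2: aortic/pulmonic closure)
give the mechanical landmarks. From these the package computes, per beat:

- `lvet_ms = s2_peak - s1_end` — left ventricular ejection time, the
  aortic-valve open-to-close interval;
- `emat_ms = s1_peak - qrs_onset` — electromechanical activation time;
- `lvst_ms = s2_peak - s1_peak` — left ventricular systolic time;
- `q2s2max_ratio = s2_peak_amplitude / qrs_amplitude` — an index of aortic
  valve closure strength (the raw S2 amplitude is reported alongside,
  because device reports print the amplitude itself; the two differ only by
  the QRS-amplitude normalization).

These definitions fix two points the clinical literature leaves loose.
First, some texts gloss S2 as aortic valve *opening*; the package uses S2 =
closure, the standard physiology, which is also the only reading consistent
with LVET being an open-to-close interval. Second, LVST's endpoints are not
standardized; the package defines it S1-peak to S2-peak because both peaks
are the most robust envelope landmarks, and this choice keeps
`lvst >= lvet` on every ordered beat (the S1 peak precedes the S1 end) with
a gap of roughly half the S1 duration, matching the ~20 ms LVST-LVET gap
clinical tables show.

An identity links the intervals per beat and is asserted in the tests:
`emat + (s1_end - s1_peak) + lvet = s2_peak - qrs_onset`, the Q-to-aortic-
valve-closure time.

# The synthetic signal model

`generate_recording()` renders each beat from closed-form primitives so
ground truth is exact by construction:

- ECG: a P-QRS-T stencil per beat — Gaussian P and T waves, and a Q-R-S
  complex of three Gaussians gated to start exactly at the scheduled QRS
  onset. The gate makes "QRS onset" a crisp, well-defined instant rather
  than the tail of a Gaussian, so onset-detection accuracy can be measured
  meaningfully at the sample level. The R peak sits 24 ms after onset.
- PCG: S1 and S2 as Gaussian-enveloped tone bursts (35 Hz and 50 Hz
  carriers, inside the 25–45 / 40–60 Hz bands where these sounds carry
  most energy). A burst's "duration" is the span over which its envelope
  exceeds 10% of peak; `s1_end` ground truth is defined by that same 10%
  criterion, since no published definition of "end of S1" exists. The
  placement enforces `s1_peak = qrs_onset + emat` and
  `s2_peak = s1_end + lvet` exactly.
- Noise: white noise scaled to an exact per-channel SNR against the clean
  render; optional sinusoidal ECG baseline wander; optional motion bursts
  that raise a synthesized accelerometer channel to a stated acceleration
  and corrupt the PCG with a broadband transient. The motion channel exists
  because the QC rule it feeds (reject > 0.5 g) needs a testable stimulus.
- Schedule: RR intervals are the nominal cycle length plus Gaussian jitter
  (`rr_jitter_ms`); with zero jitter the mean RR is exactly
  `60000 / heart_rate_bpm`.

Defaults describe a normotensive third-trimester profile: heart rate 75
bpm, LVET 301 ms (the control-group mean), EMAT 90 ms (mid-physiologic),
S1/S2 durations 70/60 ms, S2/S1 amplitude ratio 0.8, QRS 1 mV, RR jitter
10 ms. Both channels are sampled at `fs_hz = 2000` — one clock satisfies
the >= 500 Hz ECG requirement and the 20–1000 Hz PCG band with margin, and
avoids resampling.

What the simulator does **not** emulate: murmurs, S3/S4, arrhythmias beyond
RR jitter, respiratory modulation, fetal sounds, spectral (non-white)
noise, or sensor-specific transfer functions. Passing tests therefore show
the pipeline recovers intervals correctly from beat-structured signals
under additive noise and artifacts — not that it handles every pathology a
clinical recording can contain.

# Preprocessing and quality control

- **ECG bandpass 0.05–150 Hz**: a 2nd-order 0.05 Hz highpass and 4th-order
  150 Hz lowpass, each applied forward-backward (`signal::filtfilt`), so
  the cascade is zero-phase and event timing is preserved (< 2 ms shift is
  asserted in tests). Note that 0.2 Hz respiratory-scale drift is inside
  this passband by design; large drift is handled by QC, not the filter.
- **PCG denoising**: full wavelet-packet tree of depth 5 with the
  Daubechies-6 filter, periodized; soft universal thresholding per terminal
  node (`sigma * sqrt(2 log m)`, `sigma` from the node's MAD). Depth 5 at
  2000 Hz gives 31.25 Hz-wide nodes, fine enough to isolate the S1/S2
  bands. The filter bank is orthonormal, so reconstruction is exact to
  machine precision; on clean input thresholds are near zero and the
  transform is near-identity (correlation >= 0.99 asserted).
- **SQI**: the published protocol gives only a validity threshold
  (SQI > 0.8), not a formula. The package defines SQI as the mean positive
  Pearson correlation between each beat's PCG envelope (600 ms window from
  the QRS reference, resampled to 120 points) and the median envelope
  template across beats. Beat self-consistency captures the intent —
  clean periodic recordings score near 1, noise-dominated recordings fall
  far below 0.8 — and it is computable without a trained model. It is
  computed per recording, with per-segment rejection handled by flags.
- **QC flags**: motion segments where the accelerometer exceeds 0.5 g;
  a recording-level drift flag when the < 0.5 Hz ECG envelope amplitude
  (half peak-to-peak) exceeds 1 mV; a low-SQI flag at or below 0.8. A
  report is `valid` only with SQI above threshold and no flags.
- **Gain calibration**: per-beat S1 peak envelope amplitudes are measured
  at the beat references; a global gain `target / median(amplitude)`
  (clamped to ±30%) restores nominal level and per-beat residual gains
  (same absolute clamp) stabilize amplitude toward a coefficient of
  variation below 8%. A required gain outside the clamp is applied at the
  limit and recorded as a warning, not an error, mirroring how a device
  would degrade.

# Event detection

**QRS**: derivative–square–integrate (Pan–Tompkins-style) peak detection
on a 5–25 Hz zero-phase band, 150 ms integration window, threshold at 25%
of the 99.5th percentile, 300 ms refractory period. Onset is backtracked
from the steepest point of the QRS on a short-window (8 ms) RMS of the
trace's slope, to the last sample below 1.5% of the beat's maximum slope,
then snapped to the first raw-slope sample above threshold. Slope, not
amplitude, is the landmark because filtering leaves slowly-varying
baseline pedestals around the QRS whose amplitude is large but whose
derivative is negligible; amplitude-based backtracking stalls on them and
on zero-crossings inside the complex. The threshold floor adapts to the
trace-wide slope noise (3x the 25th percentile), so clean recordings
resolve the faint Q-wave onset to within a sample or two while noisy ones
fall back to the upstroke emergence, a few ms late.

**S1/S2**: S1 is sought in `[onset, onset+200)` ms and S2 in
`[onset+200, onset+600)` ms, clipped at the next beat — generous
physiologic bounds. Peaks come from the denoised PCG envelope (rectified
trace, zero-phase 30 Hz lowpass; 30 Hz suppresses the rectified-carrier
ripple of both sounds while keeping the 10%-of-peak boundary landmarks
within two sample periods of truth on clean signals). S1/S2 onset and end
use the same 10% envelope criterion as the simulator's ground-truth
definition. A beat whose S2 envelope peak falls below 15% of the
across-beat median S2 peak is rejected as `s2-not-found`.

**DTW validation**: each beat's MFCC segment (40 coefficients per 25 ms
frame, 10 ms hop, 60 triangular mel filters over 20–1000 Hz, orthonormal
DCT-II) is z-scored per coefficient and aligned to the recording's own
median-beat template with dynamic time warping (symmetric step pattern,
Sakoe–Chiba band of 25% of segment length, cost normalized by the summed
path lengths). Beats with normalized cost above 3.5 are rejected as
`poor-template-match`. The threshold was fixed by examining cost
distributions on clean simulated recordings (costs up to about 3) versus
motion-corrupted beats (typically 4–8); it is a backstop — beats
overlapping accelerometer flags are already invalidated by QC, so DTW
catches corruption the motion channel misses. Self-templating is used
because no published template exists; with fewer than 3 usable beats the
DTW check is skipped rather than trusting a degenerate template.

# Aggregation

Per-recording summaries use the **median** over valid beats as the
headline statistic (the mean is reported alongside): a single residual
artifact beat should not move a recording's LVET. Heart rate is
`60000 / median RR`. Summaries from fewer than 5 valid beats, or from
recordings failing QC, are marked low-confidence rather than suppressed.

# Cohort simulation

`cohort_spec()` defaults encode the published two-group sample: 28
controls with LVET 301.32 ± 35.42 ms and Q2S2Max 403.96 ± 33.28, 31 PE
cases with LVET 320.28 ± 26.79 ms and Q2S2Max 426.10 ± 29.46, hypertension
history 1/28 vs 9/31. Normality follows the mean ± SD reporting
convention. Heart-rate distributions are not published; the default is
Normal(85, 10) bpm in both groups, a typical third-trimester resting rate,
with a configurable PE shift — results involving heart rate are therefore
sensitive to an assumption the source does not constrain, which is why the
package asserts nothing quantitative about the heart-rate model. The
within-subject correlation among LVET, Q2S2Max and heart rate is likewise
unreported; the default is independence, with a single configurable common
correlation applied through a Gaussian copula.

The printed Q2S2Max scale (~400, labelled mV) cannot be reconciled with a
dimensionless ratio; the cohort generator reproduces the printed values as
given, and the signal pipeline reports both the ratio and the raw S2
amplitude. Only group *contrasts* in Q2S2Max are asserted anywhere, never
the absolute scale.

# Diagnostic statistics

- **Summary t-test**: Welch by default. From the published group summaries
  (320.28 ± 26.79, n = 31 vs 301.32 ± 35.42, n = 28) Welch gives
  p = 0.026, matching the abstract-level value, where the pooled test gives
  0.023 — the basis for preferring Welch. Both variants are exposed
  (`variant = "pooled"`), since group tables in this literature sometimes
  print pooled results.
- **Fisher exact**: two-sided by point-probability summation (the
  `stats::fisher.test` definition), which reproduces the published
  hypertension-contrast p = 0.013 and matches an exhaustive enumeration
  oracle in the tests; the alternative "doubling" definition does not.
- **Chi-square**: Yates-corrected, auto-routing to Fisher whenever an
  expected cell count falls below 5 (the sources name both tests without a
  rule; this is the textbook rule).
- **Screening**: univariate p < 0.1 (Welch t for continuous, Fisher for
  binary), constants excluded with a warning.
- **Stepwise logistic regression**: forward entry by likelihood-ratio test
  at p < 0.05 (configurable). The entry threshold is a package choice —
  the sources state only the screening threshold. Complete separation
  (common with a 1/28 exposure rate at n = 59) is flagged and the fit
  repeated with a weak ridge penalty via pseudo-observations so odds
  ratios stay finite; the flag is carried in the output rather than
  hidden.
- **ROC**: empirical curve; AUC by the midrank (Mann–Whitney) identity, so
  `AUC = U / (n1 n0)` holds exactly, ties included; DeLong
  placement-value variance for the 95% CI; Youden-optimal cutoff with ties
  broken toward the lowest cutoff; positivity is `score >= cutoff` for
  "greater" direction (prolonged LVET indicating PE). Confusion metrics
  return `NA` on zero denominators instead of erroring.
- **DeLong test**: paired AUC comparison from the placement-value
  covariance; degenerate variance returns p = 1 with a warning. The
  combined model's ROC score is the fitted logistic predicted probability.

# Numerical conventions and degenerate inputs

Times are milliseconds from recording start, sample indices 0-based,
windows half-open `[start, end)`. Wavelet input is zero-padded to a
multiple of 32 and trimmed after reconstruction. All-zero traces pass
through the filters unchanged; flat ECG yields an empty detection list
with a warning; fewer than 3 beats yields SQI 0 with a warning; zero valid
beats yields an empty summary with a reason. Every simulator and cohort
function is seed-deterministic, and seeding is local (the caller's RNG
state is saved and restored).

# Problem sizes used in validation

The bundled checks run at desk scale: 10–16 s recordings at 2000 Hz
(roughly 12–20 beats), an interval-recovery grid of 40 recordings
(LVET 260–360 ms crossed with PCG SNR 10–20 dB, five seeds each), and 400–500
simulated cohorts of n = 59 for the ROC and type-I-rate calibrations.
These sizes give Monte-Carlo error comfortably below the tolerances being
asserted (the LVET-recovery benchmark of 8.2 ms is met with a wide margin
on this simulator; the per-cohort AUC has SD ≈ 0.07, so 400 cohorts pin
the mean to ≈ 0.004).

# Known limitations

- The simulator's clean-world assumptions (above) mean real-device
  performance claims are out of scope; the pipeline's accuracy figures are
  statements about the synthetic signal model.
- The SQI is a self-consistency index: a recording of perfectly periodic
  artifact would score high. It is meant to gate obviously degraded
  recordings, combined with the motion and drift rules.
- EMAT depends on QRS-onset backtracking, which degrades gracefully but
  visibly with ECG noise (a few ms late at SNR 15–20 dB); LVET and LVST
  are PCG-only and unaffected.
- With n = 59 and a rare exposure, stepwise selection is unstable across
  cohort draws — different seeds select different variable sets. That is a
  property of the design being emulated, not a defect of the fitter; the
  package surfaces it rather than stabilizing it away.
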