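---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(psychsig)
```

This vignette documents the models behind each stage of the pipeline, the
parameters that matter (with units and defaults), and the choices made where
the design was genuinely open. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The skin-conductance model

Electrodermal activity is modeled as the superposition of a slowly varying
tonic level and phasic responses produced by bursts of sudomotor nerve
activity. A burst of area $a$ (µS·s) at time $t_0$ contributes
$a \cdot \mathrm{IRF}(t - t_0)$ where

$$\mathrm{IRF}(t) = \left(e^{-t/\tau_1} - e^{-t/\tau_2}\right) u(t),$$

with $u(t)$ the unit step, slow decay $\tau_1$ and fast rise $\tau_2$
($\tau_1 > \tau_2 > 0$; the degenerate case $\tau_1 = \tau_2$ is rejected).
Defaults are $\tau_1 = 2$ s, $\tau_2 = 0.75$ s, values in the typical range
for unitary skin-conductance responses. The forward generator
(`synthesize_edr()`) discretizes the impulse train onto the sample grid,
convolves with the sampled IRF (exact recursive form) and adds the
piecewise-linear tonic level plus white noise.

### Deconvolution

`deconvolve_edr()` inverts the convolution exactly in discrete time: with
$a_i = e^{-\Delta t/\tau_i}$, the sampled IRF is a two-pole recursive system
whose inverse is the three-tap FIR filter
$1 - (a_1{+}a_2) z^{-1} + a_1 a_2 z^{-2}$ (scaled and advanced one sample).
This is preferred over frequency-domain division, which distributes edge
effects globally, and over a dense non-negative least-squares fit of the
impulse train, which needs $O(N^2)$ memory at the $10^5$-sample recordings
this package targets; the inverse filter is exact on noise-free input and
linear-time.

Design parameters, all exposed:

* **Driver smoothing** (`driver_smooth`, default 0.2 s). Inverse filtering
  amplifies residual noise roughly as $f^2$ up to the 2 Hz pre-filter
  cutoff; a unit-area, zero-phase Hann smoother suppresses it while
  preserving impulse areas and peak times exactly on noise-free input.
* **Tonic estimate.** The tonic share of the raw driver is interpolated (by
  smoothing spline) through anchors placed every `tonic_grid` = 10 s in
  driver-quiet sections (within 3 robust SDs of the running driver median).
  The tonic conductance trace is then defined as input minus reconvolved
  phasic driver, which makes the reconstruction identity exact by
  construction.
* **Noise gate.** The driver noise scale σ is estimated as the MAD of the
  fast residual around a 1 s running median; only excursions whose peak
  clears 4σ are attributed to sudomotor activity, with run boundaries
  extended down to 0.5σ. On noise-free input σ = 0 and nothing is gated.
* **Edges.** The first and last 2 s of the driver are not attributed to
  phasic activity (filter start-up); stimuli never sit that close to the
  recording edges in either protocol.
* **SCR significance** (`min_amplitude`, default 0.01 µS) applies to the
  reconvolved single-response amplitude, i.e. driver-cluster area times the
  IRF maximum $\mathrm{IRF}(t^*)$, $t^* = \frac{\tau_1\tau_2}{\tau_1-\tau_2}\ln(\tau_1/\tau_2)$.

Interpretation notes: the feature battery lists "variance of the tonic
driver" under tonic features; this package computes the variance of the
tonic *component*, and houses the non-specific-response count (detected SCRs
whose onsets fall outside every stimulus response window) with the tonic
features for table compatibility, although NSRs are phasic events.

## ECG processing and HRV

* **Baseline removal**: centered moving average subtraction, default window
  0.6 s — removes respiration-scale wander (attenuation follows
  $|1 - \sin(\pi f W)/(N \sin(\pi f/f_s))|$) while sparing the QRS complex.
* **QRS detection**: the classic Pan–Tompkins chain with the published
  constants — 5–15 Hz band-pass, five-point derivative, squaring, 150 ms
  moving-window integration, adaptive signal/noise thresholds with
  search-back at 1.66× the running RR average, 200 ms refractory period —
  and final R-peak localization on the baseline-corrected signal. All
  constants are arguments.
* **NN selection**: an interval is non-sinus if it deviates more than 20%
  from the median of its five neighbouring intervals. Such intervals are
  excluded from statistics and replaced by the running median before
  resampling.
* **Berger resampling** at 4 Hz: windowed fractional beat counting over two
  output periods, clipped at the recording edges so a constant RR series
  resamples to itself exactly.
* **Spectral estimate**: Welch PSD with a Hann window; for the 20–30 s
  analysis windows used here the segment equals the window (a Hann-windowed
  periodogram), since splitting a 30 s window would destroy the LF
  resolution. Band powers are reported in ms². VLF (lower edge 0.003 Hz)
  cannot be resolved on 20–30 s windows; it is computed but flagged
  unreliable (`VLF_reliable = FALSE`) rather than omitted, so feature tables
  keep a stable shape. A band is "reliable" when the window covers at least
  two cycles of its lower edge.
* **Poincaré convention**: $SD1^2 = \mathrm{SDSD}^2/2$ and
  $SD2^2 = 2\,\mathrm{SDNN}^2 - \mathrm{SDSD}^2/2$ with sample (n−1)
  variances, making $SD1^2 + SD2^2 = 2\,\mathrm{var(nn)}$ an exact identity
  (SD2 is floored at 0 for strictly alternating series).
* **Entropy**: approximate entropy with $m = 2$, $r = 0.2\,\mathrm{SD}$,
  self-matches included; a zero-variance series has entropy 0 by definition.
* **Windows**: HRV windows shorter than 20 s are rejected outright — on
  short-term recordings, shorter windows do not support the battery. The
  picture-viewing analysis uses 20 s stimulus windows, the conditioning
  analysis 30 s windows anchored at the outcome onset (15 s image + black
  screen).
* Variance convention: sample (n−1) variance everywhere a variance or SD is
  reported; central moments for skewness/kurtosis use population (1/n)
  moments, so a two-point symmetric series has excess kurtosis −2.
* The conditioning feature names "RRmean" and "RR_tri" are not defined in
  the source material; they are mapped to the mean RR interval and the
  triangular index respectively, flagged here as interpretation.

## Motion artifacts

Grab gestures are detected per flexion channel against a 10 s running-median
baseline (immune to the slow drift of textile sensors); a channel is active
above baseline + 6×MAD (floored at 0.01 sensor units so flat channels never
trigger), and an event requires at least 3 of 5 channels active for 200 ms.
Masks pad 1 s before and 3 s after each grab (covering the gesture-locked
conductance transient) and merge overlaps. Chest ECG is never masked for
hand gestures. The automated mask is a faithful proxy for the manual
post-hoc exclusion used with real recordings, not a reproduction of it.

Activity indexes (MAI, MRI) are the summed per-axis SDs within windows of at
least 20 s; homogeneity across stimulus classes is tested with Levene's test
(mean-centered), within or between subjects.

## Arousal classification

Class labels come from the printed 12-picture catalog columns, not from
re-binning the arousal ratings: the catalog lists two borderline pictures
(arousal 3.18 and 3.72) as low-arousal in subset α even though the range
description says 1–3, and the printed membership governs. Rows are pooled
across subjects without per-subject normalization (the inter-subject
analysis is pooled in the source design; z-scoring happens inside each
validation split).

The validator runs 40 Monte-Carlo iterations of stratified random 80/20
splits — the description "40-fold cross-validation [with] 80% randomly
extracted" matches repeated random subsampling, not k-fold partitioning.
Inside each iteration, and on training rows only: missing entries (masked
windows) are imputed by the training-column median, features are z-scored,
PCA retains the smallest number of components reaching 90% cumulative
variance (unscaled PCA would be dominated by large-unit band powers), and a
pooled-covariance linear discriminant with uniform priors is fitted. Test
confusion matrices are normalized per true class to percent; the report is
their element-wise mean ± SD. Standardization/PCA fitted on training rows
only is the leakage guard; the permuted-label chance-level test is the
tripwire that would catch a violation.

## Conditioning statistics

The per-trial table uses the 1–4 s post-CS window for the first-interval
response (a 3 s window starting at the 1 s latency gate, reconciling the "3 s
after onset" text with the 1–4 s figure convention); no SCR with onset
before the gate ever contributes. Amplitude sums are normalized by the
subject's own maximum, so the per-subject maximum is exactly 1 whenever any
trial responded.

The "paired Wilcoxon ranksum" phrasing in the source describes a paired
design, so latency comparisons use the Wilcoxon signed-rank test on
per-subject means. Block and pairwise follow-ups are Bonferroni-corrected
(the correction used elsewhere in the same analyses). The Friedman test runs
across the four per-subject condition means (CS+/CS− × session); whether the
original analysis used per-trial values or aggregates is unstated, and
per-subject means are the assumption here. The extinction vagal-trend
comparison (first vs fourth CS+ trial for RMSSD, HF, SD1) is one-sided for a
decline, since the hypothesis under test is directional (vagal withdrawal).
Normality screening uses the Lilliefors-corrected Kolmogorov–Smirnov test
(`nortest::lillie.test`).

## The synthetic-data generators

The generators define the study conditions; their defaults are the stated
protocol constants wherever a value is printed, and a single realistic
choice elsewhere:

* Study 1: 7 subjects, 5-min baseline, 12 stimuli in randomized order, 20 s
  pictures, 20 s black screens, a grab 2 s before each trial. Study 2: 11
  subjects, 9 CS+ and 9 CS− trials per session in random order (the source
  text is self-contradictory between "18 per CS type" and "9 CS+ stimuli";
  9 per type is adopted), 15 s outcome images, black screens uniform on
  [14, 20] s (the text's 17 ± 3 s; a figure caption says 15 s, the text
  governs), 5-min rest between sessions.
* Sampling rates follow the acquisition hardware: ECG 250 Hz, skin
  conductance and motion 100 Hz.
* RR model: $RR(t) = 60/\mathrm{HR}_0 + \sum_i a_i \sin(2\pi f_i t + \phi_i)$
  sampled at beat times plus per-beat white noise (floored at 0.21 s);
  baseline modulators 0.02 s at 0.1 Hz (LF) and ≈0.03 s at 0.25 Hz (HF),
  HR$_0$ ≈ 72 ± 3 bpm, beat noise 0.01 s.
* The ECG beat is a fixed synthetic PQRST-like sum of Gaussian bumps with
  the R maximum pinned to the beat time — sufficient to exercise detection,
  not a biophysical model. Channel noise 0.02 mV.
* Effect model (all gains exposed; zero gains give exchangeable labels):
  stimulus-locked impulse area 0.35 + 0.08·(arousal − 4.5) µS·s (SD 0.04),
  a second late impulse with arousal-dependent probability; conditioning
  amplitude = 0.08 + asymptote·(1 − e^{−0.6·trial}) µS·s for CS+ during
  acquisition (asymptote 0.5) decaying as e^{−0.5·trial} in extinction;
  grab latency 3.4 s ± (0.2 subject, 0.45 trial) with a +0.32 s CS+
  increment during acquisition; RR lengthening 0.02 s on reinforced
  acquisition trials (sign-flipped in extinction); HF modulation declining
  across extinction CS+ trials (vagal-withdrawal analogue); spontaneous
  SCRs at 1/90 Hz; grab artifacts as additive biphasic 0.3 µS spikes locked
  to flexion pulses (the published gesture-artifact figure shows the shape
  only qualitatively); conductance noise 0.005 µS over a slowly drifting
  tonic level around 2 µS.
* Simulated self-assessment ratings (used in the power checks) share a
  per-subject anchor (SD 1.2) with within-subject noise 0.9, giving the
  marginal rating SD of 1.5 used in the published comparison.

What the generators do **not** emulate: real electrode drift and contact
artifacts, respiration coupling, ectopic beats, hardware dropouts, or
between-subject physiological diversity beyond mean-level offsets. Passing
tests therefore demonstrate that the *pipeline* recovers known ground truth
and that its statistics are calibrated — not that the published
subject-dependent values (confusion-matrix percentages, latency means,
p-values) are reproduced; those depend on the original recordings, which
were never deposited.

## Problem sizes

The suites run the full chain at desk scale: 2–7 synthetic subjects for
end-to-end checks, 90–300 s recordings for signal-level recovery, 20–50
seeds for detection/recovery aggregates, 500 replicates for null
calibration and 200 for power, all chosen as the smallest sizes at which
the Monte-Carlo error is comfortably below the margins being tested.

## Known limitations

* The deconvolution assumes fixed Bateman constants per recording; per-
  recording refinement of (τ1, τ2) is not implemented.
* TINN on sparse histograms is sensitive to bin occupancy; it is reported
  but not relied on by any downstream stage.
* The Levene, Friedman and rank tests inherit their small-sample behavior
  from base R / `car`; at n = 7 subjects the discreteness of the signed-rank
  distribution caps attainable significance levels.
* EDF import/export is not provided; the on-disk format is the delimited
  text + JSON layout written by `write_study_dataset()`.
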