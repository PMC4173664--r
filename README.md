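# psychsig

Tools for inferring affective states from ambulatory psychophysiological
recordings. The package re-implements, as tested and reusable R functions, an
inference chain used in wearable-sensor emotion research:

- **ECG → heart-rate variability (HRV).** Moving-average baseline removal,
  Pan–Tompkins QRS detection, RR/NN series construction with an ectopic-beat
  rule, Berger uniform resampling, and the full short-term HRV battery:
  time-domain statistics (MNN, SDNN, RMSSD, pNN50, …), geometric measures
  (triangular index, TINN), spectral band powers (VLF 0.003–0.04 Hz,
  LF 0.04–0.15 Hz, HF 0.15–0.4 Hz, LF/HF), Poincaré dispersions (SD1, SD2)
  and approximate entropy.
- **Skin conductance → tonic/phasic decomposition.** The electrodermal trace
  is modeled as sudomotor nerve impulses convolved with the biexponential
  Bateman impulse response `IRF(t) = (e^{-t/τ1} − e^{-t/τ2})·u(t)`; the
  package deconvolves the recording into a tonic level and a non-negative
  phasic driver, detects significant skin-conductance responses (SCRs) and
  computes event-related features (nSCR, Lat, AmpSum, Mean/Var/Max of the
  driver, AUC, tonic mean/variance, non-specific response counts).
- **Motion-artifact gating.** Grab-gesture detection from five finger-flexion
  channels (adaptive running-median baseline + majority rule), movement
  activity indexes (MAI/MRI = σx+σy+σz of acceleration/orientation per
  window), artifact masks with configurable padding, spectral-overlap
  diagnostics, and Levene homogeneity tests of movement across stimulus
  classes.
- **Arousal classification.** Feature segmentation around picture stimuli
  (5 s skin-conductance windows, 20 s HRV windows), the published 12-picture
  catalog with its α/β/γ class subsets, univariate screening
  (Lilliefors-corrected normality routing to t/ANOVA or Mann–Whitney /
  Kruskal–Wallis with Bonferroni follow-ups), and PCA (90% variance) + a
  pooled-covariance linear discriminant validated over 40 random stratified
  80/20 splits, reported as mean ± SD confusion matrices.
- **Classical-conditioning analysis.** Per-trial tables (grab latency,
  first-interval SCR amplitude in the 1–4 s post-CS window normalized to the
  subject maximum, 30 s HRV windows over the outcome image and black
  screen), early/middle/late block summaries, paired signed-rank latency
  comparisons, rank-based block statistics, Friedman tests across the four
  CS/session conditions, and the vagal-trend analysis (RMSSD, HF, SD1) over
  the first extinction trials.
- **Synthetic-data generators with ground truth.** Because no raw recordings
  are available, `simulate_study1()` and `simulate_study2()` generate the
  full channel set (ECG 250 Hz, skin conductance 100 Hz, tri-axial
  acceleration/orientation, five flexion channels) under both study
  protocols, with a tunable effect model whose zero-gain setting makes class
  labels exchangeable. Every dataset carries its latent ground truth (beat
  times, sudomotor impulses, grab times, latencies), so recovery, power and
  calibration are all testable.

Everything is tidyverse-native: generators and analysis steps take data
frames and return tibbles, fitted objects have `tidy()`/`glance()` methods
and `autoplot()` figures.

## Worked example

```r
library(psychsig)

# a separable picture-viewing dataset for 3 subjects
ds <- simulate_study1(n_subjects = 3, seed = 11)
features <- segment_and_assemble(ds)
res <- run_study1_analysis(ds, subset = "alpha", n_iter = 10, seed = 1,
                           features = features)
res$validation
#> Linear-discriminant validation over 10 random 80/20 splits
#> Mean confusion matrix (%, true classes as columns):
#>          truth
#> predicted  A1    A2
#>        A1 100  3.33
#>        A2   0 96.67
#> SD:
#>          truth
#> predicted A1    A2
#>        A1  0 10.54
#>        A2  0 10.54
#> Mean accuracy: 98.3% (SD 5.3), PCs retained (median): 7
```

The diagonal entries are the percentage of low-arousal (`A1`) and
high-arousal (`A2`) test presentations recognized correctly, averaged over
the random 80/20 validation splits; off-diagonal entries are confusions.
With the default effect model the stimulus-locked sudomotor response grows
with picture arousal, so the two classes separate almost perfectly; with
`null_effect_model()` the same pipeline sits at the 50% chance level.

Skin-conductance decomposition on its own:

```r
tr <- sudomotor_truth(data.frame(time = c(20, 21.5), amplitude = c(0.4, 0.3)),
                      tonic = 1, duration = 50)
dec <- deconvolve_edr(synthesize_edr(tr))
tidy(dec)          # two SCR events, peaks at 20.0 s and 21.5 s
autoplot(dec)      # conductance / tonic / phasic driver panels
```

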