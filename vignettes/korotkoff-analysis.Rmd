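---
title: "Korotkoff sound analysis: models, generator and design choices"
author: "korosound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Korotkoff sound analysis: models, generator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(korosound)
```

## The scientific problem

Korotkoff sounds are the audible bursts an artery emits while a
blood-pressure cuff deflates between systolic (SBP) and diastolic (DBP)
pressure. Arterial stiffening — the mechanical signature of vascular
ageing — changes how the arterial wall responds to partial compression and
pulsatile flow, and therefore plausibly changes both the *temporal
envelope* of the beat train (when in the deflation window the loud beats
occur, and how asymmetrically) and its *spectral content*. korosound
implements a full analysis chain for testing that idea: preprocessing,
a ten-feature acoustic characterisation, group and correlation statistics
against a stiffness index (brachial-ankle pulse wave velocity, baPWV, in
cm/s), and a convolutional classifier operating on continuous-wavelet
scalogram images.

Because cuff recordings from human cohorts are rarely shareable, the
package treats a *synthetic generator with known ground truth* as a
first-class component: every downstream claim the test suite makes is a
parameter-recovery or calibration statement about data whose truth is
known by construction.

## The ten features

For a window of the denoised signal containing beats at peak times
$t_i$ with envelope peak amplitudes $A_i$ (weights $w_i = A_i / \sum A$),
the features are:

* **max_amplitude** $= \max |x|$ (arbitrary sensor units — the only
  scale-dependent feature);
* **kurtosis**: fourth standardized central moment of the concatenated
  beat-segment samples (non-excess, so a sinusoid gives 1.5);
* **peak factor** (crest) $= \max|x| / \mathrm{RMS}$, **pulse factor**
  (impulse) $= \max|x| / \overline{|x|}$, **form factor**
  $= \mathrm{RMS} / \overline{|x|}$; the identity
  $\text{pulse} = \text{peak} \times \text{form}$ holds exactly and is
  asserted to $10^{-12}$ relative on every input;
* **center of mass** $= \sum w_i t_i - t_\mathrm{mid}$ (seconds, signed,
  relative to the Korotkoff-window midpoint): where the amplitude mass of
  the beat train sits within the deflation window;
* **skewness**: the standardized third amplitude-weighted temporal moment
  $\sum_i w_i (t_i - \mu)^3 / (\sum_i w_i (t_i-\mu)^2)^{3/2}$ — the
  asymmetry of the beat envelope (positive = mass early, tail late);
* **peak / centroid / mean-square frequency**: $\arg\max P(f)$,
  $\sum f P / \sum P$ (Hz) and $\sum f^2 P / \sum P$ (Hz²) of the Welch
  PSD (1-s Hann segments, 50% overlap) of the concatenated beat segments.
  Mean-square frequency $\ge$ centroid² always (Jensen), which the suite
  asserts on random inputs.

Two deliberate interpretation choices: *skewness is envelope-temporal*,
not raw-sample skewness — it is the quantity that "left/right-skewed
envelope" language describes and the only version that takes meaningful
signed values of order ±1 on beat trains; and kurtosis plus the three
factors are computed on the raw denoised samples of the beat segments,
where their magnitudes (crest factors of 5–15) are characteristic of
spiky beat trains. All definitions live in one place
(`amplitude_stats()`, `envelope_moments()`, `spectral_features()`) and are
frozen by `feature_config()`.

## Preprocessing

* **Baseline drift**: 4th-order Butterworth high-pass at 5 Hz, applied
  forward and backward (zero-phase) with odd-reflection padding so the
  start-up transient never reaches the data, and mean subtraction so DC
  rejection is exact rather than limited by the conditioning of the
  near-unity pole pair. 5 Hz preserves the 20–60 Hz Korotkoff band.
  One caveat a user should know: the *theoretical* stop-band attenuation
  of the squared response (e.g. $10^{-10}$ at 0.3 Hz) is far below the
  double-precision noise floor of recursive filtering (~$10^{-8}$), so
  transfer-function checks are only meaningful where the design gain is
  above that floor.
* **Denoising**: periodized orthogonal DWT ('db6', 4 levels), soft
  universal threshold $\hat\sigma \sqrt{2\log n}$ on the detail
  coefficients with $\hat\sigma = \mathrm{median}|d_1| / 0.6745$. All
  four choices are exposed in `feature_config()`. The transform is
  implemented in-package from the published Daubechies filter constants
  and verified by perfect-reconstruction tests.
* **Window detection** (`detect_window()`): annotated recordings return
  the annotation; otherwise beat-like envelope excursions (smoothed
  analytic-signal envelope above both an adaptive fraction of the maximum
  and a robust `median + 6 MAD` noise floor) estimate SBP/DBP as the cuff
  pressures at the first/last excursion, widened by one deflation-rate ×
  beat-interval margin, because the first audible beat appears up to one
  heart period after the cuff crosses SBP.
* **Beat segmentation** (`segment_beats()`): envelope maxima above the
  adaptive threshold, minimum separation 0.35 s (larger peak wins),
  segment boundaries at inter-peak midpoints so segments tile the window.
  Beats are detected once and shared by all features; feature code never
  re-segments.

## The synthetic generator

`generate_recording()` emulates one cuff deflation: pressure falls
linearly (default 3 mmHg/s — a typical clinical deflation — from
SBP + 30 mmHg down to DBP − 10 mmHg); Gaussian-windowed sinusoids
(centre frequency ~25–45 Hz, time constant 20 ms) fire at heart-rate
intervals with 3% jitter, *only* while DBP < pressure < SBP; sinusoidal
baseline wander and white noise overlay everything; and the recording
carries the true window as an annotation.

The beat-amplitude envelope is a Beta density on a sub-support of the
window, with two independently controllable properties:

* `envelope_peak_pos` places the amplitude-weighted mean of the envelope
  at a chosen fraction of the window — this directly controls the
  centre-of-mass feature;
* `envelope_skew` sets the signed asymmetry through the Beta shape pair
  $a = \tfrac{\nu}{2}(1 - \kappa s)$, $b = \tfrac{\nu}{2}(1 + \kappa s)$
  ($\nu = 6$, $\kappa = 0.62$, keeping both shapes > 1 so the density
  stays bounded and unimodal, and making the density skewness strictly
  monotone in $s$) — this controls the envelope-skewness feature.

The decoupling matters: within a *fixed* full-window density, location and
asymmetry are sign-coupled (a mean right of centre forces a longer left
tail), so a one-parameter envelope cannot produce cohorts where centre of
mass and skewness move in the *same* direction — which is exactly the
group structure of interest. A shiftable sub-support is the minimal
mechanism that frees the two.

`cohort_preset()` encodes three study conditions. The `young` and `older`
presets match their cohorts' demographics (ages 25.9 ± 2.2 vs 67.5 ± 6.7
years, matched BMI/BP/heart rate) and differ acoustically: young
recordings have amplitude mass later in the window with positive envelope
skew and a higher spectral band (42 ± 8 Hz vs 34 ± 5 Hz). Preset
dispersions were calibrated once so that the three discriminative
features show standardized effects of roughly $d \approx 1{-}1.7$ —
large enough that a 100 + 100 cohort flags them at the
Bonferroni-corrected 0.005 level essentially always, while keeping the
groups overlapping enough that a ten-feature logistic fit on ~200
recordings usually exists (at a few dozen recordings the synthetic groups
can be perfectly separable; `run_pipeline()` records that condition in
its report rather than aborting, since a diverging maximum-likelihood fit
is a legitimate statistical outcome of small separable samples). The
`hospital` preset draws a latent stiffness score $z \sim N(0,1)$ per
subject, couples it into the envelope and spectral parameters, and emits
baPWV from a linear covariate model
(`bapwv = 200 + 10 age + 5 SBP + 5 BMI + 80 diabetes + 100 z + N(0,120²)`,
cm/s), so covariate-adjusted regressions have a known truth to recover.

Per-subject seeds derive from the cohort seed by a fixed affine counter
scheme, giving bitwise reproducibility with independent subjects.

### What the generator does *not* emulate

It is phenomenological: no hemodynamic model of sound genesis, no sensor
transfer function, no motion artifacts, no inter-beat morphology changes,
Gaussian noise only. Passing tests therefore demonstrate that the
*analysis chain* is correct and well-calibrated — recovery of known
envelope asymmetry, location, spectral band, covariate structure — not
that real cohorts behave like the presets. Reported real-data accuracies
cannot be reproduced without the original recordings, and the package
does not attempt it.

## Statistics

`compare_groups()` reproduces the reference comparison protocol:
Kolmogorov–Smirnov normality per group, Levene's test (centred at the
mean) at 0.05 choosing pooled vs Welch t, pooled-SD Cohen's d, and flags
at `family_alpha / n_features` (0.05/10 = 0.005). `fit_logistic()` wraps
the IRLS maximum-likelihood fit and reports exactly the derived columns a
clinical table prints: Wald $\chi^2 = (\beta/\mathrm{SE})^2$,
OR $= e^\beta$, 95% CI $= e^{\beta \mp 1.959964\,\mathrm{SE}}$ (the
z value is fixed at 1.959964 because that reproduces printed CIs to their
last digit). `hosmer_lemeshow()` uses the canonical decile-of-risk
construction with $g - 2$ degrees of freedom — the convention confirmed by
back-computing the reported $\chi^2 = 6.601 \Rightarrow p = 0.580$.
Post-hoc power for Pearson correlations uses the Fisher-z normal
approximation at the observed r; published power columns for this design
are not reproducible under any standard formula, so the implementation is
validated by simulation (uniform null p-values; type-I and power
behaviour) rather than against printed values. `fit_adjusted()` z-scores
continuous variables (binary covariates stay 0/1) so slopes are
standardized betas, with VIF diagnostics.

Numerical/degenerate-input policy: zero-variance groups fall back to
Welch with a flag; probabilities must lie strictly in (0,1) for
calibration tests; aliased designs name the offending predictor;
perfect separation is detected by a diverging linear predictor
($|\eta| > 25$) and raised as an explicit error.

## Scalograms and the classifier

`cwt_scalogram()` is an analytic Morlet transform ($\omega_0 = 6$,
FFT-based, zero-padded to a composite length) on 64 log-spaced centre
frequencies in 5–100 Hz; magnitudes are linear in input amplitude.
`scalogram_to_rgb()` maps log-magnitude (relative floor 120 dB below the
peak, making the image exactly invariant to global amplitude scaling)
through per-image min–max normalization, bilinear resize, and a fixed
256-entry colour table, so images are bit-identical across runs and
backends.

The classifier is a compact from-scratch CNN — three 3×3 conv + ReLU +
2×2 max-pool blocks (8/16/32 channels), a 32-unit dense layer and a
softmax head (~23k parameters), Adam on cross-entropy — with the same
input/output contract as a large pretrained backbone but sized for
CPU-only, download-free training on 32×32 scalograms. Backpropagation is
verified against numerical differentiation. Datasets are split at the
*subject* level (stratified 70/15/15 by default), so a subject with
several recordings can never leak across splits.

## Problem sizes and reproducibility

The test suite and the acceptance script run complete analyses at
reduced but honest sizes chosen as the package's own defaults: cohorts
of 100 + 100 recordings across 10 seeds for calibration claims, 1000
replicates for family-wise error, 500 fitted models for
Hosmer–Lemeshow calibration, 40 three-second recordings for classifier
sanity. Every stochastic stage takes an explicit seed, derived from one
master seed by the documented counter scheme; identical configurations
reproduce every artifact bit-for-bit, and `run_pipeline()` writes a
manifest (config hash, seed, package version) alongside its outputs.

## Known limitations

* Absolute values of the frequency features depend on the generator's
  band placement; only signs, orderings and recovery of generator
  parameters are scientifically meaningful here. (Published frequency
  features in this area are often in ambiguous units; this package
  reports Hz and Hz² and leaves unit reconciliation to the user.)
* The envelope-weighted skewness saturates near ±0.4 for extreme shape
  parameters because threshold-based beat detection truncates thin
  envelope tails; the mapping from `envelope_skew` remains strictly
  monotone, which is what the recovery tests assert.
* The PCM-16 WAV path stores a peak-normalized waveform (documented
  headroom 0.99); absolute sensor units survive only in float-32 or CSV.
* The compact CNN is a correctness-scale model; it is not a substitute
  for large pretrained backbones on real data, and no claim about real
  recordings is made anywhere in the package.
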