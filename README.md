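# korosound

Korotkoff sounds — the bursts an artery emits while a blood-pressure cuff
deflates between systolic (SBP) and diastolic (DBP) pressure — carry
information about the mechanical state of the arterial wall. Stiffer
arteries respond differently to partial compression and pulsatile flow,
which plausibly shifts both *when* in the deflation window the loud beats
occur and *what* their spectral content is. korosound is an R package for
researchers in cardiovascular acoustics who want to test such hypotheses:
it implements the complete analysis chain from raw two-channel cuff
recordings (microphone + cuff pressure) to group statistics, correlation
with pulse-wave velocity, and a convolutional scalogram classifier — plus
a synthetic cuff-deflation generator with known ground truth, so every
stage is testable without access to clinical recordings.

## What it computes

For each recording, after baseline-drift removal (zero-phase Butterworth
high-pass), wavelet denoising (db6, soft universal threshold), Korotkoff
window location and beat segmentation, a ten-feature vector:

| feature | definition |
|---|---|
| max_amplitude | max&#124;x&#124; (sensor units) |
| kurtosis | fourth standardized moment of the beat-segment samples |
| skewness | amplitude-weighted temporal skewness of the beat envelope, Σwᵢ(tᵢ−μ)³ / (Σwᵢ(tᵢ−μ)²)^{3/2} |
| peak factor | max&#124;x&#124; / RMS (crest factor) |
| pulse factor | max&#124;x&#124; / mean&#124;x&#124; (= peak × form, exactly) |
| form factor | RMS / mean&#124;x&#124; |
| center of mass | Σwᵢtᵢ − t_mid: where the amplitude mass sits in the window (s) |
| peak frequency | argmax of the Welch PSD (Hz) |
| centroid frequency | Σf·P / ΣP (Hz) |
| mean-square frequency | Σf²·P / ΣP (Hz²), always ≥ centroid² |

with weights wᵢ = beat-peak amplitudes over beat-peak times tᵢ. The
statistics layer mirrors a clinical workflow: pooled/Welch t comparisons
chosen by Levene's test with Bonferroni control (0.05/10 = 0.005),
logistic regression reported as coefficient / SE / Wald χ² / OR / 95% CI
with Hosmer–Lemeshow calibration, Pearson correlation with Fisher-z
post-hoc power, and covariate-adjusted linear models (standardized betas,
VIF). The time-frequency layer produces analytic-Morlet CWT scalograms
exported as deterministic RGB images, and a compact from-scratch CNN
(~23k parameters, gradient-checked) classifies them with strict
subject-level splits.

## Worked example

```r
library(korosound)

# one synthetic cuff deflation: 120/78 mmHg, 3 mmHg/s, beats at 75 bpm
gen <- generate_recording(ground_truth_params(envelope_skew = 0.5,
                                              envelope_peak_pos = 0.55,
                                              seed = 42))
gen$recording
#> <koro_recording> subject=anon  27334 samples @ 1000 Hz (27.33 s)  + pressure channel  [window 10000,24000)

t(round(extract_features(gen$recording)[, feature_names()], 3))
#> max_amplitude            0.960
#> kurtosis                57.626
#> skewness                 0.294
#> peak_factor             11.874
#> pulse_factor            49.827
#> form_factor              4.196
#> center_of_mass           0.566
#> peak_frequency          36.000
#> centroid_frequency      36.767
#> mean_square_frequency 1408.153
```

The extracted skewness (+0.294) and centre of mass (+0.566 s) recover the
asymmetry and late placement this recording was generated with, and the
spectral moments sit at the generator's 37 Hz band. Comparing two
simulated cohorts the way a study would:

```r
young <- generate_cohort(cohort_preset("young"), 30, seed = 1)
older <- generate_cohort(cohort_preset("older"), 30, seed = 2)
fx <- rbind(extract_features_cohort(young$recordings),
            extract_features_cohort(older$recordings))
res <- compare_groups(fx[, feature_names()],
                      factor(rep(c("young", "older"), each = 30),
                             levels = c("young", "older")))
res[res$significant, c("feature", "mean1", "mean2", "test", "t", "p", "cohens_d")]
#>                feature    mean1    mean2     test    t        p cohens_d
#>               skewness    0.263   -0.251  Welch t 8.73 9.95e-12     2.25
#>         center_of_mass    0.852   -0.374 pooled t 4.32 6.16e-05     1.12
#>         peak_frequency   41.567   32.167 pooled t 4.92 7.54e-06     1.27
#>     centroid_frequency   41.879   32.798 pooled t 4.95 6.70e-06     1.28
#>  mean_square_frequency 1876.379 1171.528  Welch t 4.83 1.35e-05     1.25
```

Young cohorts show positive envelope skewness and centre of mass and a
higher spectral band; older cohorts the reverse — the group structure the
presets are calibrated to, flagged at the Bonferroni-adjusted 0.005
level. `run_pipeline(pipeline_config())` executes the whole chain
(simulate → features → statistics → scalograms → classifier) and writes
`features.csv`, `report.json`, classifier metrics and a reproducibility
manifest; `inst/cli/korosound.R` is a thin command-line wrapper over the
same functions. The methods vignette
(`vignettes/korotkoff-analysis.Rmd`) documents the models, the generator
design and every tunable.

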