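Package: korosound
Title: Korotkoff Sound Analysis for Arterial Stiffness Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing Korotkoff sounds recorded during cuff-based
    blood pressure measurement as a window on vascular ageing. Provides
    two-channel (microphone + cuff pressure) recording input/output, a
    synthetic cuff-deflation recording generator with known ground truth,
    preprocessing (baseline-drift removal, wavelet denoising, Korotkoff
    window detection, beat segmentation), a ten-feature acoustic
    characterisation including an amplitude-weighted temporal centre-of-mass
    statistic, continuous-wavelet-transform scalograms with RGB image
    export, a statistics pipeline (Welch/pooled t comparisons with
    Bonferroni control, logistic regression odds ratios with
    Hosmer-Lemeshow calibration, Pearson correlation with post-hoc power,
    covariate-adjusted linear models with variance inflation factors), and
    a compact convolutional scalogram classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    car,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
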