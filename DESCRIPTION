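Package: pipettefix
Title: Pipette Tip Localization and Closed-Loop Positional Correction for
    Automated Patch Clamp
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localizing patch-clamp pipette tips in DIC-like
    microscopy images and correcting micromanipulator positioning errors in
    closed loop. Provides a synthetic image generator with known ground-truth
    tip positions, the per-image contrast-stretch / crop / flip preprocessing
    pipeline, a compact convolutional regression network trained with RMSprop
    that predicts the (x, y, z) tip position, a normalized cross-correlation
    template-matching baseline, an iterative proportional feedback correction
    loop against a simulated manipulator, and the statistical evaluation layer
    (contingency-table comparisons, one-way ANOVA with Tukey HSD, and the
    D'Agostino skew/kurtosis normality test).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    png,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
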