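Package: strabscreen
Title: Strabismus Screening from Frontal Eye Images by Geometric and
    Embedded Feature Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens for strabismus (ocular misalignment) from frontal
    face photographs. Extracts per-eye regions around canthus landmarks,
    segments the iris by fusing Otsu and HSV value-channel thresholding,
    fits the limbus with an algebraic least-squares circle to estimate
    the pupil centre, and derives two geometric features: the
    position-similarity ratio S of the two irises and the Hirschberg
    corneal-light-reflex (CLR) ratio (D1+D3)/(D2+D4), with the reference
    ranges and missing-reflex imputation rules used in automated
    photo-screening. These are fused with PCA-reduced image embeddings
    (pluggable provider; deterministic seeded random projection by
    default) and classified with a linear support vector machine under a
    repeated random 15/15 split protocol reporting accuracy, sensitivity
    and specificity with 95% confidence intervals. A parametric synthetic
    eye-scene generator with exact ground-truth geometry makes every
    stage verifiable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
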