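Package: csvdseg
Title: Multi-Sequence MRI Segmentation of Cerebral Small Vessel Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testable re-implementation of a four-segmentor deep learning
    pipeline for cerebral small vessel disease (CSVD) on conventional brain
    MRI. Provides synthetic multi-sequence phantom generation with ground
    truth lesion masks (lacunes, white matter hyperintensities, recent small
    subcortical infarcts, cerebral microbleeds), white-matter histogram-peak
    intensity normalization, compact per-disease 2D U-Net segmentors with
    sequence routing and an overfitting-based stopping rule, pixel-level
    mask-exclusivity combination, and an evaluation suite (per-patient Dice,
    patch-discretized Dice, region-wise F1 and a binary-adapted FROC).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
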