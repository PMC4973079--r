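Package: fingerdecode
Title: Proportional Decoding of Individual Finger Activation from
    High-Density Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the activation level of individual
    fingers (index, middle, ring, little; flexion and extension) from
    high-density surface electromyography recorded with an 8 x 24
    electrode grid. Implements windowed RMS feature extraction, regular
    electrode-grid subsampling, and three proportional decoders: a
    multi-class common-spatial-patterns proportional estimator (CSP-PE)
    with pairwise filters and min-fusion, a pooled-covariance linear
    discriminant classifier with force-regression and MVC-scaled
    proportional back-ends, and a direct thresholding decoder on
    per-movement hotspot channel subsets. Includes force-cycle
    segmentation with outlier rejection, tracking outcome metrics
    (nMSE, Pearson correlation, mean amplitude of false activations,
    classification accuracy, one-vs-all sensitivity and specificity),
    and a synthetic HD-sEMG + fingertip-force session simulator with a
    closed-loop surrogate subject for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
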