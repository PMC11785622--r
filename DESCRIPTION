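Package: hciascreen
Title: High-Content Image Analysis Pipeline for Macrophage Drug-Response Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a high-content image analysis (HCIA) screening pipeline
    for macrophage drug-response profiling: per-cell abnormality scoring of ten
    cytotoxicity attributes against untreated-control baselines (mean +/- 2 SD
    thresholds), a quartile-based four-category treatment-response
    classification with a detachment exclusion rule, and hierarchical
    clustering of compound response profiles (Euclidean metric, Ward linkage).
    Ships a synthetic plate simulator with known ground truth (planted abnormal
    fractions, dose-dependent detachment) emulating murine J774A.1 and primary
    human alveolar macrophage screens, plus an optional synthetic imaging
    front-end (render, segment, re-extract) for validating the measurement
    path.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    readr,
    ggplot2,
    pheatmap,
    jsonlite,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
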