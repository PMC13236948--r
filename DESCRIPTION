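Package: fieldshift
Title: Reliability Characterization for Image Classifiers Under
    Controlled-to-Field Domain Shift
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing the reliability of classifiers that are
    trained on controlled laboratory imagery and deployed on heterogeneous
    field imagery. Implements post-hoc temperature scaling with calibration
    diagnostics (reliability tables, expected calibration error, Brier
    score), selective prediction with fixed-coverage and fixed-risk
    threshold transfer, open-set scoring of unknown categories (MSP,
    entropy, margin, energy; AUROC, AUPR, FPR95), ensemble
    epistemic-aleatoric uncertainty decomposition via mutual information,
    leakage-safe parent-image-aware data splitting with Hungarian crop
    matching, model-free domain-shift quantification through image
    descriptors with paired effect sizes, and channel-wise feature moment
    matching. A synthetic-cohort generator reproduces the statistical
    structure of a controlled-to-field study so the full protocol is
    testable end to end without external data.
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
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
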