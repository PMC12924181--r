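Package: oxifinger
Title: Deterioration Biomarker Fingerprints for Cold-Pressed Oil Storage Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for storage-stability studies of cold-pressed
    vegetable oils. Provides a long-format concentration data model with
    below-LOQ censoring, a synthetic storage-study generator (first-order
    fatty-acid decay, class-dependent polyphenol depletion, lagged exponential
    volatile accumulation, supplier and bottle-replicate noise), compositional
    preprocessing (centered log-ratio transform, z-score scaling,
    forward/backward imputation, Grubbs outlier screening, PCA summaries),
    three-model feature selection against storage time (LASSO coefficients,
    random-forest importances, Spearman correlation), weighted min-max
    composite biomarker scoring with ranked fingerprint tables, and
    pseudo-first-order kinetics for volatile oxidation products together with
    ANOVA/Tukey compact-letter summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    glmnet,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
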