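Package: connstab
Title: Bootstrap-Stable mRMR Selection and Nested Cross-Validated
    Classification of Connectome Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Subtype-discovery analysis for functional-connectivity and
    morphometric features: Fisher r-to-z connectivity feature engineering
    with motion QC and age/sex control, bootstrap-aggregated minimum
    redundancy maximum relevance (mRMR) feature selection with a
    selection-frequency threshold sweep, repeated nested cross-validated
    SVM-RBF classification of clinically defined subgroups, major-feature
    identification with direction and network annotation, multiple linear
    regression of verbal-memory scores on selected features with FDR
    control, and confound screens. Includes a synthetic-cohort generator
    with planted differential edges so the full pipeline can be exercised
    and calibrated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
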