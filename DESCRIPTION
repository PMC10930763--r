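Package: wsiSurrogate
Title: Surrogate Gene-Expression Biomarkers from Whole-Slide Image Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts per-sample gene expression from bags of whole-slide-image
    patch features with an attention-based multiple-instance-learning (AMIL)
    regressor, and evaluates overall survival from the predicted expression.
    Includes tile extraction with Canny-based background filtering and Macenko
    stain normalization, site-preserved quantile-balanced cross-validation,
    prognostic screening via covariate-adjusted Cox regression with
    proportional-hazards filtering and Benjamini-Hochberg correction,
    cross-validated concordance evaluation of surrogate biomarkers, and
    Kaplan-Meier risk-group stratification. A synthetic cohort generator with
    planted image-expression-survival structure makes the full pipeline
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    survival,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    png,
    EBImage,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
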