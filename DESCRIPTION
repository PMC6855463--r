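Package: clonalGS
Title: Genomic Selection for Clonally Propagated Crops with
    Population-Structure-Aware Cross-Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-stage genomic selection analysis in clonal
    crops such as cassava. Stage one fits a clonal mixed model to
    multi-environment trial data and produces deregressed BLUPs; stage
    two runs five whole-genome prediction methods (RR-BLUP, G-BLUP,
    Gaussian-kernel RKHS, BayesB and the Bayesian LASSO) on marker
    dosages, with marker quality control, additive and Gaussian kernel
    construction, DAPC population-structure inference, four
    structure-aware cross-validation designs, and method-comparison
    statistics (deviance analysis with Tukey mean separation, GEBV
    correlations and Cohen's kappa selection coincidence). A seeded
    simulator of structured genotypes and clonally replicated trials
    supports testing and power studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    lme4,
    Matrix,
    MASS,
    coda,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
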