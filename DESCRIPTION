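Package: declinesig
Title: Multi-Compartment Proteomic Signature Discovery for Rapid Lung Function Decline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers multivariate protein signatures that prospectively classify
    COPD participants at risk of accelerated FEV1 decline from paired blood and
    bronchoalveolar lavage (BAL) proteomic panels. Implements balanced-resample
    elastic-net selection-frequency ranking feeding step-forward partial least
    squares discriminant analysis (PLSDA) with k-fold cross-validated signature
    selection, random-signature null comparison, correlated ROC/AUC comparison by
    the Hanley-McNeil method, detection-limit censoring and filtering rules for
    multiplex immunoassay panels, PCA profiling with Hotelling reduced-T2 outlier
    screening and permutation tests, and Spearman-distance hierarchical clustering.
    Includes a synthetic cohort generator emulating the two-visit spirometry and
    two-compartment panel structure the analysis assumes, so the entire pipeline
    runs and is testable without access to restricted study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    multcomp,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
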