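Package: survSig
Title: Derivation and Survival Validation of Knockdown-Influenced Prognostic Gene Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: A tested pipeline for deriving a prognostic gene-expression
    signature from gene-knockdown experiments and validating it on survival
    cohorts. Implements matrix-level expression filtering (presence,
    unique-annotation, sex-chromosome), SAM-style moderated differential
    expression with permutation q-values, paired t-tests with
    Benjamini-Hochberg adjustment, concordant cross-dataset signature
    derivation, a Wald-weighted standardized risk score with median or zero
    cutoffs, Kaplan-Meier/log-rank and Cox proportional-hazards validation
    (univariate, multivariate and stratified), a size-matched random-signature
    resampling null, and Fisher's exact gene-set over-representation.
    Ships a synthetic-data generator with planted ground truth so the whole
    workflow is testable end-to-end without external downloads.
License: MIT + file LICENSE
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
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
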