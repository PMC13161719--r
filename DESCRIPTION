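Package: refsig
Title: Recursive Ensemble Feature Selection and Cross-Cohort Signature
    Validation for Microbiome ASV Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Biomarker discovery for 16S rRNA amplicon sequence variant (ASV)
    count tables. Implements recursive ensemble feature selection (REFS), in
    which an ensemble of eight heterogeneous classifiers is trained under
    stratified 10-fold cross-validation, per-classifier feature importances
    are aggregated, and the least informative features are iteratively
    eliminated until the smallest feature set attaining the maximal
    cross-validated accuracy remains. Selected signatures are graded by a
    five-classifier AUC-ROC validation module, transferred to independent
    cohorts by exact nucleotide-sequence containment (short-region amplicons
    located inside longer-region ones, summing abundances over multiple hits),
    and summarised as group-mean relative-abundance direction matrices. A
    synthetic multi-cohort generator with planted discriminative ASVs, cohort
    batch effects and nested sequence regions provides ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    glmnet,
    jsonlite,
    nnet,
    ranger,
    rpart,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
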