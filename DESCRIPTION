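Package: guidefp
Title: Interaction-Fingerprint Scoring and Optimization of CRISPR Guide RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Position-dependent RNA-DNA interaction fingerprints for
    CRISPR-Cas9 guide/off-target pairs, built from a per-base-pair-type
    feature table. Provides exhaustive PAM-constrained k-mismatch genome
    scanning, gradient-boosted off-target classification with tree-SHAP
    attribution, a Shapley-derived per-position scoring function with exact
    affine calibration to [0, 1], a genome-wide specificity aggregator, and
    a single-nucleotide guide optimizer. A seeded synthetic-data layer
    (feature tables, genomes, imbalanced labeled candidate sets, bin
    probability tables) makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
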