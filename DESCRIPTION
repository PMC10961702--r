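Package: ARbattery
Title: Optimal Minimal Assay Batteries for Androgen Receptor Bioactivity Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Data-processing workflow for deriving optimal minimal in vitro
    assay batteries for androgen receptor (AR) agonism and antagonism
    prioritization from a comprehensive 14-assay pathway model. Provides
    subset-model nomenclature parsing and enumeration, pathway-AUC
    binarization, sensitivity/specificity qualification of subset models
    against the full-model reference, minimal-battery union optimization with
    constrained and assay-exclusion variants, Tanimoto/Ward chemical-structure
    clustering with 1-nearest-neighbour assignment and cluster activity
    labeling, a volatility filter, tiered-testing cost accounting, and a
    multi-stage Monte-Carlo testing simulation. A synthetic-data generator
    emulates all required inputs (hit-call matrices, surrogate pathway AUC
    tables, structural fingerprints, QSAR-like predictions) so the whole
    workflow runs without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vegan,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
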