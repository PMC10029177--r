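Package: cnvpatho
Title: Deleteriousness-Based Pathogenicity Classification of Copy Number Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates copy number variants (CNVs) with a direction-aware
    deleteriousness feature vector (79 features by default, spanning site-level
    scores, gene-level constraint scores, genomic-element counts, candidate
    cis-regulatory elements and dosage-sensitivity genes), curates multi-source
    CNV call sets with explicit per-database filters and reciprocal-overlap
    merge rules, trains gradient-boosted five-tier (ACMG scale) and binary
    pathogenicity classifiers separately for loss and gain CNVs, and evaluates
    and explains them (ROC/AUC, balanced accuracy, TreeSHAP attributions,
    nonparametric feature-distribution statistics). A synthetic-fixture
    generator produces toy genomes, annotation bundles and labelled CNV sets
    with planted pathogenicity signal so the whole pipeline runs without
    external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    xgboost,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
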