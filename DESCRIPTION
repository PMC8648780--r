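Package: mgwas
Title: Metagenome-Genome-Wide Association Analysis for Microbiome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for metagenome-genome-wide association
    (mgGWAS) analysis: filtering and log-transforming taxon relative
    abundances into quantitative traits, greedy correlation-graph selection
    of independent taxa, per-variant linear/logistic/multivariate
    association scans with genomic-inflation diagnostics and LD clumping,
    cross-cohort replication with resampling-based enrichment testing,
    Bray-Curtis diversity and distance-based redundancy analysis for
    genetics-versus-environment variance partitioning, and cross-validated
    unweighted polygenic risk scores for binary disease prediction. A
    synthetic-cohort generator with planted SNP-taxon effects, correlated
    taxon clusters, zero inflation, collinear environmental covariates and
    liability-threshold diseases makes every stage testable without access
    to controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    vegan,
    vcfR,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
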