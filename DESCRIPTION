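Package: diffmut
Title: Differential Mutation Analysis of Somatic and Germline Cohorts
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies putative cancer driver genes by comparing each
    gene's rank-normalized somatic mutation profile across a tumor cohort
    against its rank-normalized germline variation profile across a healthy
    cohort.  Per-individual gene mutation counts (from MAF files) and
    summed germline variant dosages (from multi-sample VCF files) are rank
    normalized, aggregated into per-gene score histograms, and compared
    with a unidirectional Earth Mover's Difference (uEMD).  Significance is
    assessed with permutation-decoy empirical false discovery rates and
    q-values.  Includes an evaluation harness (top-k fraction, AUPRC with
    exclusion-aware negatives, covariate correlation) and a synthetic
    paired-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
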