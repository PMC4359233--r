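Package: pol2regulon
Title: POL II Promoter Occupancy, Poised-Gene Classification and
    Cross-Cohort Concordance for HER2-Stratified Expression Data
Version: 0.1.0
Authors@R:
    person("Farrah", "Okonkwo", email = "farrah.okonkwo@example.org",
           role = c("aut", "cre"))
Description: Calls RNA polymerase II (POL II) promoter binding from
    tiling-array ChIP-chip probe triples using a neighborhood model,
    combines site-level p-values into gene-level joint (Fisher) and
    geometric-average probabilities, and computes a promoter-proximal
    stalling index.  Re-implements empirical-Bayes moderated-t
    differential expression, quantile normalization, per-gene
    standardization and multi-cohort merging with quantile
    stratification on a marker gene.  Quantifies directional
    concordance between differential-expression analyses with Cohen's
    kappa against a permutation null, tests gene-list overlaps by
    resampling, and classifies genes into a binding regulon, regulated,
    concordant, poised and tissue-context-dependent classes.  Includes
    a synthetic-data generator with planted ground truth so the whole
    pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
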