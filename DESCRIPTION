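Package: xconcord
Title: Cross-Model Transcriptome Concordance Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential expression and cross-dataset concordance analysis
    for paired mouse-model (or cross-species) transcriptome studies.
    Implements empirical-Bayes moderated t-tests with Benjamini-Hochberg
    false discovery rate control, per-gene genotype-by-time ANOVA with
    trajectory pattern classification (up / no-change / down), ortholog
    collapsing and ranked top-list overlap statistics (hypergeometric and
    permutation), direction-split rank-bin concordance profiles,
    genotype-by-model interaction testing, and conditional hypergeometric
    over-representation analysis on a gene-set DAG with term-similarity
    clustering. Includes a seeded synthetic-data generator that emulates a
    paired two-model striatal time-course design (two genotypes, three ages,
    replicated cells) with planted differential expression, temporal
    trajectories and enrichment signal, so every stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
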