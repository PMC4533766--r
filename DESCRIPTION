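Package: dgeatlas
Title: Digital Gene Expression Atlas Analysis for Organ and Ripening
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for digital gene-expression profiling of multi-library
    transcriptome atlases from non-model plants. Provides RPKM
    normalization of read-count matrices, a multi-library log-likelihood
    ratio statistic (R) for calling preferentially expressed,
    organ-specific and ubiquitous genes, rule-based classification of
    three-stage climacteric fruit-ripening trajectories (classes I-V),
    hierarchical clustering and principal-component ordination of organ
    expression profiles, redundancy elimination and length filtering for
    unigene-set construction from assembled contigs, and seeded
    synthetic-data generators with planted ground truth for validating
    every step.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
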