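Package: crossbind
Title: Integrating Multi-Factor ChIP-Seq Differential Binding with
    RNA-Seq Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to integrate differential transcription-factor binding
    (ChIP-seq peak tables with treated and control signal) with differential
    gene expression (fold-change tables with posterior probabilities).
    Implements differential peak-enrichment classification, TSS-anchored
    intragenic annotation and closest-gene assignment, peak overlap and
    center-distance analysis, DEG calling, gene-level multi-factor
    binding-pattern classification, over-representation analysis by one-sided
    Fisher's exact test with Benjamini-Hochberg correction, preranked gene-set
    enrichment analysis with a permutation null, and position-weight-matrix
    motif enrichment against background sequences. A synthetic-data generator
    with planted ground truth (intragenic fractions, fold-change
    distributions, pattern-expression coupling, gene-set enrichments, motif
    plant rates) makes every stage testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    graphics,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
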