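Package: cistromeShift
Title: Quantifying Redistribution of Transcription-Factor Cistromes After
    Induced Binding of a Pioneer-Recruiting Factor
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for asking how induced binding of one
    transcription factor redistributes the genomic binding of others, and how
    those binding changes couple to gene expression. Provides replicate
    consensus peak calling (k-of-n per-base support), a moderated-t test for
    differential binding on region read counts with gained/lost site
    classification at a stated FDR, position-weight-matrix scanning with
    positional centrality profiles around peak summits, genomic-context
    enrichment as odds ratios with exact tests (repeat classes, enhancers,
    super enhancers, HOT regions, open chromatin), co-binding combination
    counts and phi-correlation cofactor selection, a weighted
    Kolmogorov-Smirnov rank-enrichment engine with gene-set permutation
    nulls, and a bidirectional matched primary/metastasis expression design.
    A fully deterministic synthetic-data generator with planted ground truth
    (replicate peak reproducibility, negative-binomial counts with planted
    differential binding, motif-bearing repeats, binding-coupled expression)
    exercises the whole pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    fgsea
Config/testthat/edition: 3
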