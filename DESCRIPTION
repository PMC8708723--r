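Package: crenet
Title: Integrative ChIP-seq and RNA-seq Inference of Cis-Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for placing a transcription factor inside a regulatory
    network from ChIP-seq and RNA-seq data: replicate-consensus peak
    selection, SCREEN-style candidate cis-regulatory element (cCRE)
    classification and class distributions, transcription-factor
    co-occupancy scoring with Spearman correlation clustering, GREAT-style
    basal-plus-extension peak-to-gene association, directed TF-to-target
    network inference restricted to promoter- and enhancer-like elements,
    expression-side integration (CPM, low-expression filtering, trimmed
    mean of M-values normalization, Z-score clustering, differential
    expression thresholds, bound-vs-regulated overlap statistics), and
    IUPAC consensus motif scanning with dinucleotide-shuffle background
    enrichment tests. A deterministic synthetic-data module generates
    multi-factor peak sets, signal tracks, annotation landscapes, count
    matrices and sequences with planted ground truth so every stage is
    testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    edgeR,
    igraph,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
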