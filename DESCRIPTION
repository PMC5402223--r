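Package: ratioGO
Title: Ratio-Threshold Differential Expression and Log2 GO Enrichment
    Scoring for Two-Condition Ovary Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a two-condition bulk RNA-seq
    comparison pipeline as used for premature versus mature ascidian
    ovaries: prefix-bucketed PCR-duplicate removal from FASTQ reads,
    FPKM quantification with replicate averaging, expressed-gene
    filtering and fold-change-threshold classification of differential
    expression, a log2 frequency-ratio GO-term enrichment score with a
    fixed pseudo-count computed over is_a-propagated annotations, a
    Cytoscape-oriented enrichment-graph export with level and gene-count
    visibility rules, and delta-Ct qPCR fold-change quantification.
    Ships a synthetic-data generator with known ground truth (planted
    fold changes, planted GO-term frequency skews, planted PCR-duplicate
    clusters) so every stage is testable end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
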