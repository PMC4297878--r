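Package: ampscan
Title: Promoter Co-Occupancy and Transcriptional Amplification Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for POLII-anchored promoter occupancy analysis of
    transcription-factor ChIP-seq data and for detecting transcriptional
    amplification of target-gene programs in RNA-seq. Calls per-gene factor
    binding in fixed promoter windows around transcription start sites with a
    Poisson enrichment test and Benjamini-Hochberg FDR control, derives
    co-occupancy target-gene sets and overlap statistics, builds
    quantile-normalized TSS metaprofiles, quantifies amplification of target
    genes via RPKM fold summaries, median/MAD heatmap normalization and a
    cumulative-distribution shift test (Welch's t on log10 RPKM), compares
    transcriptomes by Spearman correlation, average-linkage clustering,
    differential expression and hypergeometric gene-set enrichment, analyses
    bisulfite clone sequencing of regulatory regions (CpG calls, lollipop
    matrices, percent methylation), and provides small-sample quantifications
    (labeled-cell fractions with Wilson intervals, population composition,
    transcript-fraction partitioning, growth-curve doubling time). A
    synthetic-data module generates every input with recorded ground truth so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
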