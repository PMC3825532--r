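Package: dmrcap
Title: Differential Methylation Region Discovery from Methyl-Capture Tags
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for methyl-capture sequencing of group-structured
    designs: Poisson sliding-window enrichment calling of candidate regions over
    all pairwise sample comparisons (fixed tag shift, local-background lambda),
    interval merging, tag counting, centile filtering, trimmed-mean (TMM)
    normalization, a shrunken negative-binomial exact test with
    Benjamini-Hochberg adjustment, genomic-feature overlap enrichment
    (conditional maximum-likelihood log2 odds ratios with exact confidence
    intervals and Fisher's exact test), preranked gene-set enrichment analysis
    with interval-derived gene sets, and validation statistics for bisulfite
    clone sequencing and qPCR delta-delta-Ct quantification. Includes a
    synthetic-data generator (toy genomes, capture tags, coupled expression
    counts, bisulfite clones, qPCR plates) so the whole workflow is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    fgsea,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
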