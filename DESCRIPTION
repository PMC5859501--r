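Package: crmpeaks
Title: Differential Chromatin Accessibility Analysis for Cis-Regulatory
    Module Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of a differential
    chromatin-accessibility pipeline for discovering lineage-specific
    cis-regulatory modules from ATAC-seq and DNase-seq peak calls:
    reference-peak-set construction by non-reciprocal overlap, FRiP and
    replicate-concordance quality gates, a negative-binomial Wald test for
    differential peaks, cross-assay merging of differential peaks,
    peak-to-gene annotation with five location categories, Fisher-exact
    enrichment statistics, and PWM motif scanning with a two-step
    shuffled-control enrichment test. A synthetic-data module generates a
    toy genome, gene models, replicate peak calls, negative-binomial count
    matrices with planted effects, and planted motifs, so the full
    pipeline is testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
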