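Package: tfinfer
Title: Infer Influential Transcription Factors and Their Targets from
    ATAC-seq, ChIP-seq and RNA-seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A species-agnostic toolkit for regulatory genomics: links
    ATAC-seq/ChIP-seq peaks to genes under nearest-gene, gene-scan and
    gene-bound annotation strategies; scores links by correlating peak
    accessibility with gene expression (or distal peaks with promoter
    peaks) across samples; computes regulatory-potential (RP) profiles
    with an exponential distance-decay model from coverage tracks,
    peak-count matrices or TF ChIP-seq peaks; calls direct TF targets by
    combining RP ranks with differential-expression ranks via rank
    product; and ranks influential transcription factors for a query
    gene or peak set with six complementary statistics (Fisher and
    Wilcoxon enrichment, target-pair over-representation, TSS-proximal
    hit counts, attributable region-RP, and motif activity response
    analysis by ridge regression). Includes a synthetic-data generator
    with planted signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
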