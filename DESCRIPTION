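Package: dnfindex
Title: Exon-Level Domain-Imbalance Profiling and DNF-Index Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for exon-level expression-imbalance analysis of CIZ1-style
    two-domain genes in tumor cohorts. Computes per-exon TPM profiles
    anchored to a reference exon, the anchor-domain to replication-domain
    (AD:RD) DNF index with A-D group segmentation, a from-scratch two-group
    negative-binomial Wald differential-expression test with median-of-ratios
    size factors and Benjamini-Hochberg FDR, pi-value gene ranking, 10-Mb
    sliding-window positional cluster enrichment with lncRNA/coding biotype
    partitioning, hypergeometric gene-set overlap enrichment, and
    comparative-Ct (2^-ddCt) qPCR quantification. Includes seeded synthetic
    generators for every input (exon-level counts with an internal
    transcription start site, cohorts with planted ratio regimes, genomes
    with planted UP-gene clusters, two-group count matrices with planted
    fold changes, and coupled qPCR amplicon panels) so the full pipeline is
    testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    MASS,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
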