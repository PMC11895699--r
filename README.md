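# dnfindex

Exon-level domain-imbalance profiling and DNF-index segmentation for
two-domain genes, built around the breast-cancer biology of CIZ1.

CIZ1 is a nuclear protein whose N-terminal **replication domain (RD)** is
encoded by 5' exons (sampled at exons 5 and 7) and whose C-terminal
**anchor domain (AD)** is encoded by 3' exons (sampled at exons 14 and 16).
In tumors, a C-terminal dominant-negative fragment (DNF) can be expressed
from an internal transcription start site within exon 10, elevating AD
transcript levels over RD levels. This package quantifies that imbalance
from per-exon read counts and follows it through the downstream analyses a
tumor-cohort study needs — cohort segmentation, differential expression,
positional clustering of affected genes, gene-set overlap and qPCR
validation — with seeded synthetic generators standing in for
controlled-access tumor data.

## The statistics at the core

* **Within-gene exon TPM.** For exon *e* with length *L<sub>e</sub>* and
  count *c<sub>e</sub>*, rate *r<sub>e</sub>* = *c<sub>e</sub>* /
  *L<sub>e</sub>* and TPM<sub>e</sub> = *r<sub>e</sub>* / sum(*r*) x 10^6.
  Profiles can be anchored to a reference exon (exon 2 or exon 7 styles).
* **DNF index.** ratio = TPM<sub>ex14</sub> / TPM<sub>ex5</sub> per sample,
  segmented as **A** (> 2), **B** (1.1–2], **C** [0.9–1.1], **D** (< 0.9);
  per-stratum group profiles are compared with a goodness-of-fit
  chi-squared test.
* **Two-group NB Wald test.** Median-of-ratios size factors,
  method-of-moments dispersions with optional trend shrinkage
  (variance mu + phi mu^2), delta-method standard error of log2FC, normal
  reference; Benjamini–Hochberg q-values; UP/DN calls at |log2FC| >= 1 and
  q < 0.05; pi = log2FC x (-log10 q) ranking. The same test serves gene
  counts and ATAC consensus-peak counts.
* **Positional clustering.** 10-Mb windows sliding at 1 Mb; per-category
  fold enrichment of window density over chromosome-average density;
  clusters are merged runs of windows with UP-coding enrichment >= 2 vs
  chromosome, >= 2 vs local gene density, and >= 5 UP genes; lncRNA/coding
  partition with exact Clopper–Pearson intervals; hypergeometric gene-set
  overlap with BH correction.
* **Comparative Ct.** RQ = 2^-ddCt calibrated per amplicon, Welch t tests
  between amplicons per stage, Pearson correlation between amplicons on
  the log2(RQ) scale.

## Worked example

```r
library(dnfindex)

## a 90-tumor cohort with three planted regimes of mean AD:RD ratio
sim  <- simulateCohort(CohortSimSpec(groupSizes = c(30, 30, 30),
                                     meanRatios = c(2.5, 1.0, 0.7),
                                     seed = 42))
prof <- normalizeToAnchor(computeExonTpm(sim$counts), anchor = 7)
dnf  <- computeDnfIndex(prof)
table(dnf$group)
#>  A  B  C  D
#> 30  1 29 30
head(dnf, 3)
#>      sample_id ratio group excluded reason
#> S001      S001  2.61     A    FALSE   <NA>
#> S002      S002  2.49     A    FALSE   <NA>
#> S003      S003  2.47     A    FALSE   <NA>
```

The planted regimes (30 samples each at ratios 2.5 / 1.0 / 0.7) come back
as 30 A, 29 + 1 C/B and 30 D: one balanced sample fell just above the
1.1 boundary, the rest classify into the planted groups.

```r
## differential expression with 40 planted features (|log2FC| = 2)
planted <- setNames(c(rep(2, 20), rep(-2, 20)), sprintf("f%05d", 1:40))
deg <- simulateDegCounts(DegSimSpec(nFeatures = 500, nPerGroup = c(20, 20),
                                    baselineMeans = rep(200, 500),
                                    dispersion = 0.1,
                                    plantedLog2Fc = planted, seed = 43))
de <- runDeAnalysis(deg$counts, deg$condition)
table(de$direction)
#>  UP  DN  NS
#>  20  20 460
head(piRank(de)[c("feature_id", "log2FC", "q", "direction", "pi")], 3)
#>   feature_id log2FC        q direction  pi
#> 7     f00007   2.23 8.63e-55        UP 120
#> 4     f00004   2.05 1.68e-53        UP 108
#> 8     f00008   2.17 3.24e-48        UP 103
```

All 40 planted features are recovered with the correct direction and no
false calls among the 460 null features; the pi ranking puts the strongest
planted effects first.

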