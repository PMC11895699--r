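---
title: "Methods: exon-level domain imbalance, the DNF index, and downstream analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exon-level domain imbalance, the DNF index, and downstream analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnfindex)
```

# The problem

CIZ1 is a two-domain nuclear protein: 5' exons encode the replication
domain (RD), 3' exons the anchor domain (AD). An internal transcription
start site within exon 10 can produce a C-terminal fragment that acts as a
dominant negative on CIZ1-RNA assemblies. In expression data this shows up
as 3' exon coverage exceeding 5' exon coverage within the same gene. The
package measures that imbalance per sample, segments cohorts by it, and
carries the segmentation through the downstream comparisons such a study
makes. Because the motivating tumor datasets are controlled-access, every
input has a seeded synthetic generator with planted ground truth; the test
suite and the acceptance script run entirely on generated data.

# Exon profiles and the DNF index

## Within-gene TPM

Per-exon counts are length-corrected (`rate = count / length`) and scaled
to sum to 10^6 within the gene. This is a deliberate, documented deviation
from library-wide TPM: only one gene's profile is analyzed, and both the
anchor normalization and the AD:RD ratio divide one exon's value by
another's, so any transcriptome-wide constant cancels. The choice makes
the analysis self-contained — no whole-transcriptome quantification is
needed to study one gene's internal balance.

Anchor normalization divides each exon's TPM by the anchor exon's TPM.
Two anchor conventions are in use for CIZ1 — the first translated exon
(exon 2) for cell-line profiles and mid-RD exon 7 for tumor-cohort work —
and no rule selects between them, so the anchor is a parameter
(`normalizeToAnchor(profiles, anchor)`, default 7). Samples with zero
anchor TPM are flagged excluded with a reason rather than dropped or
errored: exclusions are data, and group profiles report them separately.

## The DNF index and groups A-D

The index is `TPM(exon 14) / TPM(exon 5)` (AD over RD), computed on raw
within-gene TPM; the anchor cancels, so anchor-normalized values give the
identical ratio. Group boundaries follow the published segmentation with
the printed ranges made airtight: the printed bounds ("exceeds 2",
"1.1-1.99", "within 0.9-1.1", "< 0.9") leave the points 0.9, 1.1 and 2.0
ambiguous. The package adopts

* A = (2, Inf) — "exceeds 2" honored strictly, so a ratio of exactly 2 is B;
* B = (1.1, 2];
* C = [0.9, 1.1] — closed, so boundary ties fall to the conservative
  "balanced" call;
* D = (0, 0.9).

Every positive finite ratio receives exactly one label (property-tested).
Samples with zero RD signal are excluded with reason `"zero RD signal"`.

## Stratum profiles and the chi-squared comparison

`cohortProfile()` tabulates A-D counts and proportions per stratum
(stage, subtype, ...). Each stratum is compared to the cohort-wide profile
with a goodness-of-fit chi-squared: expected counts are cohort proportions
times stratum size, the statistic sums `(obs - exp)^2 / exp` over groups
with positive expectation, and df is that group count minus one. This
"similarity to the cohort profile" reading (one-sample goodness of fit,
not a 2x4 independence test) matches how the comparison is described for
stage strata; groups absent from both are dropped, and a positive
observation against zero expectation is reported as a degenerate p = 0
rather than an error. Strata with fewer than ~5 expected per cell warn
about the approximation.

## Coverage transitions

`detectInternalTss()` locates a single changepoint in an ordered coverage
vector by exhaustive scan of the least-squares criterion
`n1 n2 / n (m2 - m1)^2`, with a minimum segment length (default 3 bins)
and a transition call only when the downstream/upstream mean ratio leaves
`[1/1.5, 1.5]`. Binary segmentation with a single breakpoint is the
package's own choice — the original observation located the transition by
inspection — and the threshold 1.5 marks a 50% coverage shift, well above
Poisson noise at the coverage this gene shows. A flat profile returns "no
transition"; an upstream mean of zero gives ratio Inf (a transition).

# Synthetic generators: what they emulate

All generators are pure functions of their spec (every spec carries a
`seed`); identical specs give bit-identical output, and planted truth is
always returned alongside the data.

## Exon counts (`ExonSimSpec`, `simulateExonCounts`)

Two transcripts: a full-length one covering all exons at abundance
`baseAbundance` (reads per bp at library scale 1, default 8 — several
hundred reads per exon, deep coverage of a well-expressed gene), and an
internal-TSS transcript covering exons >= 10 at abundance `alpha`.
Expected counts are `libScale x length x (base + alpha [e >= tss])`;
library scales are log-normal with CV `librarySizeCv` (default 0.2,
realistic depth variation).

Overdispersion is realized as a gamma-mixed Poisson with **one gamma
factor per sample shared across the gene's exons**. Marginally each exon
count is exactly NB with the requested dispersion (default 0.05, a
typical biological-replicate value), but within-gene exon:exon ratios
carry only Poisson noise. This is the scientifically right dependence
structure: all exons of a gene are read from the same transcript pool, so
gene-level biological variability (tumor purity, overall expression
state) moves them together and cancels in the AD:RD ratio. Had the exons
been drawn as independent NB variables, the ratio's CV would be about
`sqrt(2 x dispersion)` (~32% at dispersion 0.05) and the +/-10% group-C
band could never be recovered reliably — no cohort study could have
segmented tumors this way if within-gene ratios were that noisy.

`alpha` may be negative down to `-baseAbundance` (exclusive), modelling
3'-depleted profiles; without this the generator could not produce the
D-group tumors (ratio < 0.9) that the segmentation defines.

The default exon model (`ciz1ExonModel()`) uses synthetic lengths of
realistic magnitude for the 16 translated exons (ids 2-17); they are
labelled synthetic in the documentation, and every ratio-based analysis
is invariant to them because counts are length-corrected.

## Cohorts (`CohortSimSpec`, `simulateCohort`)

Regimes are parameterized by their target mean AD:RD ratio (the
internal-TSS abundance is derived as `alpha = (ratio - 1) x base`), which
is the quantity the analysis measures. Defaults plant three regimes of
100 samples at ratios 2.5 / 1.0 / 0.7 — a cohort whose expected groups
are A / C / D with comfortable margins to the boundaries, sized so that
recovery is informative (300 tumors) while running in seconds. Stages are
sampled uniformly from I-IV when not given.

## Genomes (`GenomeSimSpec`, `simulateGenome`)

Background genes are placed uniformly per chromosome (counts split by
length), with direction labels at rates taken from the observed cohort
statistics this package models: ~5.6% of genes differentially expressed,
15% of those UP and 85% DN, with 38% of UP and 4% of DN genes lncRNAs
(all overridable). Planted clusters add UP genes inside their interval so
local UP density reaches `clusterDensityFold` times background, with
lncRNA share `clusterLncRNAFraction` (default 0.38). Genes are points at
their start coordinate for all density purposes, matching how positional
maps are plotted; gene extents and strand are carried but ignored by
window computations. Defaults use a 3 x 200 Mb genome with 3,300 genes
(~5.5 genes/Mb, the right order for a gene-rich genome slice).

## Count matrices (`DegSimSpec`) and qPCR panels (`QpcrSimSpec`)

DE counts are independent NB per feature (`variance = mu + phi mu^2`,
dispersion 0 special-cased to Poisson), log-normal baselines, log-normal
library scaling to exercise size-factor estimation, and planted signed
log2 fold changes applied in group 2. qPCR panels draw per-sample latent
log2 abundances from a multivariate normal whose correlation matrix
encodes amplicon coupling — RD pair (ex5, ex7) at 0.95, AD pair (ex14,
ex16) at 0.95, RD-AD uncoupled — then `Ct = referenceCt - log2 abundance
+ noise` (0.25 cycles technical noise). An optional per-stage step
elevates the AD amplicons with stage.

What the generators do **not** emulate: splice-isoform structure beyond
the two-transcript mixture, positional gene clustering of the background
(real gene density is not uniform), GC/length biases, batch effects,
correlated features in DE matrices, and qPCR efficiency differences
between amplicons. Passing tests therefore demonstrate correctness of the
computations and recoverability of planted structure under idealized
noise, not robustness to every artifact of real libraries.

# The NB differential test

The test re-implements, as documented simplifications, the standard
two-group count workflow:

* **Size factors**: median over features (nonzero in all samples) of the
  count to geometric-mean ratio — the median taken on the linear scale,
  exactly as the definition reads — then rescaled to geometric mean 1 so
  factors are identifiable. If no feature qualifies, total-count ratios
  are used with a warning.
* **Dispersions**: per-feature method of moments on normalized counts,
  pooled within groups with df weights; the Poisson variance term uses
  `mu x mean(1/sf)` so normalization-induced variance is not mistaken for
  overdispersion. Raw estimates (which may be negative) are optionally
  shrunk halfway toward a mean-dispersion trend `a/mu + b` fitted by least
  squares, then truncated at zero. Shrinkage is on by default: at 20
  samples per group the per-feature moment estimator is noisy, and
  truncating without shrinkage both biases estimates up and lets
  underestimates inflate the Wald statistic.
* **Wald test**: `log2FC = log2(mu2/mu1)` of normalized group means; when
  a group mean is zero, half the feature's smallest positive normalized
  count is added to both means (a local pseudocount keeps the fold change
  finite without biasing every other feature). The standard error comes
  from the delta method on `var = mu + phi mu^2` summed over samples; the
  reference is normal (no t correction), the Wald convention at these
  sample sizes. Features with no nonzero counts are reported untested.
* **BH q-values** via the standard step-up (the implementation delegates
  to `stats::p.adjust`; tests compare against an independent exhaustive
  step-up oracle). Direction calls use `log2FC >= 1` / `<= -1` (boundary
  included, matching how UP counts are reported) and `q < 0.05`. The
  printed DN threshold appears once as "log2FC <= 1"; the methods
  statement "absolute log2 fold change > 1" fixes the intended `<= -1`.
* **pi values**: `log2FC x (-log10 q)`, with q = 0 clamped to 1e-300 so
  ranks are preserved without infinities; ties in the descending sort
  break by feature id for determinism.

Because features are interval-agnostic, the same functions serve ATAC
consensus-peak counts; features are peak ids.

Calibration at the study conditions (5,000 null features, 20 + 20
samples, dispersion 0.1; planted |log2FC| = 2 at base mean >= 50 with
30 + 30 samples) is asserted by the test suite and recomputed by
`scripts/acceptance.R`; the problem sizes were chosen as the smallest
that make the type-I fraction and sensitivity estimates tight enough to
be meaningful.

# Positional analysis

Windows of 10 Mb slide at 1 Mb steps; a trailing partial window keeps
coverage of the chromosome end, and its density uses the actual span.
Genes belong to every window covering their start coordinate. Fold
enrichment vs chromosome is the window's category density over the
chromosome's; `fe_up_coding_vs_local` is the window's UP-coding share of
genes over the chromosome's share — a scale-free operationalization of
"denser than expected for local gene density". Windows qualify as cluster
material at UP-coding enrichment >= 2 (vs chromosome and vs local) with
>= 5 UP genes — thresholds taken from the lower bounds reported for tumor
UP clusters (2-12x over gene enrichment, 4-14x over chromosomal average)
— and qualified windows merge into clusters with the maximal-enrichment
window as peak. No multiple-testing correction is applied across windows;
cluster calling is a descriptive threshold rule, and the fixed published
regions become test fixtures rather than hard-coded targets.

A detectability note that shaped the tests: with ~0.5 UP genes expected
per 10-Mb window (the genome-wide UP density the defaults encode), a
window needs roughly a 20x local excess before it reliably holds 5 UP
genes, while the same sparseness is what keeps null genomes clean at
these thresholds. A 5x excess over so sparse a background carries ~2-3
genes in expectation and cannot clear the 5-gene floor with any
regularity — the recovery tests therefore plant clusters in the
detectable regime (~10+ genes per window, the gene counts the published
clusters actually show), and the 5x-on-sparse-background configuration is
exercised as a known-infeasible corner. Raising background UP density
instead would flood the null scan with chance 5-gene windows: the two
requirements pin the background from opposite sides.

lncRNA fractions among UP and DN genes come with exact Clopper-Pearson
95% intervals (`stats::binom.test`); empty classes are flagged, not
errors. Gene-set overlap uses the upper-tail hypergeometric
`P(X >= k)` after intersecting each set with the universe, BH-corrected
across the collection; `k = 0` gives p = 1 by construction.

# qPCR

`computeRq()` averages replicate wells per (sample, amplicon) — replicate
handling is otherwise unspecified — then applies the comparative-Ct
closed form `RQ = 2^-(dCt - mean calibrator dCt)` per amplicon.
Between-amplicon comparisons per stage use the Welch t test by default
(the unequal-variance reading of "two-sample unpaired t test"; pooled by
flag), with the conventional significance bands. Amplicon correlations
default to the log2(RQ) scale because RQ is multiplicative; the linear
scale is a flag, since the published dot plots do not state their scale.

# File formats and conventions

Counts travel as plain TSV (feature ids in the first column, sample ids
in the header; non-negative integers enforced). Annotation reads from
BED6+1 (seventh column biotype) or GFF3 (`gene_biotype`/`biotype`
attribute); unknown biotypes map to `other`. Internally intervals live in
`GRanges` (1-based inclusive, the Bioconductor convention); BED's 0-based
half-open coordinates are converted on read and restored on write, and
all reported intervals are 1-based inclusive. Result tables write with 6
significant digits — enough that a write/read round trip preserves every
quantity the analyses compare.

# Known limitations

* The NB test is a simplification: no GLM fit, no shrunken fold changes,
  no Cook's-distance outlier handling; agreement with full-featured
  implementations is expected at the level of calibration and ranking,
  not per-feature p-values.
* The chi-squared stratum comparison treats cohort proportions as fixed,
  ignoring their sampling error; for strata that are large fractions of
  the cohort the test is slightly anticonservative.
* Changepoint detection fits exactly one breakpoint; multi-transition
  profiles report only the dominant one.
* Cluster calling has no FDR across windows (by design, matching the
  descriptive published procedure); interpret calls on sparse genomes
  with the detectability note above in mind.
* The Mann-Whitney exon comparison is unpaired, as the published captions
  state, although exon values come from the same tumors; a paired test
  would be more powerful but would not reproduce the published procedure.
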