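#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
NULL

## ---------------------------------------------------------------------------
## ExonModel
## ---------------------------------------------------------------------------

#' Exon model for a single gene
#'
#' Describes the ordered translated exons of one gene and their lengths, the
#' coordinate system in which per-exon read counts are interpreted. The
#' default model describes CIZ1, whose 16 translated exons (ids 2-17) encode
#' the N-terminal replication domain (5' exons, sampled at exons 5/7) and the
#' C-terminal anchor domain (3' exons, sampled at exons 14/16).
#'
#' @slot geneId single gene identifier.
#' @slot exonIds strictly increasing integer exon ids.
#' @slot exonLengths exon lengths in bp, parallel to `exonIds`, all > 0.
#'
#' @export
setClass("ExonModel",
  representation(geneId = "character", exonIds = "integer",
                 exonLengths = "numeric"))

setValidity("ExonModel", function(object) {
  msg <- NULL
  if (length(object@geneId) != 1L) msg <- c(msg, "geneId must be length 1")
  if (length(object@exonIds) != length(object@exonLengths))
    msg <- c(msg, "exonIds and exonLengths must have equal length")
  if (length(object@exonIds) < 2L)
    msg <- c(msg, "an exon model needs at least two exons")
  if (is.unsorted(object@exonIds, strictly = TRUE))
    msg <- c(msg, "exonIds must be strictly increasing")
  if (any(!is.finite(object@exonLengths)) || any(object@exonLengths <= 0))
    msg <- c(msg, "exonLengths must be positive")
  if (is.null(msg)) TRUE else msg
})

#' @param geneId,exonIds,exonLengths see slots.
#' @return `ExonModel()` returns an ExonModel object.
#' @rdname ExonModel-class
#' @export
ExonModel <- function(geneId, exonIds, exonLengths) {
  new("ExonModel", geneId = as.character(geneId),
      exonIds = as.integer(exonIds), exonLengths = as.numeric(exonLengths))
}

## Synthetic CIZ1-like exon lengths (bp) for translated exons 2-17. These are
## stand-in values of realistic magnitude for internal coding exons, not
## measured CIZ1 exon lengths; analyses that matter (anchor normalization,
## the AD:RD ratio) are invariant to them because counts are length-corrected.
.ciz1ExonLengths <- c(196, 140, 125, 103, 151, 98, 132, 118,
                      164, 109, 87, 173, 146, 201, 94, 342)

#' Default CIZ1-style exon model (translated exons 2-17, synthetic lengths)
#'
#' @return an [ExonModel] with exon ids 2 to 17.
#' @export
ciz1ExonModel <- function() {
  ExonModel("CIZ1", 2:17, .ciz1ExonLengths)
}

setMethod("show", "ExonModel", function(object) {
  cat("ExonModel for", object@geneId, "with", length(object@exonIds),
      "exons (ids", object@exonIds[1], "-",
      object@exonIds[length(object@exonIds)], ")\n")
})

#' @describeIn ExonModel-class exon ids.
#' @param object an ExonModel.
#' @export
setGeneric("exonIds", function(object) standardGeneric("exonIds"))

#' @rdname ExonModel-class
#' @export
setMethod("exonIds", "ExonModel", function(object) object@exonIds)

#' @describeIn ExonModel-class exon lengths (bp).
#' @export
setGeneric("exonLengths", function(object) standardGeneric("exonLengths"))

#' @rdname ExonModel-class
#' @export
setMethod("exonLengths", "ExonModel", function(object) object@exonLengths)

## ---------------------------------------------------------------------------
## ExonProfileSet
## ---------------------------------------------------------------------------

#' Per-sample exon TPM profiles
#'
#' A [SummarizedExperiment::SummarizedExperiment] with exons as rows and
#' samples as columns. The `"tpm"` assay holds within-gene TPM values
#' (summing to 1e6 per non-empty sample); after [normalizeToAnchor()] a
#' `"normalized"` assay holds the ratio of each exon's TPM to the anchor
#' exon's TPM. Samples whose anchor TPM is zero are flagged excluded in
#' `colData` rather than dropped.
#'
#' @export
setClass("ExonProfileSet", contains = "SummarizedExperiment")

#' @describeIn ExonProfileSet-class the exon model the profiles were built on.
#' @param object an ExonProfileSet.
#' @export
setGeneric("exonModel", function(object) standardGeneric("exonModel"))

#' @rdname ExonProfileSet-class
#' @export
setMethod("exonModel", "ExonProfileSet",
          function(object) metadata(object)$exonModel)

#' @describeIn ExonProfileSet-class the anchor exon id (NA before
#'   normalization).
#' @export
setGeneric("anchorExon", function(object) standardGeneric("anchorExon"))

#' @rdname ExonProfileSet-class
#' @export
setMethod("anchorExon", "ExonProfileSet",
          function(object) metadata(object)$anchorExon)

#' @describeIn ExonProfileSet-class the TPM assay (exons x samples).
#' @export
setGeneric("exonTpm", function(object) standardGeneric("exonTpm"))

#' @rdname ExonProfileSet-class
#' @export
setMethod("exonTpm", "ExonProfileSet",
          function(object) SummarizedExperiment::assay(object, "tpm"))

#' @describeIn ExonProfileSet-class the anchor-normalized assay.
#' @export
setGeneric("anchorNormalized", function(object) standardGeneric("anchorNormalized"))

#' @rdname ExonProfileSet-class
#' @export
setMethod("anchorNormalized", "ExonProfileSet", function(object) {
  if (!"normalized" %in% SummarizedExperiment::assayNames(object))
    stop("profiles have not been anchor-normalized; call normalizeToAnchor()",
         call. = FALSE)
  SummarizedExperiment::assay(object, "normalized")
})

#' @describeIn ExonProfileSet-class data.frame of excluded samples and
#'   exclusion reasons (zero-anchor samples after normalization).
#' @export
setGeneric("excludedSamples", function(object) standardGeneric("excludedSamples"))

#' @rdname ExonProfileSet-class
#' @export
setMethod("excludedSamples", "ExonProfileSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  keep <- if ("excluded" %in% colnames(cd)) cd$excluded else
    rep(FALSE, nrow(cd))
  data.frame(sample_id = rownames(cd)[keep],
             reason = if (any(keep)) cd$exclusionReason[keep] else character(0),
             stringsAsFactors = FALSE)
})

## ---------------------------------------------------------------------------
## Simulation specs
## ---------------------------------------------------------------------------

#' Simulation spec: exon-level counts with an internal TSS
#'
#' Generative model for per-exon read counts of a two-domain gene. A
#' full-length transcript covers every exon at relative abundance
#' `baseAbundance` (expected reads per bp at library scale 1); a second
#' transcript initiated at an internal transcription start site covers exons
#' `internalTssExon` onward at relative abundance `alpha`. The expected count
#' of exon e in sample s is
#' `libScale_s * length_e * (baseAbundance + alpha * [e >= internalTssExon])`.
#' Counts are gamma-mixed Poisson: one gamma factor with mean 1 and variance
#' `dispersion` is drawn per sample and shared by all exons of the gene, so
#' each exon count is marginally negative binomial with the requested
#' dispersion while within-gene exon:exon ratios carry only Poisson noise
#' (exons of one gene are read from the same transcript pool, so their
#' biological variability is shared, not independent).
#'
#' `alpha` may be negative (down to `-baseAbundance`, exclusive) to model 3'
#' -depleted profiles (DNF index below 1); `alpha = 0` is the balanced
#' regime.
#'
#' @export
setClass("ExonSimSpec",
  representation(exonIds = "integer", exonLengths = "numeric",
                 baseAbundance = "numeric", internalTssExon = "integer",
                 alpha = "numeric", dispersion = "numeric",
                 librarySizeCv = "numeric", seed = "numeric"))

setValidity("ExonSimSpec", function(object) {
  msg <- NULL
  if (length(object@exonIds) != length(object@exonLengths))
    msg <- c(msg, "exonIds and exonLengths must match")
  if (any(object@exonLengths <= 0)) msg <- c(msg, "exonLengths must be > 0")
  if (object@baseAbundance <= 0) msg <- c(msg, "baseAbundance must be > 0")
  if (object@alpha <= -object@baseAbundance)
    msg <- c(msg, "alpha must exceed -baseAbundance (means must stay positive)")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (object@librarySizeCv < 0) msg <- c(msg, "librarySizeCv must be >= 0")
  if (!object@internalTssExon %in% object@exonIds)
    msg <- c(msg, "internalTssExon must be one of exonIds")
  if (is.null(msg)) TRUE else msg
})

#' @param model an [ExonModel]; supplies exon ids and lengths.
#' @param baseAbundance expected reads per bp of the full-length transcript
#'   at library scale 1 (default 8, i.e. roughly 800x coverage of a 100-bp
#'   exon, deep coverage of a well-expressed gene).
#' @param internalTssExon exon id where the internal-TSS transcript begins
#'   (default 10).
#' @param alpha relative abundance of the internal-TSS transcript; 0 =
#'   balanced.
#' @param dispersion gene-level NB dispersion (default 0.05).
#' @param librarySizeCv coefficient of variation of per-sample library
#'   scaling (default 0.2).
#' @param seed optional RNG seed (NA = use current RNG state).
#' @return `ExonSimSpec()` returns an ExonSimSpec object.
#' @rdname ExonSimSpec-class
#' @export
ExonSimSpec <- function(model = ciz1ExonModel(), baseAbundance = 8,
                        internalTssExon = 10L, alpha = 0,
                        dispersion = 0.05, librarySizeCv = 0.2,
                        seed = NA_real_) {
  new("ExonSimSpec", exonIds = exonIds(model),
      exonLengths = exonLengths(model),
      baseAbundance = as.numeric(baseAbundance),
      internalTssExon = as.integer(internalTssExon),
      alpha = as.numeric(alpha), dispersion = as.numeric(dispersion),
      librarySizeCv = as.numeric(librarySizeCv), seed = as.numeric(seed))
}

#' Simulation spec: cohort with planted DNF-ratio regimes
#'
#' Each regime plants a target mean AD:RD ratio (exon 14 : exon 5); the
#' internal-TSS abundance is derived as `alpha = (ratio - 1) * baseAbundance`
#' of the accompanying [ExonSimSpec]. Defaults reproduce a three-regime
#' cohort with mean ratios 2.5 / 1.0 / 0.7 (expected groups A / C / D) of
#' 100 samples each.
#'
#' @export
setClass("CohortSimSpec",
  representation(groupSizes = "integer", meanRatios = "numeric",
                 stageAssignment = "character", seed = "numeric"))

setValidity("CohortSimSpec", function(object) {
  msg <- NULL
  if (length(object@groupSizes) < 1L) msg <- c(msg, "need at least one regime")
  if (any(object@groupSizes < 1L)) msg <- c(msg, "groupSizes must be >= 1")
  if (length(object@meanRatios) != length(object@groupSizes))
    msg <- c(msg, "meanRatios must match groupSizes")
  if (any(object@meanRatios <= 0)) msg <- c(msg, "meanRatios must be > 0")
  ok <- length(object@stageAssignment) == 0L ||
    length(object@stageAssignment) == sum(object@groupSizes)
  if (!ok) msg <- c(msg, "stageAssignment must be empty or one per sample")
  if (length(object@stageAssignment) &&
      !all(object@stageAssignment %in% .stageLevels))
    msg <- c(msg, "stages must be in {0, I, II, III, IV, NA}")
  if (is.null(msg)) TRUE else msg
})

#' @param groupSizes samples per planted regime.
#' @param meanRatios target mean AD:RD ratio per regime.
#' @param stageAssignment optional per-sample stage labels; when empty,
#'   stages I-IV are sampled uniformly.
#' @param seed optional RNG seed.
#' @return `CohortSimSpec()` returns a CohortSimSpec object.
#' @rdname CohortSimSpec-class
#' @export
CohortSimSpec <- function(groupSizes = c(100L, 100L, 100L),
                          meanRatios = c(2.5, 1.0, 0.7),
                          stageAssignment = character(0),
                          seed = NA_real_) {
  new("CohortSimSpec", groupSizes = as.integer(groupSizes),
      meanRatios = as.numeric(meanRatios),
      stageAssignment = as.character(stageAssignment),
      seed = as.numeric(seed))
}

#' Simulation spec: genome with planted UP-gene clusters
#'
#' Background genes are placed uniformly per chromosome (expected counts
#' proportional to chromosome length) and labelled UP/DN/NS at rates derived
#' from observed tumor-cohort statistics: about 5.6% of genes differentially
#' expressed, of which 15% UP and 85% DN; 38% of UP and 4% of DN genes are
#' lncRNAs. Inside each planted cluster interval, additional UP genes are
#' placed so the local UP density is `clusterDensityFold` times the
#' background UP density, with lncRNA share `clusterLncRNAFraction`.
#'
#' @export
setClass("GenomeSimSpec",
  representation(chromLengths = "numeric", nGenes = "integer",
                 lncRNAFraction = "numeric", degFraction = "numeric",
                 upShare = "numeric", upLncRNAFraction = "numeric",
                 dnLncRNAFraction = "numeric",
                 clusterIntervals = "data.frame",
                 clusterDensityFold = "numeric",
                 clusterLncRNAFraction = "numeric", seed = "numeric"))

setValidity("GenomeSimSpec", function(object) {
  msg <- NULL
  if (is.null(names(object@chromLengths)) ||
      anyDuplicated(names(object@chromLengths)))
    msg <- c(msg, "chromLengths must be uniquely named")
  if (any(object@chromLengths <= 0)) msg <- c(msg, "chromLengths must be > 0")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  for (f in c("lncRNAFraction", "degFraction", "upShare",
              "upLncRNAFraction", "dnLncRNAFraction",
              "clusterLncRNAFraction")) {
    v <- slot(object, f)
    if (v < 0 || v > 1) msg <- c(msg, paste(f, "must be in [0, 1]"))
  }
  if (object@clusterDensityFold < 0)
    msg <- c(msg, "clusterDensityFold must be >= 0")
  ci <- object@clusterIntervals
  if (nrow(ci)) {
    if (!all(c("chrom", "start", "end") %in% colnames(ci)))
      msg <- c(msg, "clusterIntervals needs chrom/start/end columns")
    else {
      if (!all(ci$chrom %in% names(object@chromLengths)))
        msg <- c(msg, "cluster chrom not in chromLengths")
      if (any(ci$start >= ci$end)) msg <- c(msg, "cluster start must be < end")
      if (any(ci$start < 1) ||
          any(ci$end > object@chromLengths[as.character(ci$chrom)]))
        msg <- c(msg, "clusters must lie within their chromosome")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' @param chromLengths named chromosome lengths in bp.
#' @param nGenes expected total number of genes.
#' @param lncRNAFraction genome-wide lncRNA fraction among NS genes.
#' @param degFraction fraction of genes carrying a direction label.
#' @param upShare UP share among direction-labelled genes.
#' @param upLncRNAFraction,dnLncRNAFraction lncRNA share among UP / DN genes.
#' @param clusterIntervals data.frame (chrom, start, end), 1-based inclusive,
#'   of planted UP clusters.
#' @param clusterDensityFold UP density multiplier inside clusters.
#' @param clusterLncRNAFraction lncRNA share among planted cluster UP genes.
#' @param seed optional RNG seed.
#' @return `GenomeSimSpec()` returns a GenomeSimSpec object.
#' @rdname GenomeSimSpec-class
#' @export
GenomeSimSpec <- function(chromLengths = c(chr1 = 2e8, chr2 = 2e8, chr3 = 2e8),
                          nGenes = 3300L, lncRNAFraction = 0.3,
                          degFraction = 0.056, upShare = 0.15,
                          upLncRNAFraction = 0.38, dnLncRNAFraction = 0.04,
                          clusterIntervals = data.frame(
                            chrom = character(0), start = numeric(0),
                            end = numeric(0)),
                          clusterDensityFold = 1,
                          clusterLncRNAFraction = 0.38,
                          seed = NA_real_) {
  new("GenomeSimSpec", chromLengths = chromLengths,
      nGenes = as.integer(nGenes), lncRNAFraction = lncRNAFraction,
      degFraction = degFraction, upShare = upShare,
      upLncRNAFraction = upLncRNAFraction,
      dnLncRNAFraction = dnLncRNAFraction,
      clusterIntervals = as.data.frame(clusterIntervals),
      clusterDensityFold = clusterDensityFold,
      clusterLncRNAFraction = clusterLncRNAFraction,
      seed = as.numeric(seed))
}

#' Simulation spec: two-group count matrix with planted fold changes
#'
#' Features are NB-distributed with log-normal baseline means and a shared
#' dispersion; planted features change by the given signed log2 fold change
#' in group 2. Per-sample library scaling (log-normal, CV `librarySizeCv`)
#' exercises size-factor estimation.
#'
#' @export
setClass("DegSimSpec",
  representation(nFeatures = "integer", nPerGroup = "integer",
                 baselineMeanlog = "numeric", baselineSdlog = "numeric",
                 baselineMeans = "numeric", dispersion = "numeric",
                 plantedLog2Fc = "numeric", librarySizeCv = "numeric",
                 seed = "numeric"))

setValidity("DegSimSpec", function(object) {
  msg <- NULL
  if (object@nFeatures < 1L) msg <- c(msg, "nFeatures must be >= 1")
  if (length(object@nPerGroup) != 2L || any(object@nPerGroup < 2L))
    msg <- c(msg, "nPerGroup must give >= 2 samples in each of two groups")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (length(object@plantedLog2Fc)) {
    if (is.null(names(object@plantedLog2Fc)) ||
        anyDuplicated(names(object@plantedLog2Fc)))
      msg <- c(msg, "plantedLog2Fc must be uniquely named by feature id")
    if (any(object@plantedLog2Fc == 0))
      msg <- c(msg, "planted log2FC values must be nonzero")
  }
  if (length(object@baselineMeans) &&
      length(object@baselineMeans) != object@nFeatures)
    msg <- c(msg, "baselineMeans must be empty or one per feature")
  if (is.null(msg)) TRUE else msg
})

#' @param nFeatures number of features.
#' @param nPerGroup samples per condition (length 2).
#' @param baselineMeanlog,baselineSdlog log-normal parameters of baseline
#'   means.
#' @param baselineMeans optional explicit baseline means (overrides the
#'   log-normal draw).
#' @param dispersion NB dispersion shared by all features.
#' @param plantedLog2Fc named numeric: feature id -> signed log2 fold change
#'   applied in group 2 (positive = UP).
#' @param librarySizeCv CV of per-sample library scaling.
#' @param seed optional RNG seed.
#' @return `DegSimSpec()` returns a DegSimSpec object.
#' @rdname DegSimSpec-class
#' @export
DegSimSpec <- function(nFeatures = 5000L, nPerGroup = c(20L, 20L),
                       baselineMeanlog = log(100), baselineSdlog = 1,
                       baselineMeans = numeric(0), dispersion = 0.1,
                       plantedLog2Fc = numeric(0), librarySizeCv = 0.2,
                       seed = NA_real_) {
  new("DegSimSpec", nFeatures = as.integer(nFeatures),
      nPerGroup = as.integer(nPerGroup),
      baselineMeanlog = baselineMeanlog, baselineSdlog = baselineSdlog,
      baselineMeans = as.numeric(baselineMeans), dispersion = dispersion,
      plantedLog2Fc = plantedLog2Fc, librarySizeCv = librarySizeCv,
      seed = as.numeric(seed))
}

#' Simulation spec: qPCR Ct values with coupled amplicons
#'
#' Per-sample latent log2 abundances of the amplicons are drawn from a
#' multivariate normal with the given correlation (coupling) structure; by
#' default the two replication-domain amplicons (ex5, ex7) are tightly
#' coupled, the two anchor-domain amplicons (ex14, ex16) are tightly
#' coupled, and the RD-AD pairs are uncoupled. Ct values are
#' `referenceCt - log2 abundance + noise`. An optional per-stage step
#' elevates the AD amplicons with tumor stage.
#'
#' @export
setClass("QpcrSimSpec",
  representation(nSamples = "integer", amplicons = "character",
                 ampliconMeans = "numeric", coupling = "matrix",
                 latentSd = "numeric", ctNoiseSd = "numeric",
                 referenceCt = "numeric", stages = "character",
                 adAmplicons = "character", adStageStep = "numeric",
                 seed = "numeric"))

setValidity("QpcrSimSpec", function(object) {
  msg <- NULL
  k <- length(object@amplicons)
  if (k < 1L || anyDuplicated(object@amplicons))
    msg <- c(msg, "amplicons must be unique and non-empty")
  if (length(object@ampliconMeans) != k)
    msg <- c(msg, "ampliconMeans must match amplicons")
  if (!all(dim(object@coupling) == c(k, k)))
    msg <- c(msg, "coupling must be k x k")
  else {
    if (any(abs(object@coupling) > 1) ||
        any(abs(diag(object@coupling) - 1) > 1e-12))
      msg <- c(msg, "coupling must be a correlation matrix")
    if (any(abs(object@coupling - t(object@coupling)) > 1e-12))
      msg <- c(msg, "coupling must be symmetric")
    else if (min(eigen(object@coupling, symmetric = TRUE,
                       only.values = TRUE)$values) < -1e-8)
      msg <- c(msg, "coupling must be positive semi-definite")
  }
  if (object@ctNoiseSd < 0) msg <- c(msg, "ctNoiseSd must be >= 0")
  if (object@latentSd < 0) msg <- c(msg, "latentSd must be >= 0")
  if (length(object@stages) &&
      length(object@stages) != object@nSamples)
    msg <- c(msg, "stages must be empty or one per sample")
  if (!all(object@adAmplicons %in% object@amplicons))
    msg <- c(msg, "adAmplicons must be a subset of amplicons")
  if (is.null(msg)) TRUE else msg
})

.defaultCoupling <- function(amplicons = c("ex5", "ex7", "ex14", "ex16"),
                             within = 0.95, between = 0) {
  k <- length(amplicons)
  rd <- amplicons %in% c("ex5", "ex7")
  m <- matrix(between, k, k, dimnames = list(amplicons, amplicons))
  m[rd, rd] <- within
  m[!rd, !rd] <- within
  diag(m) <- 1
  m
}

#' @param nSamples number of samples.
#' @param amplicons amplicon labels.
#' @param ampliconMeans baseline latent log2 abundances.
#' @param coupling correlation matrix among amplicon log2 abundances.
#' @param latentSd standard deviation of the latent log2 abundances.
#' @param ctNoiseSd technical Ct noise in cycles.
#' @param referenceCt reference-gene Ct (cycles).
#' @param stages optional per-sample stage labels.
#' @param adAmplicons amplicons elevated with stage.
#' @param adStageStep log2 abundance increment of AD amplicons per stage
#'   index above the first stage.
#' @param seed optional RNG seed.
#' @return `QpcrSimSpec()` returns a QpcrSimSpec object.
#' @rdname QpcrSimSpec-class
#' @export
QpcrSimSpec <- function(nSamples = 60L,
                        amplicons = c("ex5", "ex7", "ex14", "ex16"),
                        ampliconMeans = rep(5, length(amplicons)),
                        coupling = .defaultCoupling(amplicons),
                        latentSd = 1, ctNoiseSd = 0.25, referenceCt = 20,
                        stages = character(0),
                        adAmplicons = intersect(amplicons, c("ex14", "ex16")),
                        adStageStep = 0,
                        seed = NA_real_) {
  new("QpcrSimSpec", nSamples = as.integer(nSamples),
      amplicons = amplicons, ampliconMeans = ampliconMeans,
      coupling = coupling, latentSd = latentSd, ctNoiseSd = ctNoiseSd,
      referenceCt = referenceCt, stages = as.character(stages),
      adAmplicons = adAmplicons, adStageStep = adStageStep,
      seed = as.numeric(seed))
}
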