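#' Simulate exon-level counts for a two-domain gene
#'
#' Draws per-exon read counts under the internal-TSS mixture model described
#' in [ExonSimSpec]. One gamma overdispersion factor per sample is shared by
#' all exons, so each exon count is marginally NB(mu, dispersion) while
#' exon:exon ratios within a sample carry only Poisson noise.
#'
#' @param spec an [ExonSimSpec].
#' @param nSamples number of samples to draw.
#' @param sampleIds optional sample names (default S1..Sn).
#' @return integer count matrix (exons x samples); rownames are exon ids.
#' @export
simulateExonCounts <- function(spec, nSamples, sampleIds = NULL) {
  stopifnot(is(spec, "ExonSimSpec"))
  validObject(spec)
  nSamples <- as.integer(nSamples)
  if (nSamples < 1L) stop("nSamples must be >= 1", call. = FALSE)
  if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(nSamples))
  if (length(sampleIds) != nSamples) stop("sampleIds must match nSamples")
  .maybeSetSeed(spec@seed)
  phi <- spec@dispersion
  libScale <- .rlibraryScale(nSamples, spec@librarySizeCv)
  g <- if (phi > 0) stats::rgamma(nSamples, shape = 1 / phi, scale = phi)
       else rep(1, nSamples)
  abundance <- spec@baseAbundance +
    spec@alpha * (spec@exonIds >= spec@internalTssExon)
  mu <- outer(spec@exonLengths * abundance, libScale * g)
  counts <- matrix(stats::rpois(length(mu), as.vector(mu)),
                   nrow = nrow(mu),
                   dimnames = list(as.character(spec@exonIds), sampleIds))
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate a tumor cohort with planted DNF-ratio regimes
#'
#' Concatenates per-regime exon count tables generated by
#' [simulateExonCounts()], deriving each regime's internal-TSS abundance from
#' its target mean AD:RD ratio (`alpha = (ratio - 1) * baseAbundance`).
#'
#' @param spec a [CohortSimSpec].
#' @param exonSpec an [ExonSimSpec] providing the exon model, coverage,
#'   dispersion and library-size CV shared by all regimes (its `alpha` and
#'   `seed` are ignored; the cohort seed governs).
#' @return list with elements `counts` (exon x sample matrix), `metadata`
#'   (data.frame: sample_id, stage, subtype, receptor_status) and `truth`
#'   (data.frame: sample_id, regime, planted_ratio, expected_group).
#' @export
simulateCohort <- function(spec, exonSpec = ExonSimSpec()) {
  stopifnot(is(spec, "CohortSimSpec"), is(exonSpec, "ExonSimSpec"))
  validObject(spec); validObject(exonSpec)
  if (any(spec@meanRatios <= 0))
    stop("regime mean ratios must be positive", call. = FALSE)
  .maybeSetSeed(spec@seed)
  n <- sum(spec@groupSizes)
  sampleIds <- sprintf("S%03d", seq_len(n))
  blocks <- vector("list", length(spec@groupSizes))
  offset <- 0L
  for (r in seq_along(spec@groupSizes)) {
    alpha <- (spec@meanRatios[r] - 1) * exonSpec@baseAbundance
    rspec <- ExonSimSpec(
      model = ExonModel("gene", exonSpec@exonIds, exonSpec@exonLengths),
      baseAbundance = exonSpec@baseAbundance,
      internalTssExon = exonSpec@internalTssExon, alpha = alpha,
      dispersion = exonSpec@dispersion,
      librarySizeCv = exonSpec@librarySizeCv, seed = NA_real_)
    ids <- sampleIds[offset + seq_len(spec@groupSizes[r])]
    blocks[[r]] <- simulateExonCounts(rspec, spec@groupSizes[r], ids)
    offset <- offset + spec@groupSizes[r]
  }
  counts <- do.call(cbind, blocks)
  stages <- if (length(spec@stageAssignment)) spec@stageAssignment
            else sample(c("I", "II", "III", "IV"), n, replace = TRUE)
  metadata <- data.frame(sample_id = sampleIds, stage = stages,
                         subtype = "unspecified",
                         receptor_status = "unspecified",
                         stringsAsFactors = FALSE)
  truth <- data.frame(
    sample_id = sampleIds,
    regime = rep(seq_along(spec@groupSizes), spec@groupSizes),
    planted_ratio = rep(spec@meanRatios, spec@groupSizes),
    expected_group = as.character(
      rep(classifyDnfGroup(spec@meanRatios), spec@groupSizes)),
    stringsAsFactors = FALSE)
  list(counts = counts, metadata = metadata, truth = truth)
}

#' Simulate a genome of direction-labelled genes with planted UP clusters
#'
#' Background genes are placed uniformly per chromosome (gene count split by
#' chromosome length), labelled UP/DN/NS and coding/lncRNA at the spec's
#' rates. Inside each planted cluster interval, extra UP genes are added so
#' the local UP density reaches `clusterDensityFold` times the background UP
#' density (extra count drawn Poisson).
#'
#' @param spec a [GenomeSimSpec].
#' @return list with `annotation` (GRanges with `gene_id`, `biotype`,
#'   `direction`, `planted` metadata columns and seqlengths set) and `truth`
#'   (list: `clusterIntervals`, `nPlanted`).
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
#' @export
simulateGenome <- function(spec) {
  stopifnot(is(spec, "GenomeSimSpec"))
  validObject(spec)
  .maybeSetSeed(spec@seed)
  chroms <- names(spec@chromLengths)
  prob <- spec@chromLengths / sum(spec@chromLengths)
  nPerChrom <- as.vector(stats::rmultinom(1, spec@nGenes, prob))
  chrom <- rep(chroms, nPerChrom)
  len <- spec@chromLengths[chrom]
  pos <- floor(stats::runif(length(chrom), 1, len + 1))
  pUp <- spec@degFraction * spec@upShare
  pDn <- spec@degFraction * (1 - spec@upShare)
  direction <- sample(c("UP", "DN", "NS"), length(chrom), replace = TRUE,
                      prob = c(pUp, pDn, 1 - pUp - pDn))
  lncProb <- c(UP = spec@upLncRNAFraction, DN = spec@dnLncRNAFraction,
               NS = spec@lncRNAFraction)[direction]
  biotype <- ifelse(stats::runif(length(chrom)) < lncProb,
                    "lncRNA", "protein_coding")
  planted <- rep(FALSE, length(chrom))

  ci <- spec@clusterIntervals
  if (nrow(ci) && spec@clusterDensityFold > 1) {
    bgUpDensity <- spec@nGenes * pUp / sum(spec@chromLengths)
    for (i in seq_len(nrow(ci))) {
      w <- ci$end[i] - ci$start[i] + 1
      nExtra <- stats::rpois(1, (spec@clusterDensityFold - 1) * bgUpDensity * w)
      if (nExtra == 0) next
      chrom <- c(chrom, rep(as.character(ci$chrom[i]), nExtra))
      pos <- c(pos, floor(stats::runif(nExtra, ci$start[i], ci$end[i] + 1)))
      direction <- c(direction, rep("UP", nExtra))
      biotype <- c(biotype,
                   ifelse(stats::runif(nExtra) < spec@clusterLncRNAFraction,
                          "lncRNA", "protein_coding"))
      planted <- c(planted, rep(TRUE, nExtra))
    }
  }

  geneLen <- pmax(200, round(stats::rlnorm(length(chrom), log(2e4), 1)))
  endPos <- pmin(pos + geneLen - 1, spec@chromLengths[chrom])
  ord <- order(match(chrom, chroms), pos)
  gr <- GRanges(chrom[ord], IRanges(pos[ord], endPos[ord]), strand = "*",
                seqlengths = spec@chromLengths)
  gr$gene_id <- sprintf("g%05d", seq_along(gr))
  gr$biotype <- biotype[ord]
  gr$direction <- direction[ord]
  gr$planted <- planted[ord]
  stopifnot(all(start(gr) >= 1),
            all(end(gr) <= spec@chromLengths[as.character(seqnames(gr))]))
  list(annotation = gr,
       truth = list(clusterIntervals = ci, nPlanted = sum(planted)))
}

#' Simulate a two-group count matrix with planted fold changes
#'
#' @param spec a [DegSimSpec].
#' @return list with `counts` (features x samples integer matrix),
#'   `condition` (factor, levels g1/g2) and `truth` (data.frame: feature_id,
#'   planted_log2fc, for the planted features only).
#' @export
simulateDegCounts <- function(spec) {
  stopifnot(is(spec, "DegSimSpec"))
  validObject(spec)
  .maybeSetSeed(spec@seed)
  m <- spec@nFeatures
  featureIds <- sprintf("f%05d", seq_len(m))
  planted <- spec@plantedLog2Fc
  if (length(planted) && !all(names(planted) %in% featureIds))
    stop("planted feature ids must be among f00001..f", sprintf("%05d", m),
         call. = FALSE)
  baseline <- if (length(spec@baselineMeans)) spec@baselineMeans
              else stats::rlnorm(m, spec@baselineMeanlog, spec@baselineSdlog)
  lfc <- stats::setNames(rep(0, m), featureIds)
  lfc[names(planted)] <- planted
  n1 <- spec@nPerGroup[1]; n2 <- spec@nPerGroup[2]
  sf <- .rlibraryScale(n1 + n2, spec@librarySizeCv)
  condition <- factor(rep(c("g1", "g2"), c(n1, n2)), levels = c("g1", "g2"))
  mu <- outer(baseline, sf) *
    2^(outer(lfc, as.numeric(condition == "g2")))
  counts <- matrix(.rnbinomMu(length(mu), as.vector(mu), spec@dispersion),
                   nrow = m,
                   dimnames = list(featureIds,
                                   paste0("S", seq_len(n1 + n2))))
  storage.mode(counts) <- "integer"
  truth <- data.frame(feature_id = names(planted),
                      planted_log2fc = unname(planted),
                      stringsAsFactors = FALSE)
  list(counts = counts, condition = condition, truth = truth)
}

#' Simulate qPCR Ct values with coupled amplicons
#'
#' @param spec a [QpcrSimSpec].
#' @return data.frame with columns sample_id, amplicon, ct, reference_ct and
#'   (when stages were supplied) stage.
#' @export
simulateQpcr <- function(spec) {
  stopifnot(is(spec, "QpcrSimSpec"))
  validObject(spec)
  .maybeSetSeed(spec@seed)
  n <- spec@nSamples
  k <- length(spec@amplicons)
  sigma <- spec@latentSd^2 * spec@coupling
  latent <- MASS::mvrnorm(n, mu = spec@ampliconMeans, Sigma = sigma)
  latent <- matrix(latent, nrow = n, ncol = k,
                   dimnames = list(NULL, spec@amplicons))
  if (length(spec@stages) && spec@adStageStep != 0) {
    stageIdx <- match(spec@stages, .stageLevels)
    step <- spec@adStageStep * (stageIdx - min(stageIdx, na.rm = TRUE))
    step[is.na(step)] <- 0
    for (a in spec@adAmplicons) latent[, a] <- latent[, a] + step
  }
  sampleIds <- sprintf("S%03d", seq_len(n))
  out <- data.frame(
    sample_id = rep(sampleIds, each = k),
    amplicon = rep(spec@amplicons, times = n),
    ct = spec@referenceCt - as.vector(t(latent)) +
      stats::rnorm(n * k, 0, spec@ctNoiseSd),
    reference_ct = spec@referenceCt,
    stringsAsFactors = FALSE)
  if (length(spec@stages)) out$stage <- rep(spec@stages, each = k)
  out
}
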