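#' Compute within-gene exon TPM profiles
#'
#' Length-corrects each exon's count (`rate = count / length`) and scales
#' rates to transcripts per million within the gene
#' (`tpm = rate / sum(rates) * 1e6`), so TPM values sum to 1e6 per sample.
#' The denominator is the sum over this gene's exons, not the whole
#' transcriptome: only one gene's profile is analyzed and any
#' transcriptome-wide constant cancels in the anchor normalization and in
#' the AD:RD ratio, which makes the analysis self-contained. Samples with
#' all-zero counts get an all-zero profile with a warning.
#'
#' @param counts exon x sample count matrix; rownames must be the model's
#'   exon ids.
#' @param model an [ExonModel].
#' @return an [ExonProfileSet] with a `"tpm"` assay.
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @export
computeExonTpm <- function(counts, model = ciz1ExonModel()) {
  stopifnot(is(model, "ExonModel"))
  .assertCountMatrix(counts)
  wanted <- as.character(exonIds(model))
  if (!identical(sort(rownames(counts)), sort(wanted)))
    stop("count table exon ids do not match the exon model", call. = FALSE)
  counts <- counts[wanted, , drop = FALSE]
  rate <- counts / exonLengths(model)
  total <- colSums(rate)
  if (any(total == 0))
    warning(sum(total == 0), " sample(s) with all-zero counts; ",
            "their TPM profile is all zero")
  tpm <- sweep(rate, 2, ifelse(total > 0, total, 1), "/") * 1e6
  tpm[, total == 0] <- 0
  se <- SummarizedExperiment(
    assays = S4Vectors::SimpleList(tpm = tpm),
    rowData = S4Vectors::DataFrame(exon_id = exonIds(model),
                                   exon_length = exonLengths(model)),
    colData = S4Vectors::DataFrame(
      sample_id = colnames(counts),
      excluded = rep(FALSE, ncol(counts)),
      exclusionReason = rep(NA_character_, ncol(counts)),
      row.names = colnames(counts)),
    metadata = list(exonModel = model, anchorExon = NA_integer_))
  new("ExonProfileSet", se)
}

#' Normalize exon TPM profiles to an anchor exon
#'
#' Divides each exon's TPM by the anchor exon's TPM per sample, so the anchor
#' value is exactly 1. Anchor exon 2 reproduces profiles normalized to the
#' first translated exon; exon 7 (the default) reproduces normalization to
#' canonical mid-RD coverage. Samples whose anchor TPM is zero cannot enter
#' ratio analyses; they are flagged excluded (reason `"zero anchor TPM"`)
#' rather than dropped, and their normalized column is NA.
#'
#' @param profiles an [ExonProfileSet].
#' @param anchor anchor exon id (default 7).
#' @return the ExonProfileSet with a `"normalized"` assay and updated
#'   exclusion flags.
#' @export
normalizeToAnchor <- function(profiles, anchor = 7L) {
  stopifnot(is(profiles, "ExonProfileSet"))
  model <- exonModel(profiles)
  anchor <- as.integer(anchor)
  if (!anchor %in% exonIds(model))
    stop("anchor exon ", anchor, " is not in the exon model", call. = FALSE)
  tpm <- exonTpm(profiles)
  anchorTpm <- tpm[as.character(anchor), ]
  norm <- sweep(tpm, 2, ifelse(anchorTpm > 0, anchorTpm, NA_real_), "/")
  SummarizedExperiment::assay(profiles, "normalized") <- norm
  cd <- SummarizedExperiment::colData(profiles)
  zero <- anchorTpm == 0
  cd$excluded <- cd$excluded | zero
  cd$exclusionReason <- ifelse(zero & is.na(cd$exclusionReason),
                               "zero anchor TPM", cd$exclusionReason)
  SummarizedExperiment::colData(profiles) <- cd
  metadata(profiles)$anchorExon <- anchor
  profiles
}

#' Compare expression of two exons across a cohort (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test between the per-sample
#' values of two exons, treated as unpaired groups. The exact null
#' distribution is enumerated when both sides have at most `exactMax`
#' samples and there are no ties; otherwise the normal approximation with
#' tie and continuity correction is used.
#'
#' @param profiles an [ExonProfileSet] (anchor-normalized values are used
#'   when available, TPM otherwise; the choice does not change ranks within
#'   an exon).
#' @param exonA,exonB exon ids to compare.
#' @param useNormalized use the `"normalized"` assay (default TRUE when
#'   present).
#' @param exactMax maximum per-group n for the exact test (default 8).
#' @return list with `statistic` (U for exonA), `p.value`, `n`, `method`.
#' @export
compareExonLevels <- function(profiles, exonA, exonB,
                              useNormalized = "normalized" %in%
                                SummarizedExperiment::assayNames(profiles),
                              exactMax = 8L) {
  stopifnot(is(profiles, "ExonProfileSet"))
  vals <- if (useNormalized) anchorNormalized(profiles) else exonTpm(profiles)
  cd <- SummarizedExperiment::colData(profiles)
  keep <- !cd$excluded
  x <- vals[as.character(exonA), keep]
  y <- vals[as.character(exonB), keep]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L)
    stop("need at least two usable samples", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) <= exactMax && length(y) <= exactMax
  if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) {
    warning("all values identical in both groups; p = 1")
    return(list(statistic = length(x) * length(y) / 2, p.value = 1,
                n = length(x), method = "degenerate"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n = length(x),
       method = if (exact) "exact" else "normal approximation")
}

#' Locate a single coverage transition (internal TSS) by binary segmentation
#'
#' Scans every admissible breakpoint b and picks the one maximizing the
#' between-segment sum of squares `n1 * n2 / n * (mean2 - mean1)^2`, the
#' single-changepoint least-squares criterion. The transition is reported as
#' the index of the last bin before the break, together with the
#' downstream/upstream mean ratio. When that ratio lies within
#' `[1/ratioThreshold, ratioThreshold]` the profile is flagged as having no
#' transition.
#'
#' @param coverage ordered numeric vector of per-bin coverage.
#' @param minSegment minimum bins per segment (default 3).
#' @param ratioThreshold transition-calling threshold on the mean ratio
#'   (default 1.5).
#' @return list with `breakpoint` (last bin of the upstream segment),
#'   `ratio` (downstream mean / upstream mean; Inf if upstream mean is 0)
#'   and `transition` (logical).
#' @export
detectInternalTss <- function(coverage, minSegment = 3L, ratioThreshold = 1.5) {
  coverage <- as.numeric(coverage)
  n <- length(coverage)
  minSegment <- as.integer(minSegment)
  if (minSegment < 1L) stop("minSegment must be >= 1", call. = FALSE)
  if (n < 2L * minSegment)
    stop("coverage must have at least 2 * minSegment bins", call. = FALSE)
  if (any(!is.finite(coverage)) || any(coverage < 0))
    stop("coverage must be finite and non-negative", call. = FALSE)
  .assertScalarNumber(ratioThreshold, "ratioThreshold", lower = 1)
  candidates <- seq(minSegment, n - minSegment)
  css <- cumsum(coverage)
  bss <- vapply(candidates, function(b) {
    m1 <- css[b] / b
    m2 <- (css[n] - css[b]) / (n - b)
    b * (n - b) / n * (m2 - m1)^2
  }, numeric(1))
  best <- candidates[which.max(bss)]
  m1 <- mean(coverage[seq_len(best)])
  m2 <- mean(coverage[(best + 1):n])
  ratio <- if (m1 > 0) m2 / m1 else if (m2 > 0) Inf else 1
  list(breakpoint = best, ratio = ratio,
       transition = ratio > ratioThreshold || ratio < 1 / ratioThreshold)
}
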