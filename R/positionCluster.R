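.checkDirections <- function(annotation) {
  if (!all(c("gene_id", "biotype", "direction") %in%
           colnames(GenomicRanges::mcols(annotation))))
    stop("annotation needs gene_id, biotype and direction metadata columns",
         call. = FALSE)
  if (!all(annotation$direction %in% c("UP", "DN", "NS")))
    stop("directions must be UP, DN or NS", call. = FALSE)
  invisible(annotation)
}

.chromLengthsOf <- function(annotation, chromLengths) {
  if (!is.null(chromLengths)) return(chromLengths)
  sl <- GenomeInfoDb::seqlengths(annotation)
  if (anyNA(sl))
    stop("chromosome lengths are required (seqlengths unset)", call. = FALSE)
  sl
}

## Category counts of genes (by start coordinate) falling in each window.
.windowCategories <- list(
  genes = function(d, b) rep(TRUE, length(d)),
  coding = function(d, b) b == "protein_coding",
  lncRNA = function(d, b) b == "lncRNA",
  up = function(d, b) d == "UP",
  dn = function(d, b) d == "DN",
  up_coding = function(d, b) d == "UP" & b == "protein_coding",
  up_lncRNA = function(d, b) d == "UP" & b == "lncRNA",
  dn_coding = function(d, b) d == "DN" & b == "protein_coding",
  dn_lncRNA = function(d, b) d == "DN" & b == "lncRNA")

#' Per-chromosome gene counts and densities
#'
#' Counts genes, UP and DN genes (split by coding/lncRNA biotype) per
#' chromosome and converts them to densities per Mb of chromosome length.
#' Genes are attributed to chromosomes by their start position; strand is
#' ignored.
#'
#' @param annotation GRanges with `gene_id`, `biotype` and `direction`
#'   metadata columns (e.g. from [simulateGenome()] or [readAnnotation()]
#'   plus direction labels).
#' @param chromLengths named chromosome lengths in bp (default: taken from
#'   `seqlengths(annotation)`).
#' @return data.frame, one row per chromosome plus a `genome` totals row,
#'   with counts and per-Mb densities per category.
#' @export
chromosomeSummary <- function(annotation, chromLengths = NULL) {
  .checkDirections(annotation)
  chromLengths <- .chromLengthsOf(annotation, chromLengths)
  chrom <- as.character(GenomicRanges::seqnames(annotation))
  if (!all(chrom %in% names(chromLengths)))
    stop("gene on a chromosome missing from chromLengths", call. = FALSE)
  rows <- lapply(names(chromLengths), function(cn) {
    sel <- chrom == cn
    d <- annotation$direction[sel]; b <- annotation$biotype[sel]
    cnt <- vapply(.windowCategories, function(f) sum(f(d, b)), numeric(1))
    mb <- chromLengths[[cn]] / 1e6
    out <- data.frame(chrom = cn, length_bp = chromLengths[[cn]],
                      stringsAsFactors = FALSE)
    out[paste0("n_", names(cnt))] <- as.list(cnt)
    out[paste0("density_", names(cnt))] <- as.list(cnt / mb)
    out
  })
  res <- do.call(rbind, rows)
  d <- annotation$direction; b <- annotation$biotype
  cnt <- vapply(.windowCategories, function(f) sum(f(d, b)), numeric(1))
  mb <- sum(chromLengths) / 1e6
  tot <- data.frame(chrom = "genome", length_bp = sum(chromLengths),
                    stringsAsFactors = FALSE)
  tot[paste0("n_", names(cnt))] <- as.list(cnt)
  tot[paste0("density_", names(cnt))] <- as.list(cnt / mb)
  rbind(res, tot)
}

#' Sliding-window gene-density enrichment scan
#'
#' Slides windows (default 10 Mb, step 1 Mb) along each chromosome, assigns
#' genes to every window covering their start coordinate, and computes per
#' category the fold enrichment of window density over chromosome-average
#' density (`fe_<category>_vs_chrom`). For UP coding genes it also reports
#' `fe_up_coding_vs_local`, the window's UP-coding share of genes divided by
#' the chromosome's UP-coding share - a scale-free measure of UP enrichment
#' beyond local gene density. A final partial window is kept when the
#' chromosome length is not a multiple of the step; its density uses the
#' actual span. Fold enrichments are NA when the chromosome has no gene of
#' the category.
#'
#' @inheritParams chromosomeSummary
#' @param windowBp window span in bp (default 10 Mb).
#' @param stepBp step between window starts in bp (default 1 Mb).
#' @return data.frame of windows with counts and fold enrichments.
#' @export
scanWindows <- function(annotation, windowBp = 1e7, stepBp = 1e6,
                        chromLengths = NULL) {
  .checkDirections(annotation)
  chromLengths <- .chromLengthsOf(annotation, chromLengths)
  if (stepBp <= 0 || windowBp < stepBp)
    stop("need window >= step > 0", call. = FALSE)
  chrom <- as.character(GenomicRanges::seqnames(annotation))
  genePos <- GenomicRanges::start(annotation)
  out <- list()
  for (cn in names(chromLengths)) {
    L <- chromLengths[[cn]]
    w <- min(windowBp, L)  # window larger than chromosome: whole chromosome
    starts <- seq(1, max(1, L - w + 1), by = stepBp)
    if (max(starts) + w - 1 < L) starts <- c(starts, max(starts) + stepBp)
    ends <- pmin(starts + w - 1, L)
    sel <- chrom == cn
    pos <- genePos[sel]
    d <- annotation$direction[sel]; b <- annotation$biotype[sel]
    chromCnt <- vapply(.windowCategories, function(f) sum(f(d, b)),
                       numeric(1))
    chromDen <- chromCnt / L
    winCnt <- matrix(0, length(starts), length(.windowCategories),
                     dimnames = list(NULL, names(.windowCategories)))
    for (ci in seq_along(.windowCategories)) {
      keep <- .windowCategories[[ci]](d, b)
      p <- pos[keep]
      if (length(p))
        winCnt[, ci] <- vapply(seq_along(starts), function(i)
          sum(p >= starts[i] & p <= ends[i]), numeric(1))
    }
    span <- ends - starts + 1
    fe <- sweep(winCnt / span, 2,
                ifelse(chromDen > 0, chromDen, NA_real_), "/")
    colnames(fe) <- paste0("fe_", names(.windowCategories), "_vs_chrom")
    upShareChrom <- if (chromCnt["genes"] > 0)
      chromCnt["up_coding"] / chromCnt["genes"] else NA_real_
    feLocal <- ifelse(winCnt[, "genes"] > 0 & !is.na(upShareChrom) &
                        upShareChrom > 0,
                      (winCnt[, "up_coding"] / winCnt[, "genes"]) /
                        upShareChrom, NA_real_)
    df <- data.frame(chrom = cn, start = starts, end = ends, span = span,
                     stringsAsFactors = FALSE)
    df[paste0("n_", colnames(winCnt))] <- as.data.frame(winCnt)
    df <- cbind(df, as.data.frame(fe))
    df$fe_up_coding_vs_local <- feLocal
    out[[cn]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call UP-gene clusters from a window scan
#'
#' A window qualifies when its UP-coding fold enrichment over the
#' chromosomal average, its UP-coding enrichment over local gene density,
#' and its UP gene count all reach the thresholds. Overlapping or adjacent
#' qualified windows are merged into clusters; each cluster reports its peak
#' window (maximum UP-coding fold enrichment vs chromosome). Default
#' thresholds (2, 2, 5) take the lower bounds of enrichment reported for
#' tumor UP-gene clusters. No multiple-testing correction is applied across
#' windows; cluster calling is a descriptive threshold rule.
#'
#' @param windows data.frame from [scanWindows()].
#' @param annotation optional GRanges used to count UP genes within each
#'   merged cluster exactly (otherwise the peak window's count is reported).
#' @param feChromMin minimum UP-coding fold enrichment vs chromosome
#'   (default 2).
#' @param feLocalMin minimum UP-coding enrichment vs local gene density
#'   (default 2).
#' @param minUp minimum UP genes per window (default 5).
#' @return data.frame of clusters: chrom, start, end, peak_start, peak_end,
#'   peak_fe_chrom, peak_fe_local, n_up, n_windows.
#' @importFrom IRanges IRanges reduce
#' @export
callClusters <- function(windows, annotation = NULL, feChromMin = 2,
                         feLocalMin = 2, minUp = 5) {
  need <- c("chrom", "start", "end", "n_up", "fe_up_coding_vs_chrom",
            "fe_up_coding_vs_local")
  stopifnot(all(need %in% colnames(windows)))
  q <- !is.na(windows$fe_up_coding_vs_chrom) &
    !is.na(windows$fe_up_coding_vs_local) &
    windows$fe_up_coding_vs_chrom >= feChromMin &
    windows$fe_up_coding_vs_local >= feLocalMin &
    windows$n_up >= minUp
  if (!any(q))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), peak_start = numeric(0),
                      peak_end = numeric(0), peak_fe_chrom = numeric(0),
                      peak_fe_local = numeric(0), n_up = numeric(0),
                      n_windows = integer(0), stringsAsFactors = FALSE))
  qual <- windows[q, , drop = FALSE]
  out <- list()
  for (cn in unique(qual$chrom)) {
    qc <- qual[qual$chrom == cn, , drop = FALSE]
    merged <- IRanges::reduce(IRanges(qc$start, qc$end), min.gapwidth = 1L)
    for (i in seq_along(merged)) {
      s <- IRanges::start(merged)[i]; e <- IRanges::end(merged)[i]
      inC <- qc$start >= s & qc$end <= e
      peak <- qc[inC, , drop = FALSE]
      peak <- peak[which.max(peak$fe_up_coding_vs_chrom), , drop = FALSE]
      nUp <- if (!is.null(annotation)) {
        sel <- as.character(GenomicRanges::seqnames(annotation)) == cn &
          GenomicRanges::start(annotation) >= s &
          GenomicRanges::start(annotation) <= e &
          annotation$direction == "UP"
        sum(sel)
      } else peak$n_up
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn, start = s, end = e,
        peak_start = peak$start, peak_end = peak$end,
        peak_fe_chrom = peak$fe_up_coding_vs_chrom,
        peak_fe_local = peak$fe_up_coding_vs_local,
        n_up = nUp, n_windows = sum(inC), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' lncRNA fractions among UP and DN genes
#'
#' Reports the lncRNA share of each direction class with an exact
#' Clopper-Pearson 95% binomial confidence interval.
#'
#' @inheritParams chromosomeSummary
#' @param confLevel confidence level (default 0.95).
#' @return data.frame with one row per direction (UP, DN): n, n_lncRNA,
#'   fraction, ci_lower, ci_upper. Empty classes get NA fractions with a
#'   warning.
#' @export
biotypeFractions <- function(annotation, confLevel = 0.95) {
  .checkDirections(annotation)
  rows <- lapply(c("UP", "DN"), function(dir) {
    sel <- annotation$direction == dir
    n <- sum(sel)
    k <- sum(sel & annotation$biotype == "lncRNA")
    if (n == 0) {
      warning("no ", dir, " genes; fraction undefined")
      return(data.frame(direction = dir, n = 0, n_lncRNA = 0,
                        fraction = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, stringsAsFactors = FALSE))
    }
    ci <- stats::binom.test(k, n, conf.level = confLevel)$conf.int
    data.frame(direction = dir, n = n, n_lncRNA = k, fraction = k / n,
               ci_lower = ci[1], ci_upper = ci[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Hypergeometric gene-set overlap enrichment
#'
#' For each named set, tests whether the query list overlaps it more than
#' expected by chance in the given universe: upper-tail hypergeometric
#' `P(X >= k)` with universe size N, set size K (after intersecting the set
#' with the universe), query size n and overlap k. q-values are BH-adjusted
#' across the collection and results are sorted by p.
#'
#' @param query character vector of gene ids (must be within the universe).
#' @param collection named list of character vectors (gene sets).
#' @param universe character vector of all testable gene ids.
#' @return data.frame: set, set_size, query_size, universe_size, overlap,
#'   percent_overlap, p, q.
#' @export
overlapEnrichment <- function(query, collection, universe) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (!length(query)) stop("empty query", call. = FALSE)
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query must be a subset of the universe", call. = FALSE)
  if (!length(collection) || is.null(names(collection)))
    stop("collection must be a named list of gene sets", call. = FALSE)
  N <- length(universe); n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(set, query))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, query_size = n, universe_size = N,
               overlap = k,
               percent_overlap = if (K > 0) 100 * k / K else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- adjustBH(res$p)
  res <- res[order(res$p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad)) stop("malformed GMT line(s): need name, description, genes",
                     call. = FALSE)
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names", call. = FALSE)
  sets
}
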