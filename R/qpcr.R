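.checkCtRecords <- function(records) {
  need <- c("sample_id", "amplicon", "ct", "reference_ct")
  if (!is.data.frame(records) || !all(need %in% colnames(records)))
    stop("Ct records need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(records$ct)) || any(!is.finite(records$reference_ct)))
    stop("Ct values must be finite", call. = FALSE)
  if (any(records$ct < 10 | records$ct > 40))
    warning("Ct values outside the typical 10-40 cycle range")
  invisible(records)
}

#' Comparative-Ct (2^-ddCt) relative quantification
#'
#' Replicate wells are averaged per (sample, amplicon); then per record
#' `dCt = ct - reference_ct`, `ddCt = dCt - mean dCt of the calibrator
#' samples for the same amplicon`, and `rq = 2^-ddCt`. By construction the
#' calibrator group's geometric mean RQ is 1 for every amplicon.
#'
#' @param records data.frame with sample_id, amplicon, ct, reference_ct.
#' @param calibrator character vector of calibrator sample ids (e.g. the
#'   stage-0 samples).
#' @return data.frame: sample_id, amplicon, dct, ddct, rq, calibrator
#'   (logical flag).
#' @export
computeRq <- function(records, calibrator) {
  .checkCtRecords(records)
  if (!length(calibrator) || !any(calibrator %in% records$sample_id))
    stop("calibrator samples not found in records", call. = FALSE)
  ## average replicate wells
  agg <- stats::aggregate(cbind(ct, reference_ct) ~ sample_id + amplicon,
                          data = records, FUN = mean)
  agg$dct <- agg$ct - agg$reference_ct
  out <- NULL
  for (a in unique(agg$amplicon)) {
    sub <- agg[agg$amplicon == a, , drop = FALSE]
    cal <- sub$dct[sub$sample_id %in% calibrator]
    if (!length(cal))
      stop("amplicon ", a, " has no calibrator record", call. = FALSE)
    sub$ddct <- sub$dct - mean(cal)
    sub$rq <- 2^(-sub$ddct)
    sub$calibrator <- sub$sample_id %in% calibrator
    out <- rbind(out, sub)
  }
  rownames(out) <- NULL
  out[c("sample_id", "amplicon", "dct", "ddct", "rq", "calibrator")]
}

.significanceBand <- function(p) {
  ifelse(is.na(p), NA_character_,
  ifelse(p < 0.001, "***",
  ifelse(p < 0.01, "**",
  ifelse(p < 0.05, "*", "ns"))))
}

#' Per-stage RQ summaries and between-amplicon tests
#'
#' Summarizes relative quantities per stage and amplicon (n, mean, median,
#' quartiles) and, within each stage, compares two amplicons' RQ values with
#' a two-sample unpaired Welch t test (pooled-variance optional).
#' Significance bands follow the convention *P < 0.05, **P < 0.01,
#' ***P < 0.001. Stages with fewer than two samples are summarized but not
#' tested.
#'
#' @param rq data.frame from [computeRq()].
#' @param metadata data.frame with sample_id and stage columns.
#' @param ampliconPair the two amplicons to compare (default the first two
#'   present).
#' @param pooled use the pooled-variance t test instead of Welch (default
#'   FALSE).
#' @return list with `summary` (per stage x amplicon) and `tests` (per
#'   stage: t, df, p, band, tested flag).
#' @export
aggregateByStage <- function(rq, metadata, ampliconPair = NULL,
                             pooled = FALSE) {
  stopifnot(all(c("sample_id", "amplicon", "rq") %in% colnames(rq)),
            all(c("sample_id", "stage") %in% colnames(metadata)))
  if (!all(rq$sample_id %in% metadata$sample_id))
    stop("every RQ sample must appear in the metadata", call. = FALSE)
  rq$stage <- metadata$stage[match(rq$sample_id, metadata$sample_id)]
  if (is.null(ampliconPair)) ampliconPair <- unique(rq$amplicon)[1:2]
  if (length(ampliconPair) != 2L ||
      !all(ampliconPair %in% rq$amplicon))
    stop("ampliconPair must name two amplicons present in the data",
         call. = FALSE)
  stages <- intersect(.stageLevels, unique(rq$stage))
  summ <- do.call(rbind, lapply(stages, function(s) {
    do.call(rbind, lapply(unique(rq$amplicon), function(a) {
      v <- rq$rq[rq$stage == s & rq$amplicon == a]
      data.frame(stage = s, amplicon = a, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 median = if (length(v)) stats::median(v) else NA_real_,
                 q1 = if (length(v)) unname(stats::quantile(v, 0.25)) else NA_real_,
                 q3 = if (length(v)) unname(stats::quantile(v, 0.75)) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  tests <- do.call(rbind, lapply(stages, function(s) {
    x <- rq$rq[rq$stage == s & rq$amplicon == ampliconPair[1]]
    y <- rq$rq[rq$stage == s & rq$amplicon == ampliconPair[2]]
    if (length(x) < 2L || length(y) < 2L)
      return(data.frame(stage = s, t = NA_real_, df = NA_real_,
                        p = NA_real_, band = NA_character_, tested = FALSE,
                        stringsAsFactors = FALSE))
    if (stats::sd(x) == 0 && stats::sd(y) == 0 && x[1] == y[1])
      return(data.frame(stage = s, t = 0, df = NA_real_, p = 1, band = "ns",
                        tested = TRUE, stringsAsFactors = FALSE))
    tt <- stats::t.test(x, y, var.equal = pooled)
    data.frame(stage = s, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               band = .significanceBand(tt$p.value), tested = TRUE,
               stringsAsFactors = FALSE)
  }))
  list(summary = summ, tests = tests)
}

#' Pearson correlation between two amplicons' relative quantities
#'
#' Pairs samples across the two amplicons and computes Pearson's r with the
#' t-reference two-sided p-value. The default scale is log2(rq) because RQ
#' is multiplicative; linear is available.
#'
#' @param rq data.frame from [computeRq()].
#' @param pair the two amplicon labels.
#' @param scale `"log2"` (default) or `"linear"`.
#' @return list with `r`, `n`, `p.value`, `scale`; r is NA (flagged via
#'   `degenerate = TRUE`) when either vector has zero variance.
#' @export
ampliconCorrelation <- function(rq, pair, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  stopifnot(all(c("sample_id", "amplicon", "rq") %in% colnames(rq)),
            length(pair) == 2L)
  x <- rq[rq$amplicon == pair[1], c("sample_id", "rq")]
  y <- rq[rq$amplicon == pair[2], c("sample_id", "rq")]
  m <- merge(x, y, by = "sample_id", suffixes = c("_a", "_b"))
  if (nrow(m) < 3L)
    stop("need at least three paired samples", call. = FALSE)
  a <- m$rq_a; b <- m$rq_b
  if (scale == "log2") { a <- log2(a); b <- log2(b) }
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, n = nrow(m), p.value = NA_real_,
                scale = scale, degenerate = TRUE))
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), n = nrow(m), p.value = ct$p.value,
       scale = scale, degenerate = FALSE)
}
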