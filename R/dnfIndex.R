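#' Classify AD:RD ratios into DNF groups A-D
#'
#' Segmentation of the per-tumor anchor-domain : replication-domain
#' expression ratio: A for more than twofold AD elevation, C for balanced
#' domains (within 10%), B intermediate, D for AD depletion. Boundary
#' conventions: A = (2, Inf); B = (1.1, 2]; C = \[0.9, 1.1\]; D = (0, 0.9).
#' C is closed so ties at 0.9/1.1 fall to the conservative "balanced" call,
#' and "exceeds 2" is honored strictly. Every positive finite ratio receives
#' exactly one label.
#'
#' @param ratio numeric vector of positive finite ratios.
#' @return factor with levels A, B, C, D.
#' @export
classifyDnfGroup <- function(ratio) {
  if (!is.numeric(ratio) || any(!is.finite(ratio)) || any(ratio <= 0))
    stop("ratios must be positive and finite", call. = FALSE)
  g <- ifelse(ratio > 2, "A",
       ifelse(ratio > 1.1, "B",
       ifelse(ratio >= 0.9, "C", "D")))
  factor(g, levels = c("A", "B", "C", "D"))
}

#' Compute the per-sample DNF index
#'
#' The DNF (dominant-negative fragment) index is the ratio of anchor-domain
#' to replication-domain expression, by default exon 14 TPM over exon 5 TPM.
#' The ratio is computed on raw within-gene TPM; it is identical on
#' anchor-normalized values because the anchor cancels. Samples with zero RD
#' signal are excluded with a reason instead of erroring.
#'
#' @param profiles an [ExonProfileSet].
#' @param adExon anchor-domain exon id (default 14).
#' @param rdExon replication-domain exon id (default 5).
#' @return data.frame with columns sample_id, ratio, group, excluded,
#'   reason. Excluded samples have NA ratio and group.
#' @export
computeDnfIndex <- function(profiles, adExon = 14L, rdExon = 5L) {
  stopifnot(is(profiles, "ExonProfileSet"))
  model <- exonModel(profiles)
  if (!all(c(adExon, rdExon) %in% exonIds(model)))
    stop("AD/RD exons must be present in the exon model", call. = FALSE)
  tpm <- exonTpm(profiles)
  ad <- tpm[as.character(adExon), ]
  rd <- tpm[as.character(rdExon), ]
  excluded <- rd == 0
  ratio <- ifelse(excluded, NA_real_, ad / rd)
  ## an AD of 0 with nonzero RD is a valid (tiny) ratio only if positive;
  ## ratio 0 cannot be grouped, treat as excluded too
  zeroAd <- !excluded & ad == 0
  excluded <- excluded | zeroAd
  ratio[zeroAd] <- NA_real_
  grp <- rep(NA_character_, length(ratio))
  grp[!excluded] <- as.character(classifyDnfGroup(ratio[!excluded]))
  data.frame(
    sample_id = colnames(tpm),
    ratio = unname(ratio),
    group = grp,
    excluded = unname(excluded),
    reason = ifelse(rd == 0, "zero RD signal",
             ifelse(zeroAd, "zero AD signal", NA_character_)),
    stringsAsFactors = FALSE)
}

#' Per-stratum DNF group composition
#'
#' Tabulates DNF group counts and proportions per stratum of the sample
#' metadata (or for the whole cohort), and tests each stratum's profile
#' against the cohort-wide profile with the goodness-of-fit chi-squared of
#' [profileChiSquared()]. Excluded samples are reported but never counted.
#'
#' @param records data.frame from [computeDnfIndex()].
#' @param metadata data.frame with sample_id and stratification columns.
#' @param stratifyBy metadata column to stratify on (e.g. `"stage"`), or
#'   `"none"` for a single cohort-wide profile.
#' @return data.frame, one row per stratum, with n, per-group counts
#'   (`n_A`..`n_D`), proportions (`p_A`..`p_D`), `n_excluded`, and the
#'   chi-squared comparison to the cohort profile (`chi2`, `df`, `p`;
#'   NA for the cohort row itself).
#' @export
cohortProfile <- function(records, metadata = NULL, stratifyBy = "none") {
  stopifnot(is.data.frame(records),
            all(c("sample_id", "group", "excluded") %in% colnames(records)))
  if (stratifyBy != "none") {
    if (is.null(metadata))
      stop("metadata is required for stratification", call. = FALSE)
    if (!stratifyBy %in% colnames(metadata))
      stop("unknown stratification column: ", stratifyBy, call. = FALSE)
    if (!all(records$sample_id %in% metadata$sample_id))
      stop("every sample must appear in the metadata", call. = FALSE)
    stratum <- metadata[[stratifyBy]][match(records$sample_id,
                                            metadata$sample_id)]
  } else {
    stratum <- rep("cohort", nrow(records))
  }
  groups <- c("A", "B", "C", "D")
  tallyOne <- function(rec, label) {
    inc <- rec[!rec$excluded, , drop = FALSE]
    cnt <- table(factor(inc$group, levels = groups))
    n <- sum(cnt)
    props <- if (n > 0) as.numeric(cnt) / n else rep(NA_real_, 4)
    out <- data.frame(stratum = label, n = n,
                      n_excluded = sum(rec$excluded),
                      stringsAsFactors = FALSE)
    out[paste0("n_", groups)] <- as.list(as.numeric(cnt))
    out[paste0("p_", groups)] <- as.list(props)
    out
  }
  cohort <- tallyOne(records, "cohort")
  cohortProps <- as.numeric(cohort[paste0("p_", groups)])
  rows <- list(cohort)
  if (stratifyBy != "none") {
    for (s in unique(stratum)) {
      rec <- records[stratum == s, , drop = FALSE]
      row <- tallyOne(rec, as.character(s))
      if (row$n > 0 && !anyNA(cohortProps)) {
        cs <- profileChiSquared(as.numeric(row[paste0("n_", groups)]),
                                cohortProps)
        row$chi2 <- cs$chi2; row$df <- cs$df; row$p <- cs$p
      } else {
        row$chi2 <- NA_real_; row$df <- NA_integer_; row$p <- NA_real_
      }
      rows <- c(rows, list(row))
    }
  }
  rows[[1]]$chi2 <- NA_real_; rows[[1]]$df <- NA_integer_
  rows[[1]]$p <- NA_real_
  do.call(rbind, rows)
}

#' Goodness-of-fit chi-squared of a subset profile against cohort proportions
#'
#' Tests whether a stratum's DNF group composition differs from the
#' cohort-wide profile: expected counts are `cohort proportion * subset n`,
#' the statistic is `sum((obs - exp)^2 / exp)` over groups with positive
#' expectation, df = (number of such groups) - 1. Groups with zero expected
#' and zero observed counts are dropped; a zero expectation with positive
#' observations makes the test degenerate (p = 0, flagged).
#'
#' @param observed integer vector of subset group counts.
#' @param cohortProportions cohort proportions (same length, summing to 1).
#' @return list with `chi2`, `df`, `p`, `degenerate`.
#' @export
profileChiSquared <- function(observed, cohortProportions) {
  if (length(observed) != length(cohortProportions))
    stop("observed and cohortProportions must have equal length",
         call. = FALSE)
  if (anyNA(cohortProportions) ||
      abs(sum(cohortProportions) - 1) > 1e-8)
    stop("cohort proportions must be defined and sum to 1", call. = FALSE)
  n <- sum(observed)
  if (n < 1) stop("subset must contain at least one sample", call. = FALSE)
  if (n < 5 * length(observed))
    warning("small subset; chi-squared approximation may be poor")
  expected <- cohortProportions * n
  if (any(expected == 0 & observed > 0))
    return(list(chi2 = Inf, df = NA_integer_, p = 0, degenerate = TRUE))
  keep <- expected > 0
  chi2 <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  df <- sum(keep) - 1L
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p, degenerate = FALSE)
}
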