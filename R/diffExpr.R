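#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features of the ratio
#' of that sample's count to the feature's geometric mean across samples,
#' using only features with nonzero counts in every sample. Factors are
#' rescaled to geometric mean 1. If no feature is nonzero in all samples the
#' total-count ratio is used instead, with a warning.
#'
#' @param counts feature x sample count matrix.
#' @return named numeric vector of positive size factors (geometric mean 1).
#' @export
estimateSizeFactors <- function(counts) {
  .assertCountMatrix(counts)
  geoMeans <- exp(rowMeans(log(counts)))
  usable <- geoMeans > 0
  if (!any(usable)) {
    warning("no feature has nonzero counts in all samples; ",
            "falling back to total-count size factors")
    sf <- colSums(counts)
    if (any(sf == 0)) stop("sample with zero total counts", call. = FALSE)
  } else {
    sf <- apply(counts[usable, , drop = FALSE], 2, function(x)
      stats::median(x / geoMeans[usable]))
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Method-of-moments NB dispersion estimates with optional trend shrinkage
#'
#' Per feature, within-group moments of size-factor-normalized counts give
#' `phi_g = (s2_g - mu_g * mean(1/sf_g)) / mu_g^2` (the `mean(1/sf)` term is
#' the Poisson variance contribution after normalization); group estimates
#' are pooled with df weights. Optionally the raw estimates are shrunk
#' toward a mean-dispersion trend `phi(mu) = a / mu + b` fitted by least
#' squares, with weight `shrinkWeight`, which stabilizes the noisy
#' per-feature moments at small sample sizes. Estimates are truncated at 0
#' after shrinkage. Features with all-zero counts get NA and are skipped
#' downstream.
#'
#' @param counts feature x sample count matrix.
#' @param sf size factors (default [estimateSizeFactors()]).
#' @param groups two-level factor of sample conditions.
#' @param shrink apply trend shrinkage (default TRUE).
#' @param shrinkWeight weight of the trend in the shrunk estimate
#'   (default 0.5).
#' @return named numeric vector of dispersions with attribute
#'   `method` (`"moments"` or `"trend-shrunk"`).
#' @export
estimateDispersions <- function(counts, sf = estimateSizeFactors(counts),
                                groups, shrink = TRUE, shrinkWeight = 0.5) {
  .assertCountMatrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L || any(table(groups) < 2L))
    stop("groups must have two levels with >= 2 samples each", call. = FALSE)
  .assertScalarNumber(shrinkWeight, "shrinkWeight", 0, 1)
  y <- sweep(counts, 2, sf, "/")
  phiRaw <- rep(NA_real_, nrow(counts))
  muAll <- rowMeans(y)
  num <- 0; den <- 0
  phiAcc <- matrix(NA_real_, nrow(counts), 2)
  wAcc <- numeric(2)
  for (g in seq_len(2L)) {
    idx <- groups == levels(groups)[g]
    mu <- rowMeans(y[, idx, drop = FALSE])
    s2 <- apply(y[, idx, drop = FALSE], 1, stats::var)
    poisTerm <- mu * mean(1 / sf[idx])
    phiAcc[, g] <- ifelse(mu > 0, (s2 - poisTerm) / mu^2, NA_real_)
    wAcc[g] <- sum(idx) - 1
  }
  ok <- rowSums(!is.na(phiAcc)) > 0
  phiRaw[ok] <- apply(phiAcc[ok, , drop = FALSE], 1, function(z)
    sum(z * wAcc, na.rm = TRUE) / sum(wAcc[!is.na(z)]))
  method <- "moments"
  phi <- phiRaw
  if (shrink) {
    fitIdx <- ok & muAll > 0 & is.finite(phiRaw)
    if (sum(fitIdx) >= 10) {
      fit <- stats::lm(phiRaw[fitIdx] ~ I(1 / muAll[fitIdx]))
      trend <- pmax(0, stats::coef(fit)[1] + stats::coef(fit)[2] / muAll)
      phi <- (1 - shrinkWeight) * phiRaw + shrinkWeight * trend
      method <- "trend-shrunk"
    }
  }
  phi <- pmax(0, phi)
  phi[!ok] <- NA_real_
  structure(stats::setNames(phi, rownames(counts)), method = method)
}

#' Two-group negative-binomial Wald test
#'
#' For each feature, group means of size-factor-normalized counts give
#' `log2FC = log2(mu2 / mu1)` (group 2 vs group 1, i.e. the second factor
#' level vs the first). When one group's mean is zero, half the smallest
#' positive normalized count of that feature is added to both means, keeping
#' the fold change finite without a global pseudocount. The standard error
#' comes from the delta method on the NB variance `mu + phi * mu^2` summed
#' over samples, and the two-sided p-value from the normal reference of
#' `log2FC / se`. Features with no nonzero count in either group are
#' reported untested (NA).
#'
#' @param counts feature x sample count matrix.
#' @param groups two-level factor (log2FC is level 2 vs level 1).
#' @param sf size factors (default estimated).
#' @param dispersions per-feature dispersions (default estimated with trend
#'   shrinkage).
#' @return data.frame with feature_id, baseMean, log2FC, se, stat, p.
#' @export
nbWaldTest <- function(counts, groups, sf = estimateSizeFactors(counts),
                       dispersions = estimateDispersions(counts, sf, groups)) {
  .assertCountMatrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L || any(table(groups) < 2L))
    stop("groups must have two levels with >= 2 samples each", call. = FALSE)
  if (length(dispersions) != nrow(counts))
    stop("need one dispersion per feature", call. = FALSE)
  y <- sweep(counts, 2, sf, "/")
  i1 <- groups == levels(groups)[1]
  i2 <- groups == levels(groups)[2]
  mu1 <- rowMeans(y[, i1, drop = FALSE])
  mu2 <- rowMeans(y[, i2, drop = FALSE])
  baseMean <- rowMeans(y)
  minPos <- apply(y, 1, function(z) {
    z <- z[z > 0]
    if (length(z)) min(z) else NA_real_
  })
  tested <- !is.na(minPos) & !is.na(dispersions)
  pseudo <- ifelse(mu1 == 0 | mu2 == 0, minPos / 2, 0)
  a1 <- mu1 + pseudo
  a2 <- mu2 + pseudo
  n1 <- sum(i1); n2 <- sum(i2)
  phi <- pmax(dispersions, 0)
  v1 <- (a1 * sum(1 / sf[i1]) + phi * a1^2 * n1) / n1^2
  v2 <- (a2 * sum(1 / sf[i2]) + phi * a2^2 * n2) / n2^2
  log2FC <- log2(a2 / a1)
  se <- sqrt(v1 / a1^2 + v2 / a2^2) / log(2)
  stat <- log2FC / se
  p <- 2 * stats::pnorm(-abs(stat))
  out <- data.frame(feature_id = rownames(counts), baseMean = baseMean,
                    log2FC = log2FC, se = se, stat = stat, p = p,
                    stringsAsFactors = FALSE)
  out[!tested, c("log2FC", "se", "stat", "p")] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min over j >= i of p_(j) * m / j`,
#' capped at 1, returned in input order (delegates to
#' [stats::p.adjust()] after validating the inputs).
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed for untested
#'   features).
#' @return vector of q-values in input order.
#' @export
adjustBH <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Call differential-expression directions
#'
#' UP iff `log2FC >= lfcMin` and `q < qMax`; DN iff `log2FC <= -lfcMin` and
#' `q < qMax`; NS otherwise. The defaults are the stringent thresholds
#' |log2FC| >= 1 and BH q < 0.05. Untested features (NA) stay NS.
#'
#' @param results data.frame with log2FC and q columns.
#' @param lfcMin minimum absolute log2 fold change (default 1).
#' @param qMax FDR threshold (default 0.05).
#' @return `results` with a `direction` column (factor UP/DN/NS).
#' @export
callDegs <- function(results, lfcMin = 1, qMax = 0.05) {
  stopifnot(all(c("log2FC", "q") %in% colnames(results)))
  .assertScalarNumber(lfcMin, "lfcMin", lower = 0)
  .assertScalarNumber(qMax, "qMax", lower = 0, upper = 1)
  dir <- rep("NS", nrow(results))
  ok <- !is.na(results$log2FC) & !is.na(results$q)
  dir[ok & results$log2FC >= lfcMin & results$q < qMax] <- "UP"
  dir[ok & results$log2FC <= -lfcMin & results$q < qMax] <- "DN"
  results$direction <- factor(dir, levels = c("UP", "DN", "NS"))
  results
}

#' Rank features by pi value
#'
#' The pi value is `log2FC * (-log10 q)`, combining effect size and
#' significance into one signed ranking score. q-values of 0 are clamped to
#' 1e-300 before the log so ranks are preserved without infinities.
#'
#' @param results data.frame with feature_id, log2FC and q columns.
#' @return `results` with a `pi` column, sorted by decreasing pi (ties
#'   broken by feature id).
#' @export
piRank <- function(results) {
  stopifnot(all(c("feature_id", "log2FC", "q") %in% colnames(results)))
  q <- results$q
  if (any(!is.na(q) & q == 0)) {
    warning("q-values of 0 clamped to 1e-300 for pi ranking")
    q[!is.na(q) & q == 0] <- 1e-300
  }
  results$pi <- results$log2FC * (-log10(q))
  ord <- order(-results$pi, results$feature_id, na.last = TRUE)
  results[ord, , drop = FALSE]
}

#' Full two-group NB differential-expression analysis
#'
#' Convenience pipeline: size factors, dispersion estimation, Wald test, BH
#' adjustment, direction calls and pi values. Applies unchanged to gene-level
#' RNA counts and to ATAC consensus-peak interval counts (features are
#' interval ids).
#'
#' @inheritParams nbWaldTest
#' @inheritParams callDegs
#' @param shrink,shrinkWeight dispersion-shrinkage settings, see
#'   [estimateDispersions()].
#' @return data.frame (one row per feature, input order) with baseMean,
#'   log2FC, se, stat, p, q, direction, pi.
#' @export
runDeAnalysis <- function(counts, groups, lfcMin = 1, qMax = 0.05,
                          shrink = TRUE, shrinkWeight = 0.5) {
  sf <- estimateSizeFactors(counts)
  disp <- estimateDispersions(counts, sf, groups, shrink = shrink,
                              shrinkWeight = shrinkWeight)
  res <- nbWaldTest(counts, groups, sf, disp)
  res$q <- adjustBH(res$p)
  res <- callDegs(res, lfcMin = lfcMin, qMax = qMax)
  qc <- ifelse(!is.na(res$q) & res$q == 0, 1e-300, res$q)
  res$pi <- res$log2FC * (-log10(qc))
  res
}
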