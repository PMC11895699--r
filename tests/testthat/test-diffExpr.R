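mkCounts <- function(m, nr, nc, prefix = "f") {
  dimnames(m) <- list(sprintf("%s%03d", prefix, seq_len(nr)),
                      paste0("S", seq_len(nc)))
  storage.mode(m) <- "integer"
  m
}

test_that("size factors match the median-of-ratios definition", {
  ## identical columns: all factors 1
  m <- mkCounts(matrix(rep(c(5L, 10L, 20L), 4), 3, 4), 3, 4)
  expect_true(all(abs(estimateSizeFactors(m) - 1) < 1e-12))

  ## doubling one column doubles its factor relative to the others
  m2 <- m; m2[, 2] <- m2[, 2] * 2L
  sf <- estimateSizeFactors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)

  ## random matrices agree with the brute-force oracle
  set.seed(21)
  for (i in 1:5) {
    r <- mkCounts(matrix(rpois(20 * 4, 100) + 1L, 20, 4), 20, 4)
    expect_equal(estimateSizeFactors(r), sizeFactorOracle(r),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }

  ## geometric mean is 1 by construction
  expect_equal(exp(mean(log(estimateSizeFactors(m2)))), 1, tolerance = 1e-9)

  ## fallback when no feature is positive everywhere
  z <- mkCounts(matrix(c(0L, 5L, 3L, 0L), 2, 2), 2, 2)
  expect_warning(sfz <- estimateSizeFactors(z), "falling back")
  expect_equal(exp(mean(log(sfz))), 1, tolerance = 1e-9)
})

test_that("dispersion estimates recover simulated values", {
  groups <- factor(rep(c("g1", "g2"), each = 100))
  set.seed(22)
  ## Poisson data: median estimate near 0
  mp <- mkCounts(matrix(rpois(300 * 200, 200), 300, 200), 300, 200)
  dp <- estimateDispersions(mp, rep(1, 200), groups, shrink = FALSE)
  expect_lte(stats::median(dp, na.rm = TRUE), 0.01)

  ## NB data with phi = 0.2: mean estimate within [0.15, 0.25]
  mn <- mkCounts(matrix(rnbinom(300 * 200, mu = 200, size = 5), 300, 200),
                 300, 200)
  dn <- estimateDispersions(mn, rep(1, 200), groups, shrink = FALSE)
  expect_gte(mean(dn, na.rm = TRUE), 0.15)
  expect_lte(mean(dn, na.rm = TRUE), 0.25)

  ## constant counts: variance 0 truncates to 0
  mc <- mkCounts(matrix(7L, 5, 8), 5, 8)
  dc <- estimateDispersions(mc, rep(1, 8), factor(rep(c("a", "b"), 4)),
                            shrink = FALSE)
  expect_true(all(dc == 0))
})

test_that("the Wald test is exact on noiseless ratios and null-centered", {
  groups <- factor(rep(c("g1", "g2"), each = 4))
  ## group2 = 4 x group1 deterministically: log2FC = 2 exactly
  m <- mkCounts(matrix(rep(c(50L, 50L, 50L, 50L, 200L, 200L, 200L, 200L),
                           3), 3, 8, byrow = TRUE), 3, 8)
  res <- nbWaldTest(m, groups, sf = rep(1, 8),
                    dispersions = rep(0, 3))
  expect_equal(res$log2FC, rep(2, 3), tolerance = 1e-12)

  ## identical group means: log2FC 0, p near 1
  m0 <- mkCounts(matrix(1000L, 3, 8), 3, 8)
  r0 <- nbWaldTest(m0, groups, sf = rep(1, 8), dispersions = rep(0, 3))
  expect_equal(r0$log2FC, rep(0, 3))
  expect_equal(r0$p, rep(1, 3))

  ## all-zero features are reported untested
  mz <- m; mz[2, ] <- 0L
  rz <- nbWaldTest(mz, groups, sf = rep(1, 8), dispersions = rep(0, 3))
  expect_true(is.na(rz$p[2]))
  expect_false(anyNA(rz$p[-2]))
})

test_that("label swap negates log2FC and preserves p", {
  set.seed(23)
  sim <- simulateDegCounts(DegSimSpec(nFeatures = 50, nPerGroup = c(6, 8),
                                      dispersion = 0.1, seed = 24))
  g <- sim$condition
  gSwap <- factor(as.character(g), levels = rev(levels(g)))
  sf <- estimateSizeFactors(sim$counts)
  disp <- estimateDispersions(sim$counts, sf, g)
  a <- nbWaldTest(sim$counts, g, sf, disp)
  b <- nbWaldTest(sim$counts, gSwap, sf, disp)
  expect_equal(a$log2FC, -b$log2FC, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("rescaling a sample's counts moves its size factor, not the fold changes", {
  set.seed(25)
  sim <- simulateDegCounts(DegSimSpec(nFeatures = 200, nPerGroup = c(5, 5),
                                      dispersion = 0.05, librarySizeCv = 0,
                                      seed = 26))
  counts2 <- sim$counts
  counts2[, 3] <- counts2[, 3] * 3L
  sf1 <- estimateSizeFactors(sim$counts)
  sf2 <- estimateSizeFactors(counts2)
  expect_equal(unname(sf2[3] / sf1[3] / (sf2[1] / sf1[1])), 3,
               tolerance = 1e-9)
  r1 <- nbWaldTest(sim$counts, sim$condition, sf1,
                   dispersions = rep(0.05, 200))
  r2 <- nbWaldTest(counts2, sim$condition, sf2,
                   dispersions = rep(0.05, 200))
  expect_equal(r1$log2FC, r2$log2FC, tolerance = 1e-9)
})

test_that("BH adjustment equals the step-up oracle and validates input", {
  expect_equal(adjustBH(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjustBH(0.2), 0.2)
  expect_equal(adjustBH(rep(1, 5)), rep(1, 5))
  expect_error(adjustBH(c(0.5, 1.2)), "0, 1")
  set.seed(27)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(adjustBH(p), bhStepUpOracle(p), tolerance = 1e-12)
  }
})

test_that("direction calls apply the thresholds with >= on the boundary", {
  res <- data.frame(feature_id = paste0("f", 1:4),
                    log2FC = c(2, -2, 1.0, 0.5),
                    q = c(0.01, 0.2, 0.049, 0.001))
  out <- callDegs(res)
  expect_identical(as.character(out$direction), c("UP", "NS", "UP", "NS"))
  out2 <- callDegs(res, lfcMin = 0.4, qMax = 0.3)
  expect_identical(as.character(out2$direction), c("UP", "DN", "UP", "UP"))
})

test_that("pi values multiply effect size and significance", {
  res <- data.frame(feature_id = c("a", "b", "c"),
                    log2FC = c(2, 0, -1), q = c(0.01, 1e-8, 0.1))
  out <- piRank(res)
  expect_equal(out$pi[out$feature_id == "a"], 4)
  expect_equal(out$pi[out$feature_id == "b"], 0)
  expect_equal(out$pi[out$feature_id == "c"], -1)
  expect_identical(out$feature_id[1], "a")  # descending pi
  expect_warning(piRank(data.frame(feature_id = "z", log2FC = 1, q = 0)),
                 "clamped")
})

test_that("Poisson-limit p-values agree with an independent Poisson Wald oracle", {
  set.seed(28)
  n <- c(10, 10)
  groups <- factor(rep(c("g1", "g2"), n))
  mu <- exp(runif(100, log(50), log(2000)))
  shift <- 2^runif(100, -1, 1)
  m <- matrix(0L, 100, sum(n))
  for (f in 1:100) {
    m[f, ] <- rpois(sum(n), mu[f] * ifelse(groups == "g2", shift[f], 1))
  }
  m <- mkCounts(m, 100, sum(n))
  sf <- rep(1, sum(n))
  res <- nbWaldTest(m, groups, sf, dispersions = rep(1e-8, 100))
  oracle <- poissonWaldOracle(m, groups, sf)
  expect_true(all(abs(res$p - oracle) / pmax(oracle, 1e-12) < 0.1))
})

test_that("the full pipeline is calibrated on null data and sensitive to planted signal", {
  ## null: fraction p < 0.05 near nominal, no BH discoveries expected
  null <- simulateDegCounts(DegSimSpec(nFeatures = 1500,
                                       nPerGroup = c(20, 20),
                                       dispersion = 0.1, seed = 29))
  rn <- runDeAnalysis(null$counts, null$condition)
  expect_gt(mean(rn$p < 0.05, na.rm = TRUE), 0.03)
  expect_lt(mean(rn$p < 0.05, na.rm = TRUE), 0.07)

  ## planted signal at moderate depth is recovered
  planted <- stats::setNames(c(rep(2, 30), rep(-2, 30)),
                             sprintf("f%05d", 1:60))
  sig <- simulateDegCounts(DegSimSpec(
    nFeatures = 1000, nPerGroup = c(30, 30),
    baselineMeans = exp(runif(1000, log(50), log(500))),
    dispersion = 0.1, plantedLog2Fc = planted, seed = 30))
  rs <- runDeAnalysis(sig$counts, sig$condition)
  calledDir <- as.character(rs$direction[1:60])
  expect_gte(mean(calledDir == ifelse(sig$truth$planted_log2fc > 0,
                                      "UP", "DN")), 0.9)
})

test_that("size factors agree with the reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(31)
  m <- mkCounts(matrix(rpois(200 * 6, 150) + 1L, 200, 6), 200, 6)
  mine <- estimateSizeFactors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ## the reference takes the median of log ratios, which differs from the
  ## linear-scale median only when the usable feature count is even
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-3)
})
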