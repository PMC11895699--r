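## Small deterministic annotation builder.
mkAnnotation <- function(chrom, pos, direction, biotype,
                         chromLengths) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(pos, pos + 999),
                               seqlengths = chromLengths)
  gr$gene_id <- sprintf("g%04d", seq_along(gr))
  gr$biotype <- biotype
  gr$direction <- direction
  gr
}

test_that("chromosome summaries count and conserve categories", {
  cl <- c(chr1 = 1e8, chr2 = 5e7)
  ann <- mkAnnotation(c(rep("chr1", 50), rep("chr2", 10)),
                      c(seq(1e6, 99e6, length.out = 50),
                        seq(1e6, 45e6, length.out = 10)),
                      c(rep("UP", 5), rep("DN", 10), rep("NS", 35),
                        rep("NS", 10)),
                      rep("protein_coding", 60), cl)
  cs <- chromosomeSummary(ann)
  c1 <- cs[cs$chrom == "chr1", ]
  expect_equal(c1$n_genes, 50)
  expect_equal(c1$density_genes, 0.5)  # 50 genes / 100 Mb
  expect_equal(c1$n_up, 5)
  c2 <- cs[cs$chrom == "chr2", ]
  expect_equal(c2$n_up, 0)
  expect_equal(c2$density_up, 0)      # absence of UP genes on a chromosome
  tot <- cs[cs$chrom == "genome", ]
  expect_equal(tot$n_genes, c1$n_genes + c2$n_genes)
  expect_equal(tot$n_dn, c1$n_dn + c2$n_dn)
})

test_that("window enrichment follows the density-ratio definition", {
  ## 100 Mb chromosome, 50 genes; put 20 in one 10-Mb window -> fe = 4
  cl <- c(chr1 = 1e8)
  pos <- c(seq(20e6 + 1e5, 30e6 - 1e5, length.out = 20),
           seq(40e6, 99e6, length.out = 30))
  ann <- mkAnnotation("chr1", pos, rep("NS", 50),
                      rep("protein_coding", 50), cl)
  w <- scanWindows(ann, windowBp = 1e7, stepBp = 1e7)
  win <- w[w$start == 20e6 + 1, ]
  expect_equal(win$n_genes, 20)
  expect_equal(win$fe_genes_vs_chrom, (20 / 1e7) / (50 / 1e8))

  ## whole-chromosome window: every defined fe is exactly 1
  w1 <- scanWindows(ann, windowBp = 1e8, stepBp = 1e8)
  expect_equal(nrow(w1), 1L)
  expect_equal(w1$fe_genes_vs_chrom, 1)
  expect_equal(w1$fe_coding_vs_chrom, 1)
  expect_true(is.na(w1$fe_up_vs_chrom))  # no UP genes: fe undefined

  ## tiling (step = window): window counts sum to chromosome counts
  expect_equal(sum(w$n_genes), 50)
})

test_that("a window wider than the chromosome collapses to one window", {
  cl <- c(chrS = 5e6)
  ann <- mkAnnotation("chrS", c(1e6, 3e6), rep("NS", 2),
                      rep("protein_coding", 2), cl)
  w <- scanWindows(ann, windowBp = 1e7, stepBp = 1e6)
  expect_equal(nrow(w), 1L)
  expect_equal(w$span, 5e6)
  expect_equal(w$fe_genes_vs_chrom, 1)
})

test_that("sliding windows assign genes by start coordinate", {
  cl <- c(chr1 = 3e7)
  ## gene starting at 15 Mb belongs to every window covering 15 Mb
  ann <- mkAnnotation("chr1", 15e6, "UP", "protein_coding", cl)
  w <- scanWindows(ann, windowBp = 1e7, stepBp = 1e6)
  covering <- w$start <= 15e6 & w$end >= 15e6
  expect_true(all(w$n_up[covering] == 1))
  expect_true(all(w$n_up[!covering] == 0))
})

test_that("cluster calling qualifies, merges and peaks windows", {
  cl <- c(chr1 = 2e8)
  ## 40 background UP spread out; 12 UP packed into 148-158 Mb
  bg <- seq(1e6, 1.4e8, length.out = 40)
  hot <- seq(148.2e6, 157.8e6, length.out = 12)
  ns <- seq(1e6, 1.99e8, length.out = 400)
  ann <- mkAnnotation("chr1", c(bg, hot, ns),
                      c(rep("UP", 52), rep("NS", 400)),
                      rep("protein_coding", 452), cl)
  w <- scanWindows(ann)
  cls <- callClusters(w, ann)
  expect_equal(nrow(cls), 1L)
  expect_lte(cls$start, 158e6)
  expect_gte(cls$end, 148e6)
  expect_gte(cls$peak_fe_chrom, 2)
  expect_equal(cls$n_up, 12)

  ## raising min_up above the cluster count silences the call
  expect_equal(nrow(callClusters(w, ann, minUp = 20)), 0L)

  ## two qualified windows sharing most of their span merge to one cluster
  expect_true(all(cls$n_windows >= 2))
})

test_that("uniform null genomes rarely produce cluster calls", {
  fp <- 0
  for (s in 1:25) {
    g <- simulateGenome(GenomeSimSpec(seed = 5000 + s))
    w <- scanWindows(g$annotation)
    if (nrow(callClusters(w, g$annotation)) > 0) fp <- fp + 1
  }
  expect_lte(fp, 3)
})

test_that("strong planted clusters are recovered at the planted location", {
  ci <- data.frame(chrom = "chr2", start = 50e6 + 1, end = 60e6)
  hits <- 0
  for (s in 1:20) {
    g <- simulateGenome(GenomeSimSpec(clusterIntervals = ci,
                                      clusterDensityFold = 20,
                                      seed = 6000 + s))
    w <- scanWindows(g$annotation)
    cls <- callClusters(w, g$annotation)
    ok <- nrow(cls) > 0 &&
      any(cls$chrom == "chr2" & cls$start <= 60e6 & cls$end >= 50e6)
    if (ok) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.9)
})

test_that("biotype fractions carry exact binomial intervals", {
  cl <- c(chr1 = 1e8)
  ann <- mkAnnotation("chr1", seq(1e6, 9.9e7, length.out = 40),
                      c(rep("UP", 10), rep("DN", 30)),
                      c(rep("lncRNA", 10), rep("protein_coding", 30)), cl)
  bf <- biotypeFractions(ann)
  up <- bf[bf$direction == "UP", ]
  expect_equal(up$fraction, 1)
  expect_equal(up$ci_upper, 1)
  dn <- bf[bf$direction == "DN", ]
  expect_equal(dn$fraction, 0)
  ## matches binom.test directly
  ref <- stats::binom.test(0, 30)$conf.int
  expect_equal(dn$ci_lower, ref[1])
  expect_equal(dn$ci_upper, ref[2])
})

test_that("planted lncRNA fractions are recovered inside their intervals", {
  g <- simulateGenome(GenomeSimSpec(nGenes = 10000, degFraction = 1,
                                    upShare = 0.5, seed = 71))
  bf <- biotypeFractions(g$annotation)
  expect_equal(bf$fraction[bf$direction == "UP"], 0.38, tolerance = 0.1)
  expect_equal(bf$fraction[bf$direction == "DN"], 0.04, tolerance = 0.25)
})

test_that("hypergeometric overlap matches exhaustive enumeration", {
  ## k = 0: upper tail from zero is 1
  r0 <- overlapEnrichment("q1", list(s = c("a", "b")),
                          c("q1", "a", "b", "c"))
  expect_equal(r0$p, 1)

  ## set = universe: overlap is the whole query, p = 1
  u <- paste0("g", 1:6)
  r1 <- overlapEnrichment(u[1:3], list(all = u), u)
  expect_equal(r1$overlap, 3)
  expect_equal(r1$p, 1)

  ## enumeration oracle over small universes
  set.seed(72)
  for (i in 1:10) {
    N <- sample(8:13, 1)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:6, 1)
    u <- paste0("g", seq_len(N))
    set <- u[seq_len(K)]
    q <- sample(u, n)
    res <- overlapEnrichment(q, list(s = set), u)
    k <- res$overlap
    expect_equal(res$p, hyperOracle(N, K, n, k), tolerance = 1e-12)
  }

  expect_error(overlapEnrichment(character(0), list(s = "a"), "a"), "query")
  expect_error(overlapEnrichment("x", list(s = "a"), "a"), "subset")
})

test_that("GMT gene sets parse and drive BH-ranked enrichment", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3",
               "setB\tdesc\tg4\tg5"), f)
  sets <- readGeneSets(f)
  expect_identical(names(sets), c("setA", "setB"))
  expect_identical(sets$setA, c("g1", "g2", "g3"))

  u <- paste0("g", 1:20)
  res <- overlapEnrichment(c("g1", "g2", "g3"), sets, u)
  expect_identical(res$set[1], "setA")
  expect_equal(res$q, adjustBH(res$p), tolerance = 1e-12)
  expect_equal(res$percent_overlap[res$set == "setA"], 100)
})
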