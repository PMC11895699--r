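## Independent oracles used to check package computations. These are
## deliberately naive (enumeration / brute force) and share no code with the
## implementation.

## Benjamini-Hochberg step-up by direct enumeration of the definition:
## q_(i) = min_{j >= i} p_(j) * m / j, capped at 1, in input order.
bhStepUpOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(ps[i:m] * m / seq(i, m))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

## Exact two-sided Mann-Whitney p by enumerating all C(nx+ny, nx) group
## assignments of the pooled values (no ties assumed).
mannWhitneyOracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  splits <- utils::combn(nx + ny, nx)
  us <- apply(splits, 2, function(idx) sum(rk[idx]) - nx * (nx + 1) / 2)
  uObs <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  if (uObs > nx * ny / 2) {
    p <- 2 * mean(us >= uObs)
  } else {
    p <- 2 * mean(us <= uObs)
  }
  min(1, p)
}

## Upper-tail hypergeometric P(X >= k) by enumerating all C(N, n) draws.
hyperOracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  inSet <- draws <= K  # wlog the set is elements 1..K
  overlaps <- colSums(inSet)
  mean(overlaps >= k)
}

## Two-group Poisson Wald test (the phi -> 0 limit), coded independently.
poissonWaldOracle <- function(counts, groups, sf) {
  y <- sweep(counts, 2, sf, "/")
  g2 <- groups == levels(groups)[2]
  p <- numeric(nrow(counts))
  for (f in seq_len(nrow(counts))) {
    m1 <- mean(y[f, !g2]); m2 <- mean(y[f, g2])
    v1 <- m1 * sum(1 / sf[!g2]) / sum(!g2)^2
    v2 <- m2 * sum(1 / sf[g2]) / sum(g2)^2
    lfc <- log2(m2 / m1)
    se <- sqrt(v1 / m1^2 + v2 / m2^2) / log(2)
    p[f] <- 2 * stats::pnorm(-abs(lfc / se))
  }
  p
}

## Median-of-ratios size factors computed literally from the definition.
sizeFactorOracle <- function(counts) {
  geo <- apply(counts, 1, function(r) exp(mean(log(r))))
  use <- apply(counts, 1, function(r) all(r > 0))
  sf <- apply(counts, 2, function(col)
    stats::median(col[use] / geo[use]))
  sf / exp(mean(log(sf)))
}

## Exhaustive single-breakpoint scan (least-squares criterion).
breakpointOracle <- function(v, minSeg = 3L) {
  n <- length(v)
  best <- NA; bestSS <- -Inf
  for (b in minSeg:(n - minSeg)) {
    m1 <- mean(v[1:b]); m2 <- mean(v[(b + 1):n])
    ss <- b * (n - b) / n * (m2 - m1)^2
    if (ss > bestSS) { bestSS <- ss; best <- b }
  }
  best
}

## Tiny deterministic exon model used by several tests.
toyExonModel <- function() ExonModel("toy", 1:4, c(100, 100, 100, 100))

## Build an ExonProfileSet directly from a TPM-like matrix by passing
## integer counts proportional to tpm * length.
profileFromCounts <- function(counts, model) {
  computeExonTpm(counts, model)
}
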