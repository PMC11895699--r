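## Internal argument checks shared across modules.

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf,
                                finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name),
         call. = FALSE)
  if (finite && !is.finite(x))
    stop(sprintf("'%s' must be finite", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

.assertCountMatrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids in count table", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in count table", call. = FALSE)
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-missing", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers", call. = FALSE)
  invisible(counts)
}

## Seed the RNG only when the caller supplied a seed; generators are then
## pure functions of (spec, seed).
.maybeSetSeed <- function(seed) {
  if (!is.na(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

## Negative-binomial sampler on the (mu, dispersion) scale with
## variance mu + phi * mu^2; phi = 0 degenerates to Poisson.
.rnbinomMu <- function(n, mu, phi) {
  if (phi <= 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

## Log-normal per-sample scaling factors with mean 1 and the requested
## coefficient of variation.
.rlibraryScale <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

.stageLevels <- c("0", "I", "II", "III", "IV", "NA")
.biotypeLevels <- c("protein_coding", "lncRNA", "other")
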