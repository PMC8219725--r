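# Internal helpers shared across the package.

# Evaluate `code` under a fixed RNG seed and restore the caller's RNG state,
# so that seeded internals never perturb user-level random streams.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Pairwise Euclidean distances between rows of a and rows of b,
# returned as an |a| x |b| dense matrix.
cross_dist <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Cosine distance (1 - cosine similarity) between rows.
cross_dist_cosine <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  na <- sqrt(rowSums(a^2))
  nb <- sqrt(rowSums(b^2))
  na[na == 0] <- 1
  nb[nb == 0] <- 1
  1 - tcrossprod(a / na, b / nb)
}

row_softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
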