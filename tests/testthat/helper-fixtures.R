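# Shared fixture builders and brute-force oracles, independent of the
# package's own code paths.

# Tiny labeled expression matrix with planted class-specific means.
toy_reference <- function(n_genes = 20, n_classes = 3, cells_per_class = 5,
                          seed = 42) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    n <- n_classes * cells_per_class
    cls <- rep(paste0("c", seq_len(n_classes)), each = cells_per_class)
    X <- matrix(rpois(n_genes * n, 5), n_genes, n)
    # plant per-class shifts on the first genes
    for (k in seq_len(min(n_classes, n_genes))) {
      X[k, cls == paste0("c", k)] <- X[k, cls == paste0("c", k)] + 10L
    }
    dimnames(X) <- list(sprintf("g%02d", seq_len(n_genes)),
                        sprintf("cell%02d", seq_len(n)))
    list(mat = expression_matrix(X, "reference"),
         labels = cell_labels(setNames(cls, colnames(X))))
  })
}

# O(n^2) brute-force mutual nearest neighbors.
brute_mnn <- function(a, b, k, exclude_self = FALSE) {
  D <- as.matrix(dist(rbind(a, b)))[seq_len(nrow(a)),
                                    nrow(a) + seq_len(nrow(b)), drop = FALSE]
  if (exclude_self) diag(D) <- Inf
  edges <- NULL
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      rank_i_for_j <- rank(D[, j], ties.method = "first")[i]
      rank_j_for_i <- rank(D[i, ], ties.method = "first")[j]
      if (rank_i_for_j <= k && rank_j_for_i <= k) edges <- rbind(edges, c(i, j))
    }
  }
  if (is.null(edges)) matrix(integer(0), 0, 2) else edges
}

# Brute-force per-cell silhouette widths.
brute_silhouette <- function(coords, labels) {
  labels <- as.character(labels)
  D <- as.matrix(dist(coords))
  n <- nrow(coords)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

# Brute-force entropy/enrichment of one cluster (natural log, 0 log 0 = 0).
brute_profile <- function(m, n_c) {
  S <- (m / sum(m)) / (n_c / sum(n_c))
  p <- S / sum(S)
  p <- p[p > 0]
  list(H = -sum(p * log(p)), ES = max(S) / sum(S))
}
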