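#' Label-transfer accuracy
#'
#' Fraction of query cells whose predicted label exactly matches the truth;
#' `"unassigned"` and `"unknown"` predictions count as incorrect against a
#' true known class. Also returns per-class accuracy (the diagonal of the
#' row-normalized confusion matrix) and the raw confusion counts.
#'
#' @param predicted character vector of predicted labels, named by cell id
#'   (or a `prediction_result`).
#' @param truth character/factor vector of true labels named by cell id.
#' @return object of class `metric_report`: list with `accuracy`,
#'   `per_class_accuracy` and `confusion` (true classes in rows).
#' @export
accuracy_score <- function(predicted, truth) {
  if (inherits(predicted, "prediction_result")) {
    predicted <- stats::setNames(predicted$assigned, predicted$cell_id)
  }
  if (is.null(names(predicted)) || is.null(names(truth))) {
    stop("predicted and truth must be named by cell id")
  }
  common <- intersect(names(predicted), names(truth))
  if (length(common) == 0L) stop("predicted and truth share no cell ids")
  p <- as.character(predicted[common])
  t <- as.character(truth[common])
  lev_t <- sort(unique(t))
  lev_p <- sort(unique(c(p, lev_t)))
  confusion <- table(factor(t, levels = lev_t), factor(p, levels = lev_p))
  correct <- p == t
  per_class <- vapply(lev_t, function(cl) mean(correct[t == cl]), numeric(1))
  structure(list(accuracy = mean(correct),
                 per_class_accuracy = per_class,
                 confusion = confusion),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> accuracy = %.4f over %d cells\n",
              x$accuracy, sum(x$confusion)))
  invisible(x)
}

#' Batch-mixing entropy of an embedding
#'
#' Measures how well cells from different batches (datasets) intermingle in an
#' embedding. For each of `n_regions` randomly sampled cells, the batch
#' composition of the region formed by its `n_neighbors` Euclidean-nearest
#' cells (the sampled cell included) is summarized by the natural-log entropy
#' -sum_b p_b log p_b; the vector of region entropies is returned
#' (boxplot-ready). Values lie in [0, log B] for B batches: log 2 for two
#' perfectly interleaved batches, 0 for fully separated ones.
#'
#' @param embedding cells x d coordinate matrix (e.g. [extract_embedding()]).
#' @param batch_tags batch/dataset label per cell.
#' @param n_regions number of sampled neighborhoods (default 100).
#' @param n_neighbors neighborhood size (default 100; clamped with a warning
#'   when the data are smaller).
#' @param seed RNG seed for region sampling.
#' @return numeric vector of length `n_regions`.
#' @export
batch_mixing_entropy <- function(embedding, batch_tags, n_regions = 100L,
                                 n_neighbors = 100L, seed = 0L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  batch_tags <- factor(as.character(batch_tags))
  if (nlevels(batch_tags) < 2L) stop("need at least 2 batches")
  if (n_neighbors > n) {
    warning(sprintf("n_neighbors = %d clamped to %d", n_neighbors, n))
    n_neighbors <- n
  }
  centers <- with_seed(seed, sample(n, n_regions, replace = n_regions > n))
  D <- cross_dist(embedding[centers, , drop = FALSE], embedding)
  vapply(seq_along(centers), function(i) {
    d <- D[i, ]
    d[centers[i]] <- -Inf                     # the region includes its center
    nb <- order(d)[seq_len(n_neighbors)]
    p <- as.numeric(table(batch_tags[nb])) / n_neighbors
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
}

#' Per-cell silhouette widths
#'
#' Standard silhouette width s(i) = (b(i) - a(i)) / max(a(i), b(i)) with
#' Euclidean distance, computed on an embedding grouped by cell type.
#' Singleton-class cells (and the a = b = 0 degenerate case of coincident
#' points) get s = 0.
#'
#' @param embedding cells x d coordinate matrix.
#' @param cell_type_labels type label per cell; at least two types required.
#' @return numeric vector of silhouette widths in [-1, 1].
#' @export
silhouette_coefficient <- function(embedding, cell_type_labels) {
  f <- factor(as.character(cell_type_labels))
  if (nlevels(f) < 2L) stop("silhouette needs at least 2 cell types")
  sil <- cluster::silhouette(as.integer(f), stats::dist(as.matrix(embedding)))
  s <- if (is.matrix(sil)) sil[, "sil_width"] else rep(0, length(f))
  s[!is.finite(s)] <- 0
  unname(s)
}
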