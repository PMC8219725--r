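#' Mutual nearest neighbors between two point sets
#'
#' A pair (i, j) is an edge iff point i of `coords_a` is among the
#' `n_neighbors` nearest points of j (searching in `coords_a`) and j is among
#' the `n_neighbors` nearest of i (searching in `coords_b`). Neighbor ranks
#' use a deterministic first-index tie break, so the edge set is invariant to
#' the order cells are presented.
#'
#' @param coords_a,coords_b numeric matrices of points (rows) in the same
#'   embedding space.
#' @param n_neighbors neighborhood size; values at or above a set size are
#'   clamped with a warning.
#' @param metric `"euclidean"` (default) or `"cosine"`.
#' @param exclude_self when the two sets are the same set of points, exclude
#'   the i = j pairing (used for intra-dataset graphs).
#' @return integer matrix with columns `a` and `b` (one edge per row).
#' @export
mutual_nearest_neighbors <- function(coords_a, coords_b, n_neighbors = 5L,
                                     metric = c("euclidean", "cosine"),
                                     exclude_self = FALSE) {
  metric <- match.arg(metric)
  stopifnot(n_neighbors >= 1L)
  na <- nrow(coords_a)
  nb <- nrow(coords_b)
  cap <- min(na, nb) - if (exclude_self) 1L else 0L
  if (n_neighbors > cap) {
    warning(sprintf("n_neighbors = %d clamped to %d", n_neighbors, cap))
    n_neighbors <- cap
  }
  D <- if (metric == "euclidean") cross_dist(coords_a, coords_b)
       else cross_dist_cosine(coords_a, coords_b)
  if (exclude_self) diag(D) <- Inf
  # rank of each a-point among the neighbors of each b-point, and vice versa
  rank_a_for_b <- apply(D, 2L, rank, ties.method = "first")
  rank_b_for_a <- t(apply(D, 1L, rank, ties.method = "first"))
  hits <- (rank_a_for_b <= n_neighbors) & (rank_b_for_a <= n_neighbors)
  idx <- which(hits, arr.ind = TRUE)
  edges <- cbind(a = as.integer(idx[, 1L]), b = as.integer(idx[, 2L]))
  edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
}

#' Inter-dataset (reference-to-query) graph
#'
#' Mutual nearest neighbors between the canonical reference and query
#' coordinates; an edge anchors a query cell to a reference cell.
#'
#' @param proj a [cca_project()] result.
#' @param n_neighbors MNN neighborhood size (default 5).
#' @param metric distance metric, see [mutual_nearest_neighbors()].
#' @return integer matrix with columns `ref` and `query`.
#' @export
build_inter_graph <- function(proj, n_neighbors = 5L,
                              metric = c("euclidean", "cosine")) {
  edges <- mutual_nearest_neighbors(proj$ref_coords, proj$query_coords,
                                    n_neighbors, metric)
  colnames(edges) <- c("ref", "query")
  n_q <- nrow(proj$query_coords)
  lonely <- n_q - length(unique(edges[, "query"]))
  if (lonely > 0L) {
    message(sprintf("%d of %d query cells have no inter-dataset edge",
                    lonely, n_q))
  }
  edges
}

#' Intra-query graph
#'
#' Mutual kNN among query cells in a k-dimensional projection. By default the
#' query-side canonical coordinates from [cca_project()] are reused (pass
#' `coords = proj$query_coords`); alternatively the standardized query matrix
#' alone is projected onto its top-k right singular vectors.
#'
#' @param coords optional precomputed query coordinates (cells x k).
#' @param query_std standardized query matrix (features x cells), used when
#'   `coords` is `NULL`.
#' @param k projection dimension for the SVD fallback (default 20; clamped
#'   with a warning when the query is smaller).
#' @param n_neighbors mutual-kNN neighborhood size (default 5).
#' @param metric distance metric.
#' @return integer matrix with columns `from` < `to` (undirected edges).
#' @export
build_intra_graph <- function(coords = NULL, query_std = NULL, k = 20L,
                              n_neighbors = 5L,
                              metric = c("euclidean", "cosine")) {
  if (is.null(coords)) {
    if (is.null(query_std)) stop("supply coords or query_std")
    n_q <- ncol(query_std)
    if (n_q < 2L) stop("query needs at least 2 cells")
    kk <- min(k, nrow(query_std), n_q)
    if (kk < k) warning(sprintf("k = %d clamped to %d for the query SVD", k, kk))
    sv <- svd(as.matrix(query_std), nu = 0L, nv = kk)
    coords <- sv$v
    rownames(coords) <- colnames(query_std)
  }
  edges <- mutual_nearest_neighbors(coords, coords, n_neighbors,
                                    metric, exclude_self = TRUE)
  edges <- edges[edges[, 1L] < edges[, 2L], , drop = FALSE]
  colnames(edges) <- c("from", "to")
  edges
}

#' Assemble the hybrid adjacency matrix
#'
#' Builds the symmetric binary adjacency over n_ref + n_query nodes with block
#' structure `[0, A_RQ; t(A_RQ), A_QQ]`: reference cells connect only to query
#' cells (inter edges) and query cells additionally to each other (intra
#' edges). The reference-reference block is identically zero and the diagonal
#' is zero.
#'
#' @param edges_inter integer matrix, columns (ref, query) indices.
#' @param edges_intra integer matrix, columns (from, to) query indices.
#' @param n_ref,n_query node counts.
#' @return object of class `hybrid_graph`: list with `n_ref`, `n_query`,
#'   `edges_inter`, `edges_intra` and the sparse `adjacency`.
#' @export
assemble_hybrid <- function(edges_inter, edges_intra, n_ref, n_query) {
  edges_inter <- matrix(as.integer(edges_inter), ncol = 2L,
                        dimnames = list(NULL, c("ref", "query")))
  edges_intra <- matrix(as.integer(edges_intra), ncol = 2L,
                        dimnames = list(NULL, c("from", "to")))
  n <- n_ref + n_query
  if (nrow(edges_inter) && (any(edges_inter[, 1L] < 1L | edges_inter[, 1L] > n_ref) ||
                            any(edges_inter[, 2L] < 1L | edges_inter[, 2L] > n_query))) {
    stop("inter edge index out of range")
  }
  if (nrow(edges_intra) && any(edges_intra < 1L | edges_intra > n_query)) {
    stop("intra edge index out of range")
  }
  if (nrow(edges_intra) && any(edges_intra[, 1L] == edges_intra[, 2L])) {
    stop("intra self-loops are not allowed")
  }
  i <- c(edges_inter[, 1L], n_ref + edges_intra[, 1L])
  j <- c(n_ref + edges_inter[, 2L], n_ref + edges_intra[, 2L])
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                            dims = c(n, n), use.last.ij = FALSE)
  A@x <- pmin(A@x, 1)                      # duplicates collapse to binary
  A <- Matrix::drop0(A)
  structure(list(n_ref = n_ref, n_query = n_query,
                 edges_inter = edges_inter, edges_intra = edges_intra,
                 adjacency = A),
            class = "hybrid_graph")
}

#' @export
print.hybrid_graph <- function(x, ...) {
  cat(sprintf("<hybrid_graph> %d ref + %d query nodes; %d inter / %d intra edges\n",
              x$n_ref, x$n_query, nrow(x$edges_inter), nrow(x$edges_intra)))
  invisible(x)
}

#' Renormalized adjacency for graph convolution
#'
#' Computes `D^{-1/2} (A + I) D^{-1/2}` where D is the degree matrix of
#' A + I (self-loops guarantee positive degrees). The result is symmetric,
#' entries lie in [0, 1], and its eigenvalues lie in [-1, 1]; isolated nodes
#' map to a diagonal entry of 1.
#'
#' @param graph a [assemble_hybrid()] result, or any symmetric binary
#'   adjacency matrix (dense or sparse) with zero diagonal.
#' @return sparse symmetric matrix (`Matrix` class) of the same size.
#' @export
normalize_adjacency <- function(graph) {
  A <- if (inherits(graph, "hybrid_graph")) graph$adjacency else methods::as(Matrix::Matrix(graph, sparse = TRUE), "generalMatrix")
  n <- nrow(A)
  Ahat <- A + Matrix::Diagonal(n)
  d <- Matrix::rowSums(Ahat)
  Dm <- Matrix::Diagonal(n, x = 1 / sqrt(d))
  Dm %*% Ahat %*% Dm
}
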