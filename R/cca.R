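#' Canonical correlation projection of reference and query cells
#'
#' Projects both datasets into a shared k-dimensional space by singular value
#' decomposition of the cells x cells cross-product of the standardized
#' matrices, K = t(X_ref) %*% X_query. The i-th pair of canonical vectors
#' (mu_i over reference cells, nu_i over query cells) are the i-th left/right
#' singular vectors and maximize t(mu) K nu under unit-norm constraints; the
#' components of mu_i and nu_i serve directly as the cells' coordinates in
#' dimension i. Sign convention: the entry of largest magnitude in each mu_i
#' is positive.
#'
#' @param ref_std,query_std standardized matrices sharing the same feature
#'   rows (see [standardize_pair()]).
#' @param k number of canonical dimensions (default 20).
#' @param clamp if `TRUE`, an infeasible `k` is reduced to the achievable
#'   rank with a warning instead of an error.
#' @return object of class `cca_projection`: list with `ref_coords`
#'   (n_ref x k), `query_coords` (n_query x k), `singular_values`
#'   (nonincreasing) and `k`.
#' @export
cca_project <- function(ref_std, query_std, k = 20L, clamp = FALSE) {
  if (nrow(ref_std) != nrow(query_std)) {
    stop("reference and query must share the same feature rows")
  }
  n_r <- ncol(ref_std)
  n_q <- ncol(query_std)
  kmax <- min(nrow(ref_std), n_r, n_q)
  if (k > kmax) {
    if (clamp) {
      warning(sprintf("k = %d reduced to %d (min of m, n_ref, n_query)", k, kmax))
      k <- kmax
    } else {
      stop(sprintf("k = %d exceeds achievable dimension %d", k, kmax))
    }
  }
  K <- crossprod(as.matrix(ref_std), as.matrix(query_std))  # n_r x n_q
  sv <- svd(K)
  rank <- sum(sv$d > max(dim(K)) * .Machine$double.eps * max(sv$d, 1))
  if (k > rank) {
    if (clamp) {
      warning(sprintf("k = %d reduced to rank %d of the cross-product", k, rank))
      k <- rank
    } else {
      stop(sprintf("k = %d exceeds the cross-product rank; achievable k = %d",
                   k, rank))
    }
  }
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  for (i in seq_len(k)) {
    j <- which.max(abs(u[, i]))
    if (u[j, i] < 0) {
      u[, i] <- -u[, i]
      v[, i] <- -v[, i]
    }
  }
  rownames(u) <- colnames(ref_std)
  rownames(v) <- colnames(query_std)
  structure(list(ref_coords = u, query_coords = v,
                 singular_values = sv$d[seq_len(k)], k = k),
            class = "cca_projection")
}

#' @export
print.cca_projection <- function(x, ...) {
  cat(sprintf("<cca_projection> k = %d over %d reference + %d query cells\n",
              x$k, nrow(x$ref_coords), nrow(x$query_coords)))
  invisible(x)
}
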