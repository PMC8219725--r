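#' Select class-informative features by one-way ANOVA
#'
#' For every gene of the labeled reference, a one-way analysis of variance
#' F-statistic across the cell-type classes is computed; p-values are
#' Bonferroni-adjusted over the number of tested genes, and genes with
#' adjusted p < 0.05 are ranked by ascending adjusted p (ties broken by
#' descending F, then lexicographic feature id) and truncated to
#' `max_features`.
#'
#' The F-statistics come from the standard sum-of-squares decomposition,
#' vectorized over genes; genes constant within and across classes have an
#' undefined F and are assigned p = 1, so they are never selected.
#'
#' @param reference reference [expression_matrix()].
#' @param labels [cell_labels()] covering the reference cells.
#' @param max_features cap on the number of selected genes (default 2000).
#' @param log1p if `TRUE`, ANOVA runs on `log1p`-transformed values; values
#'   are otherwise used as provided.
#' @return An object of class `feature_selection`: list with
#'   `selected_features`, `statistic` (named per-gene F) and `adjusted_p`.
#' @export
select_variable_features <- function(reference, labels, max_features = 2000L,
                                     log1p = FALSE) {
  stopifnot(max_features >= 1L)
  reference <- as_expression_matrix(reference, "reference")
  cells <- colnames(reference)
  if (!all(cells %in% names(labels))) {
    stop("every reference cell must be labeled")
  }
  f <- factor(as.character(labels[cells]))
  sizes <- table(f)
  if (any(sizes < 2L)) {
    stop("class(es) with fewer than 2 cells: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  X <- unclass(reference)
  if (log1p) X <- log1p(X)
  n <- ncol(X)
  k <- nlevels(f)
  ind <- stats::model.matrix(~ f - 1)               # n x k indicator
  gsum <- X %*% ind                                 # genes x k group sums
  gmean <- sweep(gsum, 2L, as.numeric(sizes), "/")
  grand <- rowMeans(X)
  ssb <- rowSums(sweep((gmean - grand)^2, 2L, as.numeric(sizes), "*"))
  sst <- rowSums((X - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  df1 <- k - 1L
  df2 <- n - k
  fstat <- (ssb / df1) / (ssw / df2)
  # degenerate genes: no variation at all -> F undefined, excluded via p = 1
  const <- sst < 1e-12
  fstat[const] <- NA_real_
  pure <- !const & ssw < 1e-12 * pmax(sst, 1)       # perfect separation
  fstat[pure] <- Inf
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  p[pure] <- 0
  p[const] <- 1
  adj <- stats::p.adjust(p, method = "bonferroni")
  names(fstat) <- names(adj) <- rownames(X)

  sig <- which(adj < 0.05)
  ford <- ifelse(is.na(fstat), -Inf, fstat)
  ord <- sig[order(adj[sig], -ford[sig], rownames(X)[sig])]
  if (length(ord) < max_features) {
    warning(sprintf("only %d of the requested %d features pass adjusted p < 0.05",
                    length(ord), max_features))
  }
  sel <- rownames(X)[utils::head(ord, max_features)]
  structure(list(selected_features = sel, statistic = fstat, adjusted_p = adj),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection> %d features selected of %d tested\n",
              length(x$selected_features), length(x$statistic)))
  invisible(x)
}

#' Standardize expression rows to mean 0, sd 1
#'
#' Each retained gene row i is transformed to (x_ij - mean_i) / sd_i, the
#' standardization applied to both datasets before canonical correlation.
#' Rows with zero standard deviation are dropped with a warning (the caller
#' must re-synchronize the partner dataset; see [standardize_pair()]).
#'
#' @param matrix an [expression_matrix()] (or numeric matrix with dimnames).
#' @param features optional [select_variable_features()] result (or character
#'   vector) restricting the rows first.
#' @param sd_type `"population"` (divide by n; default) or `"sample"`
#'   (divide by n-1).
#' @return numeric matrix of standardized values; the `dropped` attribute
#'   lists zero-variance feature ids removed.
#' @export
standardize <- function(matrix, features = NULL,
                        sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  X <- if (inherits(matrix, "expression_matrix")) unclass(matrix) else as.matrix(matrix)
  if (!is.null(features)) {
    ids <- if (inherits(features, "feature_selection")) features$selected_features else features
    missing <- setdiff(ids, rownames(X))
    if (length(missing)) stop("features absent from matrix: ",
                              paste(utils::head(missing, 3L), collapse = ","))
    X <- X[ids, , drop = FALSE]
  }
  n <- ncol(X)
  mu <- rowMeans(X)
  cent <- X - mu
  denom <- if (sd_type == "population") n else n - 1L
  sds <- sqrt(rowSums(cent^2) / denom)
  zero <- sds == 0
  if (any(zero)) {
    warning(sprintf("dropping %d zero-variance feature(s): %s", sum(zero),
                    paste(utils::head(rownames(X)[zero], 5L), collapse = ",")))
  }
  out <- cent[!zero, , drop = FALSE] / sds[!zero]
  attr(out, "dropped") <- rownames(X)[zero]
  out
}

#' Standardize a reference/query pair on a common feature set
#'
#' Standardizes each dataset independently (its own row means and sds), then
#' drops from both any feature with zero variance in either, keeping the two
#' outputs row-aligned.
#'
#' @inheritParams standardize
#' @param reference,query row-aligned expression matrices.
#' @return list with standardized `reference` and `query` matrices over the
#'   same feature rows.
#' @export
standardize_pair <- function(reference, query, features = NULL,
                             sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  r <- standardize(reference, features, sd_type)
  q <- standardize(query, features, sd_type)
  keep <- intersect(rownames(r), rownames(q))
  list(reference = r[keep, , drop = FALSE], query = q[keep, , drop = FALSE])
}
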