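#' Construct an expression matrix
#'
#' Wraps a genes x cells numeric matrix with validated row (feature) and
#' column (cell) identifiers and a dataset tag. Duplicate feature identifiers
#' are merged by element-wise maximum, the convention used when collapsing
#' redundant gene symbols in droplet and sci-protocol data.
#'
#' @param values numeric matrix (features in rows, cells in columns) with
#'   dimnames, or a sparse `Matrix`; coerced to a dense base matrix.
#' @param dataset_tag `"reference"` or `"query"`.
#' @return A numeric matrix of class `expression_matrix` with unique rownames
#'   (features), unique colnames (cells) and a `dataset_tag` attribute.
#' @export
expression_matrix <- function(values, dataset_tag = c("reference", "query")) {
  dataset_tag <- match.arg(dataset_tag)
  if (inherits(values, "Matrix")) values <- as.matrix(values)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs feature rownames and cell colnames")
  }
  if (!all(is.finite(values))) stop("expression values must all be finite")
  if (anyDuplicated(colnames(values))) stop("duplicate cell identifiers")
  if (anyDuplicated(rownames(values))) {
    values <- merge_duplicate_features(values)
  }
  structure(values,
            dataset_tag = dataset_tag,
            class = c("expression_matrix", "matrix", "array"))
}

# Collapse duplicated feature ids by element-wise maximum.
merge_duplicate_features <- function(values) {
  ids <- rownames(values)
  dup <- unique(ids[duplicated(ids)])
  keep <- !duplicated(ids)
  out <- values[keep, , drop = FALSE]
  for (g in dup) {
    rows <- values[ids == g, , drop = FALSE]
    out[g, ] <- apply(rows, 2L, max)
  }
  out
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d features x %d cells (%s)\n",
              nrow(x), ncol(x), attr(x, "dataset_tag") %||% "untagged"))
  invisible(x)
}

# Re-wrap a subset while keeping class/tag (base `[` drops attributes).
em_subset <- function(x, i = NULL, j = NULL) {
  tag <- attr(x, "dataset_tag") %||% "reference"
  y <- unclass(x)
  if (!is.null(i)) y <- y[i, , drop = FALSE]
  if (!is.null(j)) y <- y[, j, drop = FALSE]
  structure(y, dataset_tag = tag,
            class = c("expression_matrix", "matrix", "array"))
}

as_expression_matrix <- function(x, dataset_tag) {
  if (inherits(x, "expression_matrix")) return(x)
  expression_matrix(x, dataset_tag)
}

#' Construct per-cell labels
#'
#' @param labels character or factor vector of class labels, named by cell id
#'   (or `cells` supplies the ids).
#' @param cells optional character vector of cell ids, same length as `labels`.
#' @return A named factor of class `cell_labels`; levels are the ordered class
#'   names.
#' @export
cell_labels <- function(labels, cells = NULL) {
  if (!is.null(cells)) names(labels) <- cells
  if (is.null(names(labels))) stop("labels must be named by cell id")
  f <- factor(as.character(labels))
  if (nlevels(f) < 2L) stop("need at least two distinct classes")
  names(f) <- names(labels)
  class(f) <- c("cell_labels", "factor")
  f
}

#' Restrict two expression matrices to their shared features
#'
#' Both matrices are subset to the intersection of their feature identifiers,
#' in the order the shared features appear in the reference. Gene symbols are
#' matched case-sensitively by exact string.
#'
#' @param reference,query `expression_matrix` objects (or matrices with
#'   dimnames).
#' @return list with elements `reference` and `query`, row-aligned on the
#'   common features.
#' @export
align_features <- function(reference, query) {
  reference <- as_expression_matrix(reference, "reference")
  query <- as_expression_matrix(query, "query")
  common <- intersect(rownames(reference), rownames(query))
  if (length(common) == 0L) {
    stop(sprintf(paste0(
      "no shared features between reference (e.g. %s) and query (e.g. %s); ",
      "feature namespaces differ - for cross-species data map gene symbols ",
      "with a homolog table first"),
      paste(utils::head(rownames(reference), 3L), collapse = ","),
      paste(utils::head(rownames(query), 3L), collapse = ",")))
  }
  list(reference = em_subset(reference, common),
       query = em_subset(query, common))
}

#' Filter low-quality cells and rarely detected features
#'
#' Cells with fewer than `min_features_per_cell` nonzero features are removed
#' first; features nonzero in fewer than `min_cells_per_feature` of the
#' retained cells are removed second. The two passes run once each (no
#' iteration), and values are never modified.
#'
#' @param matrix an `expression_matrix`.
#' @param min_features_per_cell,min_cells_per_feature nonnegative integer
#'   thresholds; a value is "expressed" when strictly positive.
#' @return the filtered `expression_matrix`.
#' @export
qc_filter <- function(matrix, min_features_per_cell = 0L,
                      min_cells_per_feature = 0L) {
  matrix <- as_expression_matrix(matrix, attr(matrix, "dataset_tag") %||% "reference")
  stopifnot(min_features_per_cell >= 0, min_cells_per_feature >= 0)
  nz <- unclass(matrix) > 0
  keep_cells <- colSums(nz) >= min_features_per_cell
  if (!any(keep_cells)) {
    stop(sprintf("all %d cells removed by min_features_per_cell = %d",
                 ncol(matrix), min_features_per_cell))
  }
  nz <- nz[, keep_cells, drop = FALSE]
  keep_feats <- rowSums(nz) >= min_cells_per_feature
  em_subset(matrix, which(keep_feats), which(keep_cells))
}
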