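#' Read a 10x-style MTX triplet
#'
#' Reads `matrix.mtx` (Matrix Market coordinate format, genes in rows) together
#' with `features.tsv` (or `genes.tsv`; the second column is taken as the gene
#' symbol when present) and `barcodes.tsv`.
#'
#' @param dir directory containing the triplet, or `NULL` when the three file
#'   paths are given explicitly.
#' @param matrix_file,features_file,barcodes_file explicit paths overriding
#'   `dir`.
#' @param dataset_tag `"reference"` or `"query"`.
#' @return an [expression_matrix()].
#' @export
read_mtx_matrix <- function(dir = NULL, matrix_file = NULL,
                            features_file = NULL, barcodes_file = NULL,
                            dataset_tag = "reference") {
  pick <- function(explicit, candidates) {
    if (!is.null(explicit)) return(explicit)
    for (f in file.path(dir, candidates)) if (file.exists(f)) return(f)
    stop("cannot locate ", paste(candidates, collapse = "/"), " in ", dir)
  }
  matrix_file <- pick(matrix_file, "matrix.mtx")
  features_file <- pick(features_file, c("features.tsv", "genes.tsv"))
  barcodes_file <- pick(barcodes_file, "barcodes.tsv")

  m <- Matrix::readMM(matrix_file)
  feats <- utils::read.delim(features_file, header = FALSE,
                             stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(barcodes_file, header = FALSE,
                                stringsAsFactors = FALSE)[[1L]]
  symbols <- if (ncol(feats) >= 2L) feats[[2L]] else feats[[1L]]
  if (nrow(m) != length(symbols) || ncol(m) != length(barcodes)) {
    stop(sprintf("MTX dimensions %dx%d do not match %d features / %d barcodes",
                 nrow(m), ncol(m), length(symbols), length(barcodes)))
  }
  m <- as.matrix(m)
  dimnames(m) <- list(symbols, barcodes)
  expression_matrix(m, dataset_tag)
}

#' Read a dense CSV/TSV expression matrix
#'
#' Genes are rows; the header row carries cell identifiers and the first
#' column the gene symbols.
#'
#' @param path file path; the separator is inferred from the extension
#'   (`.csv` = comma, otherwise tab) unless `sep` is given.
#' @param sep optional field separator.
#' @param dataset_tag `"reference"` or `"query"`.
#' @return an [expression_matrix()].
#' @export
read_dense_matrix <- function(path, sep = NULL, dataset_tag = "reference") {
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          row.names = 1L, stringsAsFactors = FALSE)
  expression_matrix(as.matrix(df), dataset_tag)
}

#' Read per-cell labels from TSV
#'
#' Expects a header line `cell_id<TAB>label`.
#'
#' @param path file path.
#' @return a [cell_labels()] factor named by cell id.
#' @export
read_cell_labels <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("labels file needs two columns: cell_id, label")
  cell_labels(df[[2L]], cells = df[[1L]])
}

#' Write a hybrid graph as a TSV edge list
#'
#' Emits `node_a<TAB>node_b<TAB>edge_type` with node ids prefixed `R:`/`Q:`.
#'
#' @param graph a [assemble_hybrid()] result.
#' @param path output path; a `.gz` suffix gzip-compresses.
#' @param ref_cells,query_cells optional cell ids (defaults to indices).
#' @return `path`, invisibly.
#' @export
write_graph_edges <- function(graph, path, ref_cells = NULL, query_cells = NULL) {
  ref_cells <- ref_cells %||% as.character(seq_len(graph$n_ref))
  query_cells <- query_cells %||% as.character(seq_len(graph$n_query))
  inter <- graph$edges_inter
  intra <- graph$edges_intra
  df <- rbind(
    if (nrow(inter)) data.frame(node_a = paste0("R:", ref_cells[inter[, 1L]]),
                                node_b = paste0("Q:", query_cells[inter[, 2L]]),
                                edge_type = "inter"),
    if (nrow(intra)) data.frame(node_a = paste0("Q:", query_cells[intra[, 1L]]),
                                node_b = paste0("Q:", query_cells[intra[, 2L]]),
                                edge_type = "intra"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write query predictions as TSV
#'
#' Columns: `cell_id`, `assigned_label`, `confidence`, then one probability
#' column per class (`p_<class>`).
#'
#' @param result a `prediction_result` from [predict_labels()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(result, path) {
  probs <- result$probabilities
  df <- data.frame(cell_id = result$cell_id,
                   assigned_label = result$assigned,
                   confidence = result$confidence,
                   check.names = FALSE)
  pcols <- as.data.frame(probs)
  names(pcols) <- paste0("p_", colnames(probs))
  utils::write.table(cbind(df, pcols), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
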