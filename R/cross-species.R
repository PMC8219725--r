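#' Load a one-to-one homolog lookup table
#'
#' Reads a TSV with at least two columns (source gene, target gene) and keeps
#' only strictly one-to-one pairs: any row participating in a many-to-one or
#' one-to-many relation is dropped entirely, and the retained/dropped counts
#' are reported.
#'
#' @param path TSV path with header `source<TAB>target` (extra columns
#'   ignored), or a two-column data frame.
#' @return object of class `homolog_table`: data frame with columns `source`
#'   and `target`, injective in both directions.
#' @export
load_homolog_table <- function(path) {
  df <- if (is.data.frame(path)) path
        else utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("homolog table needs two columns (source, target)")
  df <- data.frame(source = as.character(df[[1L]]),
                   target = as.character(df[[2L]]),
                   stringsAsFactors = FALSE)
  df <- unique(df)
  keep <- !(df$source %in% df$source[duplicated(df$source)]) &
          !(df$target %in% df$target[duplicated(df$target)])
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(sprintf("dropped %d ambiguous homolog pair(s); %d one-to-one pair(s) kept",
                    dropped, sum(keep)))
  }
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("no one-to-one homolog pairs remain after filtering")
  rownames(df) <- NULL
  class(df) <- c("homolog_table", "data.frame")
  df
}

#' Map gene identifiers across species
#'
#' Renames features found in the homolog table to their target symbols and
#' drops features absent from the table. Matching is case-sensitive and
#' exact; injectivity of the table guarantees unique output identifiers.
#'
#' @param matrix an [expression_matrix()].
#' @param table a [load_homolog_table()] result.
#' @return the renamed, possibly row-reduced `expression_matrix`.
#' @export
map_genes <- function(matrix, table) {
  matrix <- as_expression_matrix(matrix, attr(matrix, "dataset_tag") %||% "query")
  hit <- rownames(matrix) %in% table$source
  if (!any(hit)) {
    stop(paste0("no features map through the homolog table; ",
                "is the table's species orientation reversed? ",
                "(swap source/target or invert_homolog_table())"))
  }
  out <- em_subset(matrix, which(hit))
  idx <- match(rownames(out), table$source)
  rownames(out) <- table$target[idx]
  out
}

#' Invert a homolog table
#'
#' Swaps source and target columns; with a one-to-one table,
#' `map_genes(map_genes(x, table), invert_homolog_table(table))` restores the
#' original identifiers of all retained features.
#'
#' @param table a [load_homolog_table()] result.
#' @return the inverted `homolog_table`.
#' @export
invert_homolog_table <- function(table) {
  out <- data.frame(source = table$target, target = table$source,
                    stringsAsFactors = FALSE)
  class(out) <- c("homolog_table", "data.frame")
  out
}
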