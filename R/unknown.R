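#' Cluster query cells by modularity maximization
#'
#' Runs community detection (Louvain by default, Leiden optionally) on the
#' unweighted intra-query graph. Isolated cells form singleton clusters; an
#' empty graph yields all singletons with a warning. Deterministic given
#' `seed`.
#'
#' @param edges_intra integer matrix with columns (from, to) of query indices
#'   (see [build_intra_graph()]).
#' @param n_query number of query cells.
#' @param method `"louvain"` (default) or `"leiden"`.
#' @param seed RNG seed for the community detection heuristic.
#' @return integer vector of cluster ids, length `n_query`.
#' @export
cluster_query <- function(edges_intra, n_query, method = c("louvain", "leiden"),
                          seed = 0L) {
  method <- match.arg(method)
  edges_intra <- matrix(as.integer(edges_intra), ncol = 2L)
  if (nrow(edges_intra) == 0L) {
    warning("empty intra-query graph: every cell becomes a singleton cluster")
    return(seq_len(n_query))
  }
  g <- igraph::make_empty_graph(n = n_query, directed = FALSE)
  g <- igraph::add_edges(g, t(edges_intra))
  comm <- with_seed(seed, {
    if (method == "louvain") igraph::cluster_louvain(g)
    else igraph::cluster_leiden(g, objective_function = "modularity")
  })
  as.integer(igraph::membership(comm))
}

#' Entropy and enrichment profiles of query clusters
#'
#' For each query cluster h, counts m_ch = the number of cluster-h query cells
#' linked by the inter-dataset graph to reference cells of type c, forms the
#' abundance-normalized enrichment S_ch = (m_ch / sum_c m_ch) / (n_c /
#' sum_c n_c), and summarizes the profile by its information entropy
#' H_h = -sum_c p_c log p_c (natural log, p = S / sum S, 0 log 0 := 0) and the
#' enrichment score ES_h = max_c S_ch / sum_c S_ch. Clusters with no inter
#' edges are maximally ambiguous by convention: H = log C, ES = 1/C, and are
#' flagged `zero_links`.
#'
#' @param clusters integer cluster ids per query cell (see [cluster_query()]).
#' @param edges_inter integer matrix with columns (ref, query) (see
#'   [build_inter_graph()]).
#' @param ref_labels factor (or [cell_labels()]) of reference cell types, in
#'   reference node order.
#' @return object of class `cluster_profiles`: data frame with one row per
#'   cluster (`cluster`, `n_cells`, `entropy`, `enrichment`, `top_ref_type`,
#'   `zero_links`); the `S` attribute holds the clusters x types enrichment
#'   matrix and `n_types` the number of reference types C.
#' @export
enrichment_profile <- function(clusters, edges_inter, ref_labels) {
  f <- factor(as.character(ref_labels))
  C <- nlevels(f)
  if (C < 2L) stop("need at least 2 reference cell types")
  n_c <- as.numeric(table(f))
  edges_inter <- matrix(as.integer(edges_inter), ncol = 2L)
  # distinct (query cell, reference type) links
  links <- unique(cbind(q = edges_inter[, 2L],
                        t = as.integer(f)[edges_inter[, 1L]]))
  hs <- sort(unique(clusters))
  S <- matrix(0, length(hs), C, dimnames = list(hs, levels(f)))
  out <- data.frame(cluster = hs, n_cells = NA_integer_,
                    entropy = NA_real_, enrichment = NA_real_,
                    top_ref_type = NA_character_, zero_links = FALSE)
  for (i in seq_along(hs)) {
    cells <- which(clusters == hs[i])
    out$n_cells[i] <- length(cells)
    sub <- links[links[, 1L] %in% cells, , drop = FALSE]
    m <- tabulate(sub[, 2L], nbins = C)
    if (sum(m) == 0) {
      out$entropy[i] <- log(C)
      out$enrichment[i] <- 1 / C
      out$zero_links[i] <- TRUE
      out$top_ref_type[i] <- NA_character_
      next
    }
    s <- (m / sum(m)) / (n_c / sum(n_c))
    S[i, ] <- s
    p <- s / sum(s)
    nz <- p > 0
    out$entropy[i] <- -sum(p[nz] * log(p[nz]))
    out$enrichment[i] <- max(s) / sum(s)
    out$top_ref_type[i] <- levels(f)[which.max(s)]
  }
  structure(out, S = S, n_types = C,
            class = c("cluster_profiles", "data.frame"))
}

#' Flag query clusters as unknown cell types
#'
#' A cluster is flagged unknown when its link profile is both ambiguous
#' (entropy above the cutoff) and weakly enriched (enrichment below the
#' cutoff). The defaults, entropy > 0.5 * log(C) and enrichment < 2/C, place
#' pure clusters (H = 0, ES = 1) and link-free clusters (H = log C, ES = 1/C)
#' on opposite sides for any C >= 2.
#'
#' @param profiles a [enrichment_profile()] result.
#' @param entropy_cutoff flag requires entropy strictly above this (default
#'   `0.5 * log(C)`).
#' @param enrichment_cutoff flag requires enrichment strictly below this
#'   (default `2 / C`).
#' @return logical vector of flags, one per cluster row, named by cluster id.
#' @export
flag_unknown <- function(profiles, entropy_cutoff = NULL,
                         enrichment_cutoff = NULL) {
  C <- attr(profiles, "n_types")
  entropy_cutoff <- entropy_cutoff %||% (0.5 * log(C))
  enrichment_cutoff <- enrichment_cutoff %||% (2 / C)
  flags <- profiles$entropy > entropy_cutoff &
    profiles$enrichment < enrichment_cutoff
  names(flags) <- profiles$cluster
  flags
}
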