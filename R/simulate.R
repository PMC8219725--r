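#' Configuration for the synthetic reference/query generator
#'
#' Defaults describe a moderately noisy two-batch study: 4 cell types, 25
#' marker genes per type elevated by +2.0 log-mean units, 75 cells per type in
#' each dataset (300 + 300 cells), per-gene multiplicative batch shifts with
#' log-scale sd 0.5 applied to the query, lognormal overdispersion sd 0.3 on
#' top of Poisson sampling, and 20% dropout zero-inflation.
#'
#' @param n_genes total genes (default 500).
#' @param n_marker_genes_per_type genes elevated per type (default 25).
#' @param n_types number of shared cell types (default 4).
#' @param cells_per_type_ref,cells_per_type_query cells per type in each
#'   dataset (default 75 each).
#' @param batch_effect_sd sd of the per-gene log-scale batch shift applied to
#'   the query (default 0.5; 0 disables it).
#' @param dropout_rate Bernoulli zero-inflation probability in [0, 1)
#'   (default 0.2).
#' @param novel_type add one query-only cell type absent from the reference
#'   (default `FALSE`).
#' @param marker_elevation log-mean elevation of marker genes (default 2.0).
#' @param overdispersion_sd lognormal noise sd on the Poisson rate
#'   (default 0.3).
#' @param base_logmean_sd sd of per-gene baseline log-means (default 0.5).
#' @param seed RNG seed; generation is byte-reproducible given the config.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500L, n_marker_genes_per_type = 25L,
                       n_types = 4L, cells_per_type_ref = 75L,
                       cells_per_type_query = 75L, batch_effect_sd = 0.5,
                       dropout_rate = 0.2, novel_type = FALSE,
                       marker_elevation = 2.0, overdispersion_sd = 0.3,
                       base_logmean_sd = 0.5, seed = 0L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_marker_genes_per_type = as.integer(n_marker_genes_per_type),
              n_types = as.integer(n_types),
              cells_per_type_ref = as.integer(cells_per_type_ref),
              cells_per_type_query = as.integer(cells_per_type_query),
              batch_effect_sd = batch_effect_sd,
              dropout_rate = dropout_rate,
              novel_type = isTRUE(novel_type),
              marker_elevation = marker_elevation,
              overdispersion_sd = overdispersion_sd,
              base_logmean_sd = base_logmean_sd,
              seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1L, cfg$n_types >= 2L,
            cfg$n_marker_genes_per_type >= 1L,
            cfg$cells_per_type_ref >= 1L, cfg$cells_per_type_query >= 1L,
            cfg$dropout_rate >= 0, cfg$dropout_rate < 1,
            cfg$batch_effect_sd >= 0)
  n_blocks <- cfg$n_types + cfg$novel_type
  if (n_blocks * cfg$n_marker_genes_per_type > cfg$n_genes) {
    stop("n_genes too small for the requested marker blocks")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Sample a counts matrix for given per-cell types under a config.
sim_counts <- function(cfg, types, type_markers, mu0, batch_shift, prefix) {
  n_cells <- length(types)
  logmu <- matrix(mu0, cfg$n_genes, n_cells) + batch_shift
  for (t in unique(types)) {
    cols <- which(types == t)
    logmu[type_markers[[t]], cols] <- logmu[type_markers[[t]], cols] +
      cfg$marker_elevation
  }
  lam <- exp(logmu + matrix(stats::rnorm(cfg$n_genes * n_cells, 0,
                                         cfg$overdispersion_sd),
                            cfg$n_genes, n_cells))
  x <- matrix(stats::rpois(length(lam), lam), cfg$n_genes, n_cells)
  if (cfg$dropout_rate > 0) {
    x[matrix(stats::runif(length(x)) < cfg$dropout_rate,
             nrow(x), ncol(x))] <- 0
  }
  dimnames(x) <- list(sprintf("gene%04d", seq_len(cfg$n_genes)),
                      sprintf("%s_%04d", prefix, seq_len(n_cells)))
  x
}

#' Simulate a paired reference/query dataset with known ground truth
#'
#' Each cell type has a block of marker genes with elevated log-mean; counts
#' are lognormal-Poisson with Bernoulli dropout; the query receives per-gene
#' multiplicative batch shifts (additive on the log scale). When
#' `novel_type = TRUE` one extra type appears only in the query.
#'
#' @param config a [sim_config()].
#' @return list with `reference` and `query` ([expression_matrix()]),
#'   `ref_labels` ([cell_labels()]) and `query_truth` (named factor of the
#'   hidden query labels, including `"novel"` when simulated).
#' @export
simulate_pair <- function(config = sim_config()) {
  cfg <- config
  with_seed(cfg$seed, {
    mu0 <- stats::rnorm(cfg$n_genes, 0, cfg$base_logmean_sd)
    shared <- paste0("type", seq_len(cfg$n_types))
    all_types <- if (cfg$novel_type) c(shared, "novel") else shared
    type_markers <- stats::setNames(lapply(seq_along(all_types), function(i) {
      (i - 1L) * cfg$n_marker_genes_per_type + seq_len(cfg$n_marker_genes_per_type)
    }), all_types)

    ref_types <- rep(shared, each = cfg$cells_per_type_ref)
    query_types <- rep(all_types, each = cfg$cells_per_type_query)
    batch <- stats::rnorm(cfg$n_genes, 0, cfg$batch_effect_sd)

    ref <- sim_counts(cfg, ref_types, type_markers, mu0, 0, "ref")
    qry <- sim_counts(cfg, query_types, type_markers, mu0, batch, "query")

    list(reference = expression_matrix(ref, "reference"),
         query = expression_matrix(qry, "query"),
         ref_labels = cell_labels(stats::setNames(ref_types, colnames(ref))),
         query_truth = cell_labels(stats::setNames(query_types, colnames(qry))))
  })
}

#' Simulate a cross-species fixture with a homolog table
#'
#' Generates a [simulate_pair()] dataset, renames the reference genes into one
#' species namespace (`HS_*`) and the query genes into another (`MM_*`), and
#' returns a one-to-one homolog table covering `homolog_fraction` of the
#' genes, so the pipeline must map symbols before features can be aligned.
#'
#' @param config a [sim_config()].
#' @param homolog_fraction fraction of genes covered by the table, in (0, 1].
#' @return the [simulate_pair()] list plus `homolog_table` (query-to-reference
#'   orientation).
#' @export
simulate_cross_species_fixture <- function(config = sim_config(),
                                           homolog_fraction = 1) {
  stopifnot(homolog_fraction > 0, homolog_fraction <= 1)
  sim <- simulate_pair(config)
  genes <- rownames(sim$reference)
  hs <- paste0("HS_", toupper(genes))
  mm <- paste0("MM_", genes)
  rownames(sim$reference) <- hs
  rownames(sim$query) <- mm
  n_map <- floor(homolog_fraction * length(genes))
  mapped <- with_seed(config$seed + 1L, sort(sample(length(genes), n_map)))
  tab <- data.frame(source = mm[mapped], target = hs[mapped],
                    stringsAsFactors = FALSE)
  class(tab) <- c("homolog_table", "data.frame")
  sim$homolog_table <- tab
  sim
}
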