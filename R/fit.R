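#' Transfer cell-type labels from a reference to a query dataset
#'
#' End-to-end fit: (optional) homolog mapping, feature alignment, QC
#' filtering, ANOVA feature selection on the reference, per-gene
#' standardization, canonical correlation projection, mutual-nearest-neighbor
#' hybrid graph assembly and renormalization, semi-supervised GCN training on
#' the reference labels, probability thresholding into query assignments, and
#' an entropy/enrichment screen that relabels ambiguous query clusters as
#' `"unknown"`. When `query_truth` is supplied, accuracy, batch-mixing entropy
#' and silhouette metrics are computed on the result. Fully reproducible given
#' `seed`.
#'
#' @param reference,query genes x cells matrices (or [expression_matrix()]).
#' @param ref_labels [cell_labels()] (or named vector) for reference cells.
#' @param query_truth optional named vector of true query labels, for
#'   evaluation only.
#' @param homolog_table optional [load_homolog_table()] mapping query gene
#'   symbols into the reference namespace (set
#'   `homolog_direction = "reference"` to map the reference instead).
#' @param homolog_direction which dataset the homolog table is applied to.
#' @param max_features ANOVA feature cap (default 2000).
#' @param min_features_per_cell,min_cells_per_feature QC thresholds
#'   (default 0 = off).
#' @param log1p run feature selection on log1p values (default `FALSE`).
#' @param k canonical dimensions (default 20; clamped to the achievable rank
#'   with a warning on small data).
#' @param n_neighbors MNN neighborhood size for both inter- and intra-dataset
#'   graphs (default 5).
#' @param intra_mode `"cca"` reuses the query-side canonical coordinates for
#'   the intra-query graph (default); `"svd"` projects the standardized query
#'   alone.
#' @param hidden_dims hidden widths for [train_gcn()] (default 32; pass
#'   [paper_hidden_dims] for the full capacity sweep).
#' @param lr,max_epochs,patience,weight_decay,dropout training
#'   hyperparameters, see [train_gcn()].
#' @param threshold assignment probability threshold (default 0.5).
#' @param unknown_screen run the unknown-cell-type screen (default `TRUE`).
#' @param entropy_cutoff,enrichment_cutoff screen cutoffs, see
#'   [flag_unknown()].
#' @param sd_type standardization denominator, see [standardize()].
#' @param seed master RNG seed for the split, initialization, clustering and
#'   any sampling.
#' @param verbose per-epoch training output.
#' @return object of class `gcn_transfer`: list with `predictions`
#'   (data frame: cell_id, assigned, confidence), `probabilities`, `model`,
#'   `graph`, `A_norm`, `projection`, `features`, `joint`, `embedding`,
#'   `clusters`, `profiles`, `unknown_flags`, `metrics` (when truth given),
#'   `config`, `call`.
#' @examples
#' sim <- simulate_pair(sim_config(n_genes = 120, n_types = 3,
#'                                 cells_per_type_ref = 20,
#'                                 cells_per_type_query = 20, seed = 1))
#' fit <- gcn_transfer(sim$reference, sim$query, sim$ref_labels,
#'                     query_truth = sim$query_truth, k = 10,
#'                     max_epochs = 60, seed = 1)
#' fit$metrics$accuracy
#' @export
gcn_transfer <- function(reference, query, ref_labels, query_truth = NULL,
                         homolog_table = NULL,
                         homolog_direction = c("query", "reference"),
                         max_features = 2000L, min_features_per_cell = 0L,
                         min_cells_per_feature = 0L, log1p = FALSE,
                         k = 20L, n_neighbors = 5L,
                         intra_mode = c("cca", "svd"),
                         hidden_dims = 32L, lr = 0.01, max_epochs = 200L,
                         patience = 10L, weight_decay = 0, dropout = 0,
                         threshold = 0.5, unknown_screen = TRUE,
                         entropy_cutoff = NULL, enrichment_cutoff = NULL,
                         sd_type = c("population", "sample"),
                         seed = 0L, verbose = FALSE) {
  cl <- match.call()
  homolog_direction <- match.arg(homolog_direction)
  intra_mode <- match.arg(intra_mode)
  sd_type <- match.arg(sd_type)
  reference <- as_expression_matrix(reference, "reference")
  query <- as_expression_matrix(query, "query")
  if (!inherits(ref_labels, "cell_labels")) ref_labels <- cell_labels(ref_labels)

  if (!is.null(homolog_table)) {
    if (homolog_direction == "query") query <- map_genes(query, homolog_table)
    else reference <- map_genes(reference, homolog_table)
  }
  aligned <- align_features(reference, query)
  reference <- qc_filter(aligned$reference, min_features_per_cell,
                         min_cells_per_feature)
  query <- qc_filter(aligned$query, min_features_per_cell,
                     min_cells_per_feature)
  aligned <- align_features(reference, query)     # re-sync after gene QC
  reference <- aligned$reference
  query <- aligned$query
  keep_lab <- colnames(reference)
  if (!all(keep_lab %in% names(ref_labels))) stop("unlabeled reference cell(s)")

  features <- select_variable_features(reference, ref_labels,
                                       max_features = max_features,
                                       log1p = log1p)
  std <- standardize_pair(reference, query, features, sd_type)

  proj <- cca_project(std$reference, std$query, k = k, clamp = TRUE)
  edges_inter <- build_inter_graph(proj, n_neighbors = n_neighbors)
  intra_coords <- if (intra_mode == "cca") proj$query_coords else NULL
  edges_intra <- build_intra_graph(coords = intra_coords,
                                   query_std = std$query, k = k,
                                   n_neighbors = n_neighbors)
  graph <- assemble_hybrid(edges_inter, edges_intra,
                           n_ref = ncol(std$reference),
                           n_query = ncol(std$query))
  A_norm <- normalize_adjacency(graph)

  joint <- build_joint_input(std$reference, std$query, ref_labels, seed = seed)
  model <- train_gcn(joint, A_norm, hidden_dims = hidden_dims, lr = lr,
                     max_epochs = max_epochs, patience = patience,
                     weight_decay = weight_decay, dropout = dropout,
                     seed = seed, verbose = verbose)
  P <- gcn_forward(joint, A_norm, model)
  query_rows <- joint$n_ref + seq_len(joint$n_query)
  pred <- predict_labels(P[query_rows, , drop = FALSE], threshold = threshold)
  assigned <- pred$assigned

  clusters <- profiles <- unknown_flags <- NULL
  if (unknown_screen) {
    clusters <- cluster_query(edges_intra, joint$n_query, seed = seed)
    ref_lab_vec <- factor(as.character(ref_labels[colnames(std$reference)]))
    profiles <- enrichment_profile(clusters, edges_inter, ref_lab_vec)
    unknown_flags <- flag_unknown(profiles, entropy_cutoff, enrichment_cutoff)
    bad <- profiles$cluster[unknown_flags]
    assigned[clusters %in% bad] <- "unknown"
  }

  embedding <- extract_embedding(joint, A_norm, model)
  predictions <- data.frame(cell_id = pred$cell_id, assigned = assigned,
                            confidence = pred$confidence,
                            stringsAsFactors = FALSE)

  metrics <- NULL
  if (!is.null(query_truth)) {
    acc <- accuracy_score(stats::setNames(assigned, pred$cell_id), query_truth)
    mix <- batch_mixing_entropy(embedding, joint$dataset,
                                n_regions = 100L,
                                n_neighbors = min(100L, nrow(embedding) - 1L),
                                seed = seed)
    truth_all <- c(as.character(ref_labels[colnames(std$reference)]),
                   as.character(query_truth[pred$cell_id]))
    sil <- silhouette_coefficient(embedding, truth_all)
    metrics <- list(accuracy = acc$accuracy,
                    per_class_accuracy = acc$per_class_accuracy,
                    confusion = acc$confusion,
                    mixing_entropy = mix,
                    silhouette = sil)
  }

  structure(list(predictions = predictions,
                 probabilities = pred$probabilities,
                 threshold = threshold,
                 model = model, graph = graph, A_norm = A_norm,
                 projection = proj, features = features, joint = joint,
                 embedding = embedding, clusters = clusters,
                 profiles = profiles, unknown_flags = unknown_flags,
                 metrics = metrics,
                 class_names = joint$class_names,
                 config = list(max_features = max_features, k = proj$k,
                               n_neighbors = n_neighbors,
                               hidden_dims = hidden_dims, lr = lr,
                               max_epochs = max_epochs, patience = patience,
                               threshold = threshold, seed = seed),
                 call = cl),
            class = "gcn_transfer")
}

#' @export
print.gcn_transfer <- function(x, ...) {
  cat("Graph-convolutional label transfer\n")
  cat(sprintf("  %d reference + %d query cells, %d features, k = %d, hidden = %d\n",
              x$joint$n_ref, x$joint$n_query, nrow(x$joint$X), x$config$k,
              x$model$hidden_dim))
  tab <- sort(table(x$predictions$assigned), decreasing = TRUE)
  cat("  query assignments:\n")
  print(tab)
  if (!is.null(x$metrics)) {
    cat(sprintf("  accuracy vs supplied truth: %.4f\n", x$metrics$accuracy))
  }
  invisible(x)
}

#' @export
summary.gcn_transfer <- function(object, ...) {
  x <- object
  cat("Graph-convolutional label transfer - summary\n\n")
  cat(sprintf("Graph: %d inter / %d intra edges over %d + %d cells\n",
              nrow(x$graph$edges_inter), nrow(x$graph$edges_intra),
              x$joint$n_ref, x$joint$n_query))
  log <- x$model$training_log
  cat(sprintf("Training: %d epochs, final val loss %.4f, val accuracy %.4f\n",
              nrow(log), log$val_loss[nrow(log)], log$val_acc[nrow(log)]))
  cat(sprintf("Assignments (threshold %.2f):\n", x$threshold))
  print(sort(table(x$predictions$assigned), decreasing = TRUE))
  cat(sprintf("Mean confidence: %.4f\n", mean(x$predictions$confidence)))
  if (!is.null(x$profiles)) {
    cat("\nQuery cluster screen (entropy / enrichment):\n")
    print(data.frame(x$profiles, unknown = x$unknown_flags,
                     row.names = NULL), digits = 4)
  }
  if (!is.null(x$metrics)) {
    cat(sprintf("\nAccuracy: %.4f\n", x$metrics$accuracy))
    cat("Per-class accuracy:\n")
    print(round(x$metrics$per_class_accuracy, 4))
    cat(sprintf("Median mixing entropy: %.4f   Mean silhouette: %.4f\n",
                stats::median(x$metrics$mixing_entropy),
                mean(x$metrics$silhouette)))
  }
  invisible(x)
}

#' @export
coef.gcn_transfer <- function(object, ...) object$model$weights

#' @export
fitted.gcn_transfer <- function(object, ...) object$probabilities

#' Re-threshold query predictions of a fitted transfer
#'
#' @param object a [gcn_transfer()] fit.
#' @param threshold assignment threshold (defaults to the fitted one).
#' @param ... unused.
#' @return data frame with `cell_id`, `assigned`, `confidence` (the unknown
#'   screen of the original fit is re-applied).
#' @export
predict.gcn_transfer <- function(object, threshold = NULL, ...) {
  threshold <- threshold %||% object$threshold
  pred <- predict_labels(object$probabilities, threshold = threshold)
  assigned <- pred$assigned
  if (!is.null(object$unknown_flags)) {
    bad <- object$profiles$cluster[object$unknown_flags]
    assigned[object$clusters %in% bad] <- "unknown"
  }
  data.frame(cell_id = pred$cell_id, assigned = assigned,
             confidence = pred$confidence, stringsAsFactors = FALSE)
}

#' Plot the learned joint embedding
#'
#' Principal-component view of the GCN hidden embedding, colored by predicted
#' (or reference) label with plotting symbol distinguishing the datasets.
#'
#' @param x a [gcn_transfer()] fit.
#' @param color `"label"` (default) or `"dataset"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gcn_transfer <- function(x, color = c("label", "dataset"), ...) {
  color <- match.arg(color)
  pc <- stats::prcomp(x$embedding, rank. = 2L)
  lab <- if (color == "dataset") x$joint$dataset else {
    ref_lab <- max.col(x$joint$onehot[seq_len(x$joint$n_ref), , drop = FALSE])
    c(x$class_names[ref_lab], x$predictions$assigned)
  }
  lab <- factor(lab)
  pch <- ifelse(x$joint$dataset == "reference", 16L, 17L)
  graphics::plot(pc$x[, 1L], pc$x[, 2L], col = as.integer(lab), pch = pch,
                 xlab = "PC1", ylab = "PC2", ...)
  graphics::legend("topright", legend = levels(lab),
                   col = seq_len(nlevels(lab)), pch = 15L, cex = 0.8)
  invisible(x)
}

#' Within-dataset label-transfer benchmark
#'
#' Splits one labeled dataset into a pseudo-reference and pseudo-query by a
#' stratified random `holdout_fraction` split (default 50/50), runs
#' [gcn_transfer()], and reports the recovery accuracy on the held-out half.
#' Classes too small to split are kept whole in the reference with a warning.
#'
#' @param data genes x cells [expression_matrix()].
#' @param labels [cell_labels()] for all cells.
#' @param holdout_fraction fraction of cells held out as the query
#'   (default 0.5).
#' @param seed RNG seed for the split (also passed to the fit).
#' @param ... further arguments to [gcn_transfer()].
#' @return list with `accuracy` and the full `fit`.
#' @export
within_data_benchmark <- function(data, labels, holdout_fraction = 0.5,
                                  seed = 0L, ...) {
  data <- as_expression_matrix(data, "reference")
  if (!inherits(labels, "cell_labels")) labels <- cell_labels(labels)
  cells <- colnames(data)
  y <- factor(as.character(labels[cells]))
  hold <- logical(length(cells))
  whole <- character(0)
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      n_hold <- floor(length(idx) * holdout_fraction)
      if (n_hold < 1L || length(idx) - n_hold < 2L) {
        whole <- c(whole, cl)
        next
      }
      hold[sample(idx, n_hold)] <- TRUE
    }
  })
  if (length(whole)) {
    warning("class(es) too small to split, kept whole in the reference: ",
            paste(whole, collapse = ", "))
  }
  ref <- em_subset(data, j = which(!hold))
  qry <- structure(unclass(data)[, hold, drop = FALSE],
                   dataset_tag = "query",
                   class = c("expression_matrix", "matrix", "array"))
  fit <- gcn_transfer(ref, qry, ref_labels = labels[colnames(ref)],
                      query_truth = labels[colnames(qry)], seed = seed, ...)
  list(accuracy = fit$metrics$accuracy, fit = fit)
}
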