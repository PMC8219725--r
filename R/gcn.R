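#' Build the joint node-feature input for the GCN
#'
#' Concatenates the standardized reference and query columns
#' (reference-then-query node order), one-hot encodes the reference labels
#' (query rows stay zero), and partitions the labeled reference cells into
#' train/validation/test masks, stratified by class. Classes with at least 3
#' cells contribute to all three masks; classes with 1-2 cells go entirely to
#' the training mask with a warning. The split is deterministic given `seed`.
#'
#' @param ref_std,query_std standardized matrices sharing feature rows.
#' @param labels [cell_labels()] for the reference cells.
#' @param split_fractions train/validation/test fractions summing to 1
#'   (default `c(0.8, 0.1, 0.1)`).
#' @param seed RNG seed for the random stratified split.
#' @return object of class `joint_input`: list with `X` (features x nodes),
#'   `onehot` (nodes x F), `masks` (logical train/val/test over nodes),
#'   `class_names`, `n_ref`, `n_query`, `cell_ids`, `dataset`.
#' @export
build_joint_input <- function(ref_std, query_std, labels,
                              split_fractions = c(0.8, 0.1, 0.1), seed = 0L) {
  stopifnot(abs(sum(split_fractions) - 1) < 1e-8, length(split_fractions) == 3L)
  if (!identical(rownames(ref_std), rownames(query_std))) {
    stop("reference and query must be row-aligned on the same features")
  }
  cells_r <- colnames(ref_std)
  cells_q <- colnames(query_std)
  if (!all(cells_r %in% names(labels))) stop("unlabeled reference cell(s)")
  y <- factor(as.character(labels[cells_r]))
  cls <- levels(y)
  n_r <- length(cells_r)
  n_q <- length(cells_q)
  N <- n_r + n_q

  X <- cbind(as.matrix(ref_std), as.matrix(query_std))
  onehot <- matrix(0, N, length(cls), dimnames = list(NULL, cls))
  onehot[cbind(seq_len(n_r), as.integer(y))] <- 1

  train <- val <- test <- logical(N)
  tiny <- character(0)
  with_seed(seed, {
    for (ci in seq_along(cls)) {
      idx <- which(as.integer(y) == ci)
      n <- length(idx)
      if (n < 3L) {
        tiny <- c(tiny, cls[ci])
        train[idx] <- TRUE
        next
      }
      idx <- sample(idx)
      n_val <- max(1L, floor(n * split_fractions[2L]))
      n_test <- max(1L, floor(n * split_fractions[3L]))
      val[idx[seq_len(n_val)]] <- TRUE
      test[idx[n_val + seq_len(n_test)]] <- TRUE
      train[idx[(n_val + n_test + 1L):n]] <- TRUE
    }
  })
  if (length(tiny)) {
    warning("class(es) with < 3 cells assigned entirely to training: ",
            paste(tiny, collapse = ", "))
  }
  structure(list(X = X, onehot = onehot,
                 masks = list(train = train, val = val, test = test),
                 class_names = cls, n_ref = n_r, n_query = n_q,
                 cell_ids = c(cells_r, cells_q),
                 dataset = rep(c("reference", "query"), c(n_r, n_q))),
            class = "joint_input")
}

#' Single graph-convolution layer
#'
#' Returns `activation(A_norm %*% H %*% W)`.
#'
#' @param H node x d input matrix.
#' @param A_norm renormalized adjacency from [normalize_adjacency()].
#' @param W d x d' weight matrix.
#' @param activation `"relu"`, `"identity"` or `"softmax"` (row-wise).
#' @return node x d' matrix.
#' @export
gcn_layer <- function(H, A_norm, W, activation = c("relu", "identity", "softmax")) {
  activation <- match.arg(activation)
  if (ncol(H) != nrow(W)) stop("shape mismatch: ncol(H) != nrow(W)")
  if (nrow(H) != nrow(A_norm)) stop("shape mismatch: nrow(H) != nrow(A_norm)")
  Z <- as.matrix(A_norm %*% H) %*% W
  switch(activation,
         relu = pmax(Z, 0),
         identity = Z,
         softmax = row_softmax(Z))
}

# Shared forward pass on the precomputed XA = A_norm %*% t(X) (nodes x m).
gcn_forward_xa <- function(XA, A_norm, W0, W1, drop_mask = NULL) {
  Z1 <- XA %*% W0
  H1 <- pmax(Z1, 0)
  if (!is.null(drop_mask)) H1 <- H1 * drop_mask
  AH <- as.matrix(A_norm %*% H1)
  Z2 <- AH %*% W1
  list(Z1 = Z1, H1 = H1, AH = AH, P = row_softmax(Z2))
}

#' Full forward propagation of the two-layer GCN
#'
#' Computes `softmax(A_norm %*% ReLU(A_norm %*% t(X) %*% W0) %*% W1)`; each
#' output row is a probability distribution over the F classes.
#'
#' @param joint a [build_joint_input()] result.
#' @param A_norm renormalized adjacency.
#' @param model a trained [train_gcn()] model (or any list with `weights`).
#' @return nodes x F probability matrix (rows sum to 1).
#' @export
gcn_forward <- function(joint, A_norm, model) {
  XA <- as.matrix(A_norm %*% t(joint$X))
  P <- gcn_forward_xa(XA, A_norm, model$weights[[1L]], model$weights[[2L]])$P
  if (!all(is.finite(P))) stop("non-finite activations in forward pass")
  colnames(P) <- joint$class_names
  rownames(P) <- joint$cell_ids
  P
}

#' Masked cross-entropy loss
#'
#' `-sum over masked nodes of sum_f Y_lf * ln(Yhat_lf)` (a sum, not a mean),
#' with the log argument clamped at 1e-12.
#'
#' @param pred probability matrix (rows in the simplex).
#' @param onehot matching one-hot label matrix.
#' @param mask logical (or integer index) vector selecting labeled nodes.
#' @return nonnegative scalar loss.
#' @export
masked_cross_entropy <- function(pred, onehot, mask) {
  if (is.logical(mask)) mask <- which(mask)
  if (length(mask) == 0L) stop("empty mask")
  -sum(onehot[mask, , drop = FALSE] *
         log(pmax(pred[mask, , drop = FALSE], 1e-12)))
}

# Loss and analytic gradients of the masked cross-entropy wrt W0, W1.
# Used by the Adam loop and by the finite-difference gradient test.
gcn_gradients <- function(XA, A_norm, W0, W1, onehot, mask,
                          drop_mask = NULL, weight_decay = 0) {
  fw <- gcn_forward_xa(XA, A_norm, W0, W1, drop_mask)
  loss <- masked_cross_entropy(fw$P, onehot, mask)
  G2 <- fw$P - onehot
  G2[!mask, ] <- 0
  dW1 <- crossprod(fw$AH, G2)
  dH <- as.matrix(A_norm %*% (G2 %*% t(W1)))
  if (!is.null(drop_mask)) dH <- dH * drop_mask
  dZ1 <- dH * (fw$Z1 > 0)
  dW0 <- crossprod(XA, dZ1)
  if (weight_decay > 0) {
    loss <- loss + weight_decay / 2 * (sum(W0^2) + sum(W1^2))
    dW0 <- dW0 + weight_decay * W0
    dW1 <- dW1 + weight_decay * W1
  }
  list(loss = loss, dW0 = dW0, dW1 = dW1, P = fw$P)
}

glorot_init <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

mask_accuracy <- function(P, onehot, mask) {
  if (!any(mask)) return(NA_real_)
  pred <- max.col(P[mask, , drop = FALSE], ties.method = "first")
  truth <- max.col(onehot[mask, , drop = FALSE], ties.method = "first")
  mean(pred == truth)
}

#' Train the semi-supervised GCN
#'
#' Full-batch Adam optimization of the masked cross-entropy over the training
#' mask, with early stopping when the validation loss fails to improve for
#' `patience` consecutive epochs (the best-validation weights are kept). When
#' several hidden dimensions are supplied, one model is trained per dimension
#' and the one with the highest validation accuracy wins (ties go to the
#' smaller dimension); `paper_hidden_dims` holds the published sweep list.
#'
#' @param joint a [build_joint_input()] result.
#' @param A_norm renormalized adjacency over the same nodes.
#' @param hidden_dims integer vector of hidden-layer widths to try
#'   (default 32).
#' @param lr Adam learning rate (default 0.01).
#' @param max_epochs maximum training epochs (default 200).
#' @param patience early-stopping window (default 10).
#' @param weight_decay L2 penalty coefficient (default 0 = off).
#' @param dropout dropout probability on the hidden layer during training
#'   (default 0 = off).
#' @param seed RNG seed controlling initialization (and dropout); training is
#'   deterministic given the seed.
#' @param verbose print per-epoch losses.
#' @return object of class `gcn_model`: list with `weights` (W0 m x h,
#'   W1 h x F), `hidden_dim`, `activation`, `training_log` (per-epoch data
#'   frame), `sweep` (per-dimension summary), `class_names`.
#' @export
train_gcn <- function(joint, A_norm, hidden_dims = 32L, lr = 0.01,
                      max_epochs = 200L, patience = 10L, weight_decay = 0,
                      dropout = 0, seed = 0L, verbose = FALSE) {
  XA <- as.matrix(A_norm %*% t(joint$X))
  m <- ncol(XA)
  Fk <- ncol(joint$onehot)
  tr <- joint$masks$train
  va <- joint$masks$val
  if (!any(tr)) stop("empty training mask")
  has_val <- any(va)

  fit_one <- function(h, dim_seed) with_seed(dim_seed, {
    W0 <- glorot_init(m, h)
    W1 <- glorot_init(h, Fk)
    mW0 <- vW0 <- W0 * 0; mW1 <- vW1 <- W1 * 0
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    best <- list(val = Inf, W0 = W0, W1 = W1)
    wait <- 0L
    log <- vector("list", max_epochs)
    for (t in seq_len(max_epochs)) {
      dm <- if (dropout > 0) {
        (matrix(stats::runif(nrow(XA) * h), nrow(XA), h) >= dropout) / (1 - dropout)
      } else NULL
      g <- gcn_gradients(XA, A_norm, W0, W1, joint$onehot, tr, dm, weight_decay)
      if (!is.finite(g$loss)) return(NULL)
      mW0 <- b1 * mW0 + (1 - b1) * g$dW0; vW0 <- b2 * vW0 + (1 - b2) * g$dW0^2
      mW1 <- b1 * mW1 + (1 - b1) * g$dW1; vW1 <- b2 * vW1 + (1 - b2) * g$dW1^2
      c1 <- 1 - b1^t; c2 <- 1 - b2^t
      W0 <- W0 - lr * (mW0 / c1) / (sqrt(vW0 / c2) + eps)
      W1 <- W1 - lr * (mW1 / c1) / (sqrt(vW1 / c2) + eps)

      ev <- gcn_forward_xa(XA, A_norm, W0, W1)
      train_loss <- masked_cross_entropy(ev$P, joint$onehot, tr)
      val_loss <- if (has_val) masked_cross_entropy(ev$P, joint$onehot, va) else train_loss
      log[[t]] <- data.frame(epoch = t, train_loss = train_loss,
                             val_loss = val_loss,
                             train_acc = mask_accuracy(ev$P, joint$onehot, tr),
                             val_acc = mask_accuracy(ev$P, joint$onehot, va))
      if (verbose) {
        message(sprintf("h=%d epoch %3d train %.4f val %.4f", h, t,
                        train_loss, val_loss))
      }
      if (val_loss < best$val) {
        best <- list(val = val_loss, W0 = W0, W1 = W1)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    log <- do.call(rbind, log[!vapply(log, is.null, logical(1))])
    ev <- gcn_forward_xa(XA, A_norm, best$W0, best$W1)
    list(W0 = best$W0, W1 = best$W1, log = log,
         val_acc = if (has_val) mask_accuracy(ev$P, joint$onehot, va)
                   else mask_accuracy(ev$P, joint$onehot, tr))
  })

  hidden_dims <- sort(as.integer(hidden_dims))
  fits <- list()
  for (i in seq_along(hidden_dims)) {
    fits[[i]] <- fit_one(hidden_dims[i], seed + i - 1L)
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("training diverged (non-finite loss) for every hidden dimension")
  accs <- vapply(fits, function(f) if (is.null(f)) -Inf else f$val_acc, numeric(1))
  pick <- which.max(accs)            # ascending dims: ties keep the smaller
  best <- fits[[pick]]
  structure(list(weights = list(W0 = best$W0, W1 = best$W1),
                 hidden_dim = hidden_dims[pick],
                 activation = c("relu", "softmax"),
                 training_log = best$log,
                 sweep = data.frame(hidden_dim = hidden_dims[ok],
                                    val_accuracy = accs[ok]),
                 class_names = joint$class_names,
                 seed = seed),
            class = "gcn_model")
}

#' Published hidden-dimension sweep
#'
#' The hidden-layer widths checked when sweeping model capacity.
#' @export
paper_hidden_dims <- c(32L, 64L, 128L, 256L, 528L, 1024L)

#' @export
print.gcn_model <- function(x, ...) {
  n <- nrow(x$training_log)
  cat(sprintf("<gcn_model> hidden = %d, %d classes, %d epochs (final val loss %.4f)\n",
              x$hidden_dim, length(x$class_names), n, x$training_log$val_loss[n]))
  invisible(x)
}

#' Threshold class probabilities into label assignments
#'
#' A query cell is assigned class f when its probability for f reaches
#' `threshold` (default 0.5, under which at most one class can qualify except
#' for an exact tie, which goes to the lower class index and is reported);
#' cells where no class reaches the threshold are `"unassigned"`.
#'
#' @param prob n_query x F probability matrix (rows sum to 1), columns named
#'   by class.
#' @param threshold assignment threshold (default 0.5).
#' @return object of class `prediction_result`: list with `cell_id`,
#'   `assigned` (class name or "unassigned"), `confidence` (max probability)
#'   and the `probabilities` matrix.
#' @export
predict_labels <- function(prob, threshold = 0.5) {
  cls <- colnames(prob)
  if (is.null(cls)) cls <- paste0("class", seq_len(ncol(prob)))
  assigned <- rep("unassigned", nrow(prob))
  ties <- 0L
  for (i in seq_len(nrow(prob))) {
    meets <- which(prob[i, ] >= threshold)
    if (length(meets) == 0L) next
    if (length(meets) > 1L) {
      top <- meets[prob[i, meets] == max(prob[i, meets])]
      if (length(top) > 1L) ties <- ties + 1L
      meets <- top[1L]
    }
    assigned[i] <- cls[meets]
  }
  if (ties > 0L) message(sprintf("%d threshold tie(s) resolved to the lower class index", ties))
  structure(list(cell_id = rownames(prob) %||% as.character(seq_len(nrow(prob))),
                 assigned = assigned,
                 confidence = apply(prob, 1L, max),
                 probabilities = prob,
                 threshold = threshold),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  tab <- sort(table(x$assigned), decreasing = TRUE)
  cat(sprintf("<prediction_result> %d cells (threshold %.2f)\n",
              length(x$assigned), x$threshold))
  print(tab)
  invisible(x)
}

#' Hidden-layer embedding of all nodes
#'
#' Returns `ReLU(A_norm %*% t(X) %*% W0)`, the aggregated hidden
#' representation in which reference and query cells of the same type
#' co-locate; rows are tagged by dataset of origin.
#'
#' @inheritParams gcn_forward
#' @return (n_ref + n_query) x h matrix with a `dataset` attribute.
#' @export
extract_embedding <- function(joint, A_norm, model) {
  XA <- as.matrix(A_norm %*% t(joint$X))
  H <- pmax(XA %*% model$weights[[1L]], 0)
  rownames(H) <- joint$cell_ids
  attr(H, "dataset") <- joint$dataset
  H
}
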