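# Small fully-specified graph/feature instances for the network oracles.
toy_instance <- function(n = 6, m = 4, Fk = 3, seed = 20) {
  set.seed(seed)
  A <- matrix(rbinom(n * n, 1, 0.4), n, n)
  A <- (A + t(A)) > 0; diag(A) <- FALSE
  A_norm <- normalize_adjacency(A * 1)
  X <- matrix(rnorm(m * n), m, n)           # features x nodes
  onehot <- diag(Fk)[sample(Fk, n, TRUE), ]
  list(A_norm = A_norm, X = X, onehot = onehot, n = n, m = m, Fk = Fk)
}

test_that("gcn_layer equals a naive triple-loop multiply", {
  ti <- toy_instance()
  W <- matrix(rnorm(6 * 2), 6, 2)
  H <- matrix(rnorm(ti$n * 6), ti$n, 6)
  got <- gcn_layer(H, ti$A_norm, W, activation = "relu")
  Ad <- as.matrix(ti$A_norm)
  naive <- matrix(0, ti$n, 2)
  AH <- matrix(0, ti$n, 6)
  for (i in seq_len(ti$n)) for (j in seq_len(6)) {
    for (l in seq_len(ti$n)) AH[i, j] <- AH[i, j] + Ad[i, l] * H[l, j]
  }
  for (i in seq_len(ti$n)) for (j in 1:2) {
    for (l in seq_len(6)) naive[i, j] <- naive[i, j] + AH[i, l] * W[l, j]
  }
  expect_equal(got, pmax(naive, 0), tolerance = 1e-10)

  # identity propagation and the hand-evaluated 2-node case
  I2 <- normalize_adjacency(matrix(0, 2, 2))
  expect_equal(gcn_layer(diag(2), I2, diag(2), "identity"), diag(2))
  A2 <- Matrix::Matrix(matrix(0.5, 2, 2), sparse = TRUE)
  expect_equal(gcn_layer(diag(2), A2, diag(2), "relu"),
               matrix(0.5, 2, 2), ignore_attr = TRUE)
  expect_error(gcn_layer(diag(3), A2, diag(2)), "shape mismatch")
})

test_that("forward pass composes two layers and normalizes rows", {
  ti <- toy_instance()
  joint <- list(X = ti$X, class_names = paste0("k", seq_len(ti$Fk)),
                cell_ids = paste0("n", seq_len(ti$n)))
  W0 <- matrix(rnorm(ti$m * 5), ti$m, 5)
  W1 <- matrix(rnorm(5 * ti$Fk), 5, ti$Fk)
  model <- list(weights = list(W0, W1))
  P <- gcn_forward(joint, ti$A_norm, model)
  expect_equal(unname(rowSums(P)), rep(1, ti$n), tolerance = 1e-6)
  # compositional oracle from gcn_layer
  H1 <- gcn_layer(t(ti$X), ti$A_norm, W0, "relu")
  P2 <- gcn_layer(H1, ti$A_norm, W1, "softmax")
  expect_equal(unname(P), P2, tolerance = 1e-10)

  # zero weights -> uniform probabilities
  P0 <- gcn_forward(joint, ti$A_norm, list(weights = list(W0 * 0, W1 * 0)))
  expect_equal(unname(P0), matrix(1 / ti$Fk, ti$n, ti$Fk), tolerance = 1e-12)
})

test_that("an isolated node with crafted logits gives closed-form softmax", {
  A_norm <- normalize_adjacency(matrix(0, 1, 1))   # single node, Atilde = 1
  X <- matrix(1, 1, 1)                             # one feature
  W0 <- matrix(1, 1, 1)                            # hidden = relu(1) = 1
  W1 <- matrix(c(log(3), 0), 1, 2)                 # logits (ln 3, 0)
  joint <- list(X = X, class_names = c("a", "b"), cell_ids = "n1")
  P <- gcn_forward(joint, A_norm, list(weights = list(W0, W1)))
  expect_equal(unname(P[1, ]), c(0.75, 0.25), tolerance = 1e-12)
})

test_that("masked cross-entropy matches closed forms and brute force", {
  onehot <- diag(4)[c(1, 2, 3, 4, 1, 2, 3, 4, 1, 2), ]
  expect_equal(masked_cross_entropy(onehot, onehot, rep(TRUE, 10)), 0)
  unif <- matrix(0.25, 10, 4)
  expect_equal(masked_cross_entropy(unif, onehot, rep(TRUE, 10)),
               10 * log(4), tolerance = 1e-10)
  set.seed(21)
  P <- t(apply(matrix(runif(40), 10, 4), 1, function(r) r / sum(r)))
  mask <- c(rep(TRUE, 6), rep(FALSE, 4))
  brute <- 0
  for (i in 1:6) for (f in 1:4) {
    brute <- brute - onehot[i, f] * log(max(P[i, f], 1e-12))
  }
  expect_equal(masked_cross_entropy(P, onehot, mask), brute, tolerance = 1e-10)
  expect_error(masked_cross_entropy(P, onehot, rep(FALSE, 10)), "empty mask")
})

test_that("analytic gradients agree with central finite differences", {
  ti <- toy_instance(n = 6, m = 3, Fk = 2, seed = 22)
  XA <- as.matrix(ti$A_norm %*% t(ti$X))
  set.seed(22)
  W0 <- matrix(rnorm(3 * 4, sd = 0.5), 3, 4)
  W1 <- matrix(rnorm(4 * 2, sd = 0.5), 4, 2)
  mask <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  g <- gcnTransfer:::gcn_gradients(XA, ti$A_norm, W0, W1, ti$onehot, mask)
  lossf <- function(W0, W1) {
    P <- gcnTransfer:::gcn_forward_xa(XA, ti$A_norm, W0, W1)$P
    masked_cross_entropy(P, ti$onehot, mask)
  }
  h <- 1e-5
  for (w in c("dW0", "dW1")) {
    W <- if (w == "dW0") W0 else W1
    num <- W * 0
    for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W))) {
      Wp <- W; Wm <- W
      Wp[i, j] <- W[i, j] + h; Wm[i, j] <- W[i, j] - h
      num[i, j] <- if (w == "dW0") (lossf(Wp, W1) - lossf(Wm, W1)) / (2 * h)
                   else (lossf(W0, Wp) - lossf(W0, Wm)) / (2 * h)
    }
    rel <- max(abs(g[[w]] - num)) / max(1e-8, max(abs(num)))
    expect_lt(rel, 1e-4)
  }
})

test_that("stratified masks have the right sizes and are seed-deterministic", {
  set.seed(23)
  m <- 5
  mk_std <- function(n, prefix) {
    x <- matrix(rnorm(m * n), m, n,
                dimnames = list(paste0("g", 1:m), paste0(prefix, 1:n)))
    x
  }
  ref <- mk_std(100, "r"); qry <- mk_std(30, "q")
  lab <- cell_labels(setNames(rep(c("A", "B"), c(90, 10)), colnames(ref)))
  j1 <- build_joint_input(ref, qry, lab, seed = 5)
  j2 <- build_joint_input(ref, qry, lab, seed = 5)
  expect_identical(j1$masks, j2$masks)
  expect_equal(sum(j1$masks$train), 80)
  expect_equal(sum(j1$masks$val), 10)
  expect_equal(sum(j1$masks$test), 10)
  # masks disjoint, reference-only, each class in each mask
  expect_false(any(j1$masks$train & j1$masks$val))
  expect_false(any(with(j1$masks, train | val | test)[101:130]))
  y <- rep(c("A", "B"), c(90, 10))
  for (msk in j1$masks) expect_setequal(unique(y[msk[1:100]]), c("A", "B"))
  # proportions within one cell of the global split per class
  for (cl in c("A", "B")) {
    n_cl <- sum(y == cl)
    expect_lte(abs(sum(j1$masks$val[1:100] & y == cl) - 0.1 * n_cl), 1)
  }
  # one-hot rows of labeled cells sum to 1; query rows zero
  expect_true(all(rowSums(j1$onehot[1:100, ]) == 1))
  expect_true(all(j1$onehot[101:130, ] == 0))

  lab2 <- cell_labels(setNames(c(rep("A", 98), "B", "B"), colnames(ref)))
  expect_warning(build_joint_input(ref, qry, lab2, seed = 1), "entirely to training")
})

test_that("training reaches high accuracy on separable data, reproducibly", {
  sim <- simulate_pair(sim_config(n_genes = 150, n_types = 3,
                                  cells_per_type_ref = 50,
                                  cells_per_type_query = 50,
                                  batch_effect_sd = 0.2, seed = 30))
  fit <- suppressWarnings(suppressMessages(
    gcn_transfer(sim$reference, sim$query, sim$ref_labels, k = 15,
                 unknown_screen = FALSE, seed = 30)))
  log <- fit$model$training_log
  expect_gte(log$train_acc[nrow(log)], 0.95)
  fit2 <- suppressWarnings(suppressMessages(
    gcn_transfer(sim$reference, sim$query, sim$ref_labels, k = 15,
                 unknown_screen = FALSE, seed = 30)))
  expect_identical(fit$model$weights, fit2$model$weights)
  expect_identical(fit$predictions, fit2$predictions)
})

test_that("hidden-dim sweep keeps the smaller dimension on ties", {
  sim <- simulate_pair(sim_config(n_genes = 100, n_types = 2,
                                  cells_per_type_ref = 30,
                                  cells_per_type_query = 10, seed = 31))
  std <- suppressWarnings(standardize_pair(sim$reference, sim$query))
  joint <- build_joint_input(std$reference, std$query, sim$ref_labels, seed = 31)
  proj <- cca_project(std$reference, std$query, k = 8)
  g <- assemble_hybrid(build_inter_graph(proj, 5),
                       build_intra_graph(coords = proj$query_coords, n_neighbors = 5),
                       joint$n_ref, joint$n_query)
  model <- train_gcn(joint, normalize_adjacency(g), hidden_dims = c(8, 16),
                     max_epochs = 40, seed = 31)
  expect_equal(nrow(model$sweep), 2)
  if (model$sweep$val_accuracy[1] >= model$sweep$val_accuracy[2]) {
    expect_equal(model$hidden_dim, 8)
  }
})

test_that("predict_labels applies the 0.5 rule with deterministic ties", {
  prob <- rbind(c(0.9, 0.1), c(0.5, 0.5))
  colnames(prob) <- c("a", "b")
  res <- suppressMessages(predict_labels(prob, 0.5))
  expect_identical(res$assigned, c("a", "a"))
  expect_message(predict_labels(prob, 0.5), "tie")
  res2 <- predict_labels(rbind(c(0.4, 0.35, 0.25)), 0.5)
  expect_identical(res2$assigned, "unassigned")
})

test_that("embedding equals the first layer and spans all nodes", {
  ti <- toy_instance()
  joint <- list(X = ti$X, class_names = paste0("k", 1:3),
                cell_ids = paste0("n", 1:6),
                dataset = rep(c("reference", "query"), c(3, 3)))
  W0 <- matrix(rnorm(ti$m * 4), ti$m, 4)
  model <- list(weights = list(W0, matrix(rnorm(4 * 3), 4, 3)))
  E <- extract_embedding(joint, ti$A_norm, model)
  expect_equal(nrow(E), 6)
  expect_equal(unname(E), gcn_layer(t(ti$X), ti$A_norm, W0, "relu"),
               tolerance = 1e-12, ignore_attr = TRUE)
  E0 <- extract_embedding(joint, ti$A_norm, list(weights = list(W0 * 0, NULL)))
  expect_true(all(E0 == 0))
})
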