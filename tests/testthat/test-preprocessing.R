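test_that("align_features restricts both datasets to shared features in shared order", {
  mk <- function(genes, tag) {
    m <- matrix(seq_along(genes), length(genes), 2,
                dimnames = list(genes, paste0(tag, 1:2)))
    expression_matrix(m, tag)
  }
  out <- align_features(mk(c("A", "B", "C"), "reference"),
                        mk(c("B", "C", "D"), "query"))
  expect_identical(rownames(out$reference), c("B", "C"))
  expect_identical(rownames(out$query), c("B", "C"))

  r <- mk(c("A", "B", "C"), "reference")
  q <- mk(c("A", "B", "C"), "query")
  out <- align_features(r, q)
  expect_equal(unclass(out$reference), unclass(r), ignore_attr = TRUE)
  expect_equal(unclass(out$query), unclass(q), ignore_attr = TRUE)

  expect_error(align_features(mk("A", "reference"), mk("B", "query")),
               "no shared features")
})

test_that("duplicate feature ids are merged by element-wise maximum", {
  m <- matrix(c(1, 5, 2,
                4, 1, 9,
                0, 7, 3), 3, 3, byrow = TRUE,
              dimnames = list(c("dup", "dup", "g2"), paste0("c", 1:3)))
  em <- expression_matrix(m, "reference")
  expect_equal(nrow(em), 2)
  expect_equal(unname(unclass(em)["dup", ]), c(4, 5, 9))
})

test_that("qc_filter keeps cells/features by nonzero counts, one pass each", {
  set.seed(1)
  # 3 cells with 600 / 499 / 500 expressed genes out of 700
  X <- matrix(0, 700, 3, dimnames = list(sprintf("g%03d", 1:700), c("a", "b", "c")))
  X[1:600, 1] <- 1; X[1:499, 2] <- 1; X[1:500, 3] <- 1
  out <- qc_filter(expression_matrix(X, "reference"), min_features_per_cell = 500)
  expect_identical(colnames(out), c("a", "c"))

  em <- toy_reference()$mat
  expect_equal(unclass(qc_filter(em, 0, 0)), unclass(em), ignore_attr = TRUE)

  # brute-force feature pass on a 5x4 toy with one all-zero gene
  Y <- matrix(rpois(20, 1), 5, 4, dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
  Y[3, ] <- 0
  out <- qc_filter(expression_matrix(Y, "reference"), min_cells_per_feature = 1)
  expect_identical(rownames(out), rownames(Y)[rowSums(Y > 0) >= 1])
  # output is a submatrix: values unchanged
  expect_equal(unclass(out), Y[rownames(out), ], ignore_attr = TRUE)

  expect_error(qc_filter(expression_matrix(Y, "reference"),
                         min_features_per_cell = 100), "all 4 cells removed")
})

test_that("ANOVA F-statistics match stats::oneway.test gene by gene", {
  toy <- toy_reference(n_genes = 50, n_classes = 3, cells_per_class = 20)
  sel <- suppressWarnings(select_variable_features(toy$mat, toy$labels,
                                                   max_features = 50))
  f <- factor(as.character(toy$labels[colnames(toy$mat)]))
  for (g in rownames(toy$mat)) {
    x <- unclass(toy$mat)[g, ]
    if (var(x) == 0) next
    ref <- oneway.test(x ~ f, var.equal = TRUE)
    expect_equal(unname(sel$statistic[g]), unname(ref$statistic),
                 tolerance = 1e-8)
    expect_equal(unname(sel$adjusted_p[g]),
                 min(1, unname(ref$p.value) * nrow(toy$mat)), tolerance = 1e-8)
  }
})

test_that("feature selection is deterministic and permutation-invariant", {
  toy <- toy_reference()
  sel1 <- suppressWarnings(select_variable_features(toy$mat, toy$labels, 10))
  # permute cells and genes
  pc <- sample(ncol(toy$mat)); pg <- sample(nrow(toy$mat))
  perm <- expression_matrix(unclass(toy$mat)[pg, pc], "reference")
  sel2 <- suppressWarnings(select_variable_features(perm, toy$labels, 10))
  expect_setequal(sel1$selected_features, sel2$selected_features)
  expect_identical(sel1$selected_features, sel2$selected_features)
})

test_that("degenerate genes and tiny classes are handled", {
  toy <- toy_reference()
  X <- unclass(toy$mat)
  X["g20", ] <- 7                       # constant gene
  em <- expression_matrix(X, "reference")
  sel <- suppressWarnings(select_variable_features(em, toy$labels, 20))
  expect_equal(unname(sel$adjusted_p["g20"]), 1)
  expect_false("g20" %in% sel$selected_features)

  lab <- setNames(c("solo", as.character(toy$labels[-1])), names(toy$labels))
  expect_error(select_variable_features(em, cell_labels(lab), 5), "solo")
})

test_that("standardize matches the closed form with population sd", {
  m <- matrix(c(1, 2, 3), 1, 3, dimnames = list("g1", paste0("c", 1:3)))
  out <- standardize(m)
  expect_equal(unname(out[1, ]), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(mean(out[1, ]), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(out[1, ]^2)), 1, tolerance = 1e-12)

  # idempotent on already standardized input
  again <- standardize(out)
  expect_equal(unclass(again), unclass(out), tolerance = 1e-12,
               ignore_attr = TRUE)

  # sample-sd variant
  s <- standardize(m, sd_type = "sample")
  expect_equal(unname(s[1, ]), c(-1, 0, 1), tolerance = 1e-12)
})

test_that("zero-variance rows are dropped from both datasets with a warning", {
  r <- matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("r", 1:3)))
  q <- matrix(c(4, 6, 8, 1, 2, 9), 2, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("q", 1:3)))
  expect_warning(out <- standardize(r), "zero-variance")
  expect_identical(attr(out, "dropped"), "g2")
  pair <- suppressWarnings(standardize_pair(r, q))
  expect_identical(rownames(pair$reference), "g1")
  expect_identical(rownames(pair$query), "g1")
  for (m in pair) {
    expect_true(all(abs(rowMeans(m)) < 1e-8))
    expect_true(all(abs(sqrt(rowMeans(m^2)) - 1) < 1e-6))
  }
})
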