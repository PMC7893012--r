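random_conn <- function(n, seed) {
  set.seed(seed)
  x <- matrix(rnorm(200 * n), 200, n)
  cor(x)
}

test_that("proportional threshold retains round(K * E) strongest |r| edges", {
  m <- random_conn(7, 61)
  expect_equal(proportional_threshold(m, 0.15)$n_edges, 3)   # round(3.15)
  expect_equal(proportional_threshold(m, 0.89)$n_edges, 19)  # round(18.69)
  bg <- proportional_threshold(m, 0.15)
  expect_equal(sum(bg$adjacency) / 2, 3)
  expect_identical(bg$adjacency, t(bg$adjacency))
  expect_true(all(diag(bg$adjacency) == 0))
  expect_error(proportional_threshold(m, 0.01), "zero edges")
})

test_that("strong negative edges are retained by absolute value", {
  idx <- edge_index(7)
  set.seed(62)
  v <- runif(21, -0.4, 0.4)
  v[5] <- -0.9
  m <- edge_to_matrix(v, 7, diag_value = 1)
  bg <- proportional_threshold(m, 0.1)   # round(2.1) = 2 edges
  kept <- which(bg$adjacency[idx] == 1)
  expect_true(5 %in% kept)
})

test_that("edge counts are identical across subjects at fixed cost", {
  counts <- vapply(1:6, function(s) {
    proportional_threshold(random_conn(7, 100 + s), 0.3)$n_edges
  }, numeric(1))
  expect_equal(length(unique(counts)), 1)
})

test_that("boundary ties break deterministically by lexicographic order", {
  v <- rep(0.5, 21)
  m <- edge_to_matrix(v, 7, diag_value = 1)
  b1 <- proportional_threshold(m, 0.15)
  b2 <- proportional_threshold(m, 0.15)
  expect_identical(b1$adjacency, b2$adjacency)
  idx <- edge_index(7)
  expect_equal(which(b1$adjacency[idx] == 1), 1:3)  # first edges in order
})

test_that("cost grids follow the documented endpoint convention", {
  g90 <- default_cost_grid("aal90")
  expect_equal(length(g90), 43)
  expect_equal(g90[1], 0.05)
  expect_equal(g90[43], 0.89)
  expect_equal(unique(round(diff(g90), 10)), 0.02)
  g7 <- default_cost_grid("yeo7")
  expect_equal(g7[1], 0.15)
  expect_equal(g7[length(g7)], 0.83)
  expect_true(all(g7 < 0.85))
})

test_that("measure curves integrate finite values over the grid", {
  m <- random_conn(7, 63)
  cm <- structure(list(values = m, subject_id = "s", condition = "natural",
                       atlas = yeo7_atlas()), class = "connectivity_matrix")
  mc <- measure_curves(cm, seed = 9)
  expect_equal(colnames(mc$values), c("B", "T", "A", "Geff", "S"))
  expect_equal(length(mc$k_grid), 35)
  expect_true(all(is.finite(mc$auc[c("B", "T", "Geff")])))
  expect_equal(mc$auc[["Geff"]],
               trapezoid_auc(mc$k_grid, mc$values[, "Geff"]))
  # Geff grows with cost
  expect_true(all(diff(mc$values[, "Geff"]) >= 0))
})

test_that("AUC comparison is calibrated on identical input and reproducible", {
  set.seed(64)
  auc <- matrix(rnorm(24 * 5), 24, 5,
                dimnames = list(NULL, c("B", "T", "A", "Geff", "S")))
  same <- compare_conditions_auc(auc, auc, n_perm = 500, seed = 3)
  expect_true(all(same$p_value > 0.99))
  a2 <- auc + matrix(rnorm(24 * 5, 0.5, 0.2), 24, 5)
  r1 <- compare_conditions_auc(a2, auc, n_perm = 500, seed = 4)
  r2 <- compare_conditions_auc(a2, auc, n_perm = 500, seed = 4)
  expect_identical(r1$p_value, r2$p_value)
  expect_true(all(r1$p_value < 0.05))
  # subjects with undefined AUCs are dropped with a warning
  a3 <- auc; a3[1, 2] <- NaN
  expect_warning(r3 <- compare_conditions_auc(a3, auc, n_perm = 200,
                                              seed = 5), "dropped")
  expect_equal(r3$n_subjects, c(24, 23, 24, 24, 24))
})

test_that("BH step-up matches the worked decisions", {
  d1 <- fdr_correct(c(0.01, 0.02, 0.03, 0.04, 0.5))
  expect_equal(d1$significant, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  d2 <- fdr_correct(c(0.029, 0.013, 0.048, 0.4, 0.6))
  expect_false(any(d2$significant))
  expect_false(any(fdr_correct(rep(1, 5))$significant))
  expect_error(fdr_correct(numeric(0)), "empty")
  expect_equal(fdr_correct(c(0.01, 0.04))$p_adjusted,
               p.adjust(c(0.01, 0.04), "BH"))
})
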