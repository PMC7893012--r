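test_that("edge-wise paired t matches hand computation and t.test", {
  tr <- matrix(c(0.2, 0.3, 0.1, 0.4), 4, 1) + 0.5
  rf <- matrix(0.5, 4, 1)
  res <- edgewise_paired_t(tr, rf)
  expect_equal(res$t, 3.873, tolerance = 1e-3)
  expect_equal(res$df, 3)
  expect_equal(res$t,
               unname(t.test(tr[, 1], rf[, 1], paired = TRUE)$statistic))
  expect_equal(edgewise_paired_t(tr, tr)$t, 0)
})

test_that("constant nonzero differences trigger the zero-variance guard", {
  tr <- matrix(1, 4, 2); rf <- matrix(0, 4, 2)
  expect_warning(res <- edgewise_paired_t(tr, rf), "zero-variance")
  expect_equal(res$t, c(0, 0))
})

test_that("covariate-adjusted t equals the lm intercept test", {
  set.seed(21)
  n <- 12
  d <- matrix(rnorm(n * 5), n, 5)
  cov <- rnorm(n)
  res <- edgewise_paired_t(d, matrix(0, n, 5), covariate = cov)
  expect_equal(res$df, n - 2)
  for (j in 1:5) {
    fit <- summary(lm(d[, j] ~ scale(cov, scale = FALSE)))
    expect_equal(res$t[j], fit$coefficients["(Intercept)", "t value"],
                 tolerance = 1e-10)
  }
  # a constant covariate is equivalent to no covariate
  plain <- edgewise_paired_t(d, matrix(0, n, 5))
  const <- edgewise_paired_t(d, matrix(0, n, 5), covariate = rep(3, n))
  expect_equal(const$t, plain$t)
  expect_equal(const$df, plain$df)
})

test_that("suprathreshold component search finds BFS components", {
  idx <- edge_index(7)
  key <- paste(idx[, 1], idx[, 2])
  tvec <- rep(0, 21)
  tvec[match(c("1 2", "2 3", "5 6"), key)] <- 3
  comps <- suprathreshold_components(tvec, 2.5, 7)
  expect_equal(sort(vapply(comps, `[[`, integer(1), "extent")), c(1L, 2L))
  expect_equal(length(suprathreshold_components(rep(0, 21), 2.5, 7)), 0)
  all_comp <- suprathreshold_components(rep(5, 21), 2.5, 7)
  expect_equal(length(all_comp), 1)
  expect_equal(all_comp[[1]]$extent, 21)
  expect_equal(all_comp[[1]]$nodes, 1:7)
})

test_that("raising the primary threshold never grows a component", {
  set.seed(22)
  tvec <- rnorm(21, 1.5, 1.5)
  for (pair in list(c(1, 2), c(2, 2.5), c(2.5, 3))) {
    lo <- suprathreshold_components(tvec, pair[1], 7)
    hi <- suprathreshold_components(tvec, pair[2], 7)
    expect_lte(length(hi), length(lo))
    if (length(hi) && length(lo)) {
      expect_lte(max(vapply(hi, `[[`, integer(1), "extent")),
                 max(vapply(lo, `[[`, integer(1), "extent")))
    }
    hi_edges <- unlist(lapply(hi, `[[`, "edges"))
    lo_edges <- unlist(lapply(lo, `[[`, "edges"))
    expect_true(all(hi_edges %in% lo_edges))
  }
})

test_that("NBS permutation is deterministic under a fixed seed", {
  set.seed(23)
  n <- 10
  tr <- matrix(rnorm(n * 21, 0.3), n, 21)
  rf <- matrix(rnorm(n * 21), n, 21)
  cfg <- nbs_config(primary_threshold = 2, n_permutations = 200, seed = 99)
  r1 <- nbs_permutation(tr, rf, cfg)
  r2 <- nbs_permutation(tr, rf, cfg)
  expect_identical(r1$null_max_extent, r2$null_max_extent)
  expect_identical(lapply(r1$components, `[[`, "p_fwe"),
                   lapply(r2$components, `[[`, "p_fwe"))
  expect_true(all(vapply(r1$components, `[[`, numeric(1), "p_fwe") >=
                    1 / 201))
})

test_that("NBS p-values are equivariant under node relabelling", {
  set.seed(24)
  n <- 12; nn <- 7
  tr <- matrix(rnorm(n * 21, 0.25), n, 21)
  rf <- matrix(rnorm(n * 21), n, 21)
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  idx <- edge_index(nn)
  # edge remap under the node permutation
  key <- paste(pmin(perm[idx[, 1]], perm[idx[, 2]]),
               pmax(perm[idx[, 1]], perm[idx[, 2]]))
  remap <- match(paste(idx[, 1], idx[, 2]), key)
  cfg <- nbs_config(primary_threshold = 2, n_permutations = 300, seed = 5)
  r1 <- nbs_permutation(tr, rf, cfg)
  r2 <- nbs_permutation(tr[, remap], rf[, remap], cfg)
  expect_identical(r1$null_max_extent, r2$null_max_extent)
  p1 <- sort(vapply(r1$components, `[[`, numeric(1), "p_fwe"))
  p2 <- sort(vapply(r2$components, `[[`, numeric(1), "p_fwe"))
  expect_equal(p1, p2)
})

test_that("few subjects triggers the coarse-resolution warning", {
  tr <- matrix(rnorm(4 * 21, 1), 4, 21)
  rf <- matrix(rnorm(4 * 21), 4, 21)
  expect_warning(
    nbs_permutation(tr, rf, nbs_config(n_permutations = 100, seed = 1)),
    "coarse")
})

test_that("null max-extent ranks are exchangeable with the observed extent", {
  # under a sign-symmetric null the observed max extent should not be
  # systematically extreme relative to the permutation null
  set.seed(26)
  n <- 16
  ranks <- replicate(40, {
    d <- matrix(rnorm(n * 21), n, 21)
    res <- nbs_permutation(d, matrix(0, n, 21),
                           nbs_config(primary_threshold = 2,
                                      n_permutations = 100,
                                      seed = sample.int(1e6, 1)))
    obs <- if (length(res$components)) {
      max(vapply(res$components, `[[`, integer(1), "extent"))
    } else 0L
    mean(res$null_max_extent < obs)
  })
  # mean sub-null rank should be near its exchangeable expectation
  expect_gt(mean(ranks), 0.20)
  expect_lt(mean(ranks), 0.65)
})
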