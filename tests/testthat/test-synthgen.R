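test_that("population covariance places base and planted correlations", {
  cfg <- synthetic_config(base_between_r = 0.1, delta_r = 0.3,
                          covariate_slope = 0)
  atl <- cfg$atlas
  nat <- build_population_covariance(cfg, cfg$years_mean, "natural")
  blt <- build_population_covariance(cfg, cfg$years_mean, "built")
  dmn <- which(atl$network_of == "Default")
  dan <- which(atl$network_of == "DorsalAttention")
  vis <- which(atl$network_of == "Visual")
  expect_equal(nat[dmn, dan], 0.4)
  expect_equal(blt[dmn, dan], 0.1)
  expect_equal(nat[dmn, vis], 0.1)
  expect_equal(diag(nat), rep(1, 7), ignore_attr = TRUE)
  # null configuration: conditions identical for every subject
  cfg0 <- synthetic_config(delta_r = 0, covariate_slope = 0)
  for (yu in c(0, 7.65, 15)) {
    expect_equal(build_population_covariance(cfg0, yu, "natural"),
                 build_population_covariance(cfg0, yu, "built"))
  }
})

test_that("covariate slope shifts only natural planted edges", {
  cfg <- synthetic_config(covariate_slope = -0.01)
  atl <- cfg$atlas
  lo <- build_population_covariance(cfg, 0, "natural")
  hi <- build_population_covariance(cfg, 15, "natural")
  dmn <- which(atl$network_of == "Default")
  dan <- which(atl$network_of == "DorsalAttention")
  vis <- which(atl$network_of == "Visual")
  expect_equal(lo[dmn, dan] - hi[dmn, dan], 0.15)
  expect_equal(lo[dmn, vis], hi[dmn, vis])
  expect_equal(build_population_covariance(cfg, 0, "built"),
               build_population_covariance(cfg, 15, "built"))
})

test_that("non-positive-definite configurations are rejected", {
  a90 <- aal90_atlas()
  cfg <- synthetic_config(atlas = a90, delta_r = 0.3)
  expect_error(build_population_covariance(cfg, 7.65, "natural"),
               "positive definite")
  # but the same delta is fine on the 7-node atlas
  expect_silent(build_population_covariance(synthetic_config(), 7.65,
                                            "natural"))
})

test_that("sampled timeseries converge to the target correlation", {
  cv <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
  ts <- sample_timeseries(cv, 10000, 2, noise_sd = 0, seed = 31)
  r <- cor(ts$data)[1, 2]
  expect_gte(r, 0.78)
  expect_lte(r, 0.82)
  # identity covariance: mean off-diagonal correlation near zero
  rs <- vapply(1:20, function(k) {
    ts <- sample_timeseries(diag(4), 400, 2, noise_sd = 0, seed = 100 + k)
    mean(edge_vector(cor(ts$data)))
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.03)
  expect_identical(sample_timeseries(cv, 100, 2, seed = 7)$data,
                   sample_timeseries(cv, 100, 2, seed = 7)$data)
  expect_error(sample_timeseries(cv, 10, 2), "n_volumes")
})

test_that("simulated motion stays under the inclusion threshold", {
  still <- sample_motion(100, motion_scale = 0, seed = 1)
  expect_equal(framewise_displacement(still)$mean_fd, 0)
  fds <- vapply(1:100, function(k) {
    framewise_displacement(sample_motion(150, seed = k))$mean_fd
  }, numeric(1))
  expect_true(all(fds < 0.5))
  expect_gt(mean(fds), 0.02)   # but not implausibly still
  expect_identical(sample_motion(50, seed = 3)$params,
                   sample_motion(50, seed = 3)$params)
})

test_that("years of urban upbringing match the target moments on [0, 15]", {
  y <- sample_years_urban(20000, seed = 5)
  expect_true(all(y >= 0 & y <= 15))
  expect_equal(mean(y), 7.65, tolerance = 0.05)
  expect_equal(sd(y), 6.29, tolerance = 0.05)
})

test_that("full dataset generation is seed-reproducible with valid ranges", {
  cfg <- synthetic_config(n_subjects = 4, n_volumes = 60, seed = 77)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$timeseries, d2$timeseries)
  expect_identical(d1$subjects, d2$subjects)
  rating_cols <- grep("_(natural|built)$", names(d1$subjects), value = TRUE)
  for (rc in rating_cols) {
    expect_true(all(d1$subjects[[rc]] >= 0 & d1$subjects[[rc]] <= 100))
  }
  expect_true(all(d1$subjects$years_urban >= 0 &
                    d1$subjects$years_urban <= 15))
  # truth record identifies the planted edges without the config
  expect_equal(d1$truth$delta_r, cfg$delta_r)
  idx <- edge_index(7)
  planted <- idx[d1$truth$planted_edge_rows, , drop = FALSE]
  nets <- cfg$atlas$network_of
  pairs <- apply(planted, 1, function(e) {
    paste(sort(c(nets[e[1]], nets[e[2]])), collapse = "-")
  })
  expect_setequal(pairs, c("Default-DorsalAttention", "Default-Somatomotor",
                           "DorsalAttention-VentralAttention"))
})

test_that("the default covariate slope plants a clear negative correlation", {
  # with the fixed default slope (-0.010/year) the correlation between
  # years urban and mean planted natural connectivity must come out
  # negative and of roughly the designed magnitude; the precise
  # target-recovery study at the design conditions lives in the
  # acceptance suite
  cfg <- synthetic_config()
  rs <- vapply(1:30, function(k) {
    cfg$seed <- 6100 + k
    se <- simulate_condition_edges(cfg)
    cc <- component_mean_connectivity(se$stacked,
                                      se$truth$planted_edge_rows)
    yu <- se$subjects$years_urban[
      match(se$stacked$subjects, se$subjects$subject_id)]
    cor(yu, cc$mean_r[, "natural"])
  }, numeric(1))
  expect_lt(mean(rs), -0.3)
  expect_gt(mean(rs), -0.75)
})

test_that("edge recall is non-decreasing in the planted effect size", {
  recall_at <- function(delta, seed0) {
    cfg <- synthetic_config(n_subjects = 12, delta_r = delta,
                            covariate_slope = 0)
    mean(vapply(1:12, function(r) {
      cfg$seed <- seed0 + r
      se <- simulate_condition_edges(cfg)
      res <- nbs_permutation(se$stacked$conditions$natural,
                             se$stacked$conditions$built,
                             nbs_config(n_permutations = 200,
                                        seed = seed0 + 500 + r))
      sig <- significant_components(res)
      planted <- se$truth$planted_edge_rows
      length(intersect(unlist(lapply(sig, `[[`, "edges")), planted)) /
        length(planted)
    }, numeric(1)))
  }
  r_lo <- recall_at(0.05, 7100)
  r_hi <- recall_at(0.45, 7200)
  expect_gte(r_hi, r_lo)
  expect_gt(r_hi, 0.5)
})
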