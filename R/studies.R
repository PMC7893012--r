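# Replicated simulation studies over the generator: null calibration of
# the NBS stage, power / planted-edge recovery, covariate recovery, and
# AUC-test calibration.  These back the analysis drivers and the
# acceptance checks; each runs the same in-memory path as the pipeline
# (simulate -> preprocess -> Pearson matrices -> stacked edges) without
# touching disk.

#' Simulate one study replicate and return stacked edge matrices
#'
#' Runs the generator and the timeseries-level preprocessing (discard,
#' motion nuisance regression, detrend, band-pass), builds per
#' subject-condition Pearson matrices, and stacks them for the paired
#' analyses.
#'
#' @param config a [synthetic_config()].
#' @param discard leading volumes to drop (default 10).
#' @return list: `stacked` (see [stack_condition_matrices()]), `subjects`,
#'   `truth`, `fd_diff` (natural - built mean FD per subject), `gsf`
#'   (subject x condition matrix).
#' @export
simulate_condition_edges <- function(config = synthetic_config(),
                                     discard = 10) {
  ds <- simulate_dataset(config)
  conditions <- c("natural", "built")
  mats <- list()
  fd <- matrix(NA_real_, config$n_subjects, 2,
               dimnames = list(names(ds$timeseries), conditions))
  gsf <- fd
  for (s in names(ds$timeseries)) {
    for (cond in conditions) {
      ts <- preprocess_run(ds$timeseries[[s]][[cond]],
                           motion = ds$motion[[s]][[cond]],
                           discard = discard,
                           low_hz = config$band[1],
                           high_hz = config$band[2])
      mats[[paste(s, cond)]] <- pearson_matrix(ts, config$atlas)
      fd[s, cond] <- framewise_displacement(ds$motion[[s]][[cond]])$mean_fd
      gsf[s, cond] <- global_signal_fluctuation(ts)
    }
  }
  list(stacked = stack_condition_matrices(mats), subjects = ds$subjects,
       truth = ds$truth, fd_diff = fd[, "natural"] - fd[, "built"],
       gsf = gsf)
}

#' Null calibration study of the NBS stage
#'
#' Repeatedly simulates data with no condition effect (delta_r = 0, zero
#' covariate slope) and runs the pipeline's NBS stage.  Reports the
#' single-contrast rejection fraction (any component with p_fwe <= alpha
#' for the natural > built contrast) and the pipeline-level family-wise
#' rate (either one-sided contrast significant — the pipeline tests both
#' directions).
#'
#' @param n_reps replicates (200 in the default calibration study).
#' @param n_perm permutations per NBS call.
#' @param alpha significance level.
#' @param config template config; its delta_r / covariate_slope are zeroed.
#' @param threshold primary t threshold.
#' @param use_covariate include the mean-FD difference covariate (default
#'   TRUE, as in the pipeline).
#' @param seed study seed.
#' @return list with `rate_one_sided`, `rate_pipeline`, and the per-rep
#'   logical vectors.
#' @export
nbs_null_calibration <- function(n_reps = 200, n_perm = 1000, alpha = 0.05,
                                 config = synthetic_config(),
                                 threshold = 2.5, use_covariate = TRUE,
                                 seed = 1L) {
  config$delta_r <- 0
  config$covariate_slope <- 0
  rej_g <- rej_l <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    config$seed <- derive_seed(seed, 21, r)
    se <- simulate_condition_edges(config)
    cov <- if (use_covariate) se$fd_diff else NULL
    for (dir_label in c("greater", "less")) {
      res <- nbs_permutation(
        se$stacked$conditions$natural, se$stacked$conditions$built,
        nbs_config(primary_threshold = threshold, n_permutations = n_perm,
                   alpha = alpha, covariate = cov, direction = dir_label,
                   seed = derive_seed(seed, 22, r, dir_label == "greater")))
      hit <- length(significant_components(res, alpha)) > 0
      if (dir_label == "greater") rej_g[r] <- hit else rej_l[r] <- hit
    }
  }
  list(rate_one_sided = mean(rej_g), rate_pipeline = mean(rej_g | rej_l),
       reject_greater = rej_g, reject_less = rej_l)
}

#' Power / planted-edge recovery study
#'
#' Simulates a planted condition effect of standardised size `cohens_d`
#' (converted to the correlation scale by [delta_for_cohens_d()]) and
#' measures, per replicate, the recall of the planted edges among
#' significant NBS components and the smallest component p-value.
#'
#' @param n_reps replicates.
#' @param cohens_d standardised paired effect size on planted edges.
#' @param n_perm permutations per NBS call.
#' @param alpha significance level.
#' @param config template config.
#' @param seed study seed.
#' @return list with `success_rate` (fraction of replicates with recall >=
#'   `recall_target` and p_fwe <= alpha), `recall` vector, `p_min` vector,
#'   `delta_r` used.
#' @param recall_target recall defining a successful replicate (0.8).
#' @export
nbs_power_study <- function(n_reps = 50, cohens_d = 1.0, n_perm = 1000,
                            alpha = 0.05, config = synthetic_config(),
                            recall_target = 0.8, seed = 1L) {
  config$covariate_slope <- 0
  delta <- delta_for_cohens_d(cohens_d, config, n_reps = 60,
                              seed = derive_seed(seed, 31))
  config$delta_r <- delta
  recall <- p_min <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    config$seed <- derive_seed(seed, 32, r)
    se <- simulate_condition_edges(config)
    res <- nbs_permutation(
      se$stacked$conditions$natural, se$stacked$conditions$built,
      nbs_config(n_permutations = n_perm, alpha = alpha,
                 covariate = se$fd_diff,
                 seed = derive_seed(seed, 33, r)))
    sig <- significant_components(res, alpha)
    planted <- se$truth$planted_edge_rows
    sig_edges <- unlist(lapply(sig, `[[`, "edges"))
    recall[r] <- length(intersect(sig_edges, planted)) / length(planted)
    p_min[r] <- if (length(res$components)) {
      min(vapply(res$components, `[[`, numeric(1), "p_fwe"))
    } else 1
  }
  list(success_rate = mean(recall >= recall_target & p_min <= alpha),
       recall = recall, p_min = p_min, delta_r = delta)
}

#' Covariate-correlation recovery / calibration study
#'
#' Simulates datasets with a covariate slope targeting population
#' correlation `target_r` (via [slope_for_target_r()]; 0 for the null) and
#' returns the per-replicate estimated Pearson r and p between years of
#' urban upbringing and mean planted-edge connectivity in the natural
#' condition.
#'
#' @param n_reps replicates.
#' @param target_r target population correlation (0 = null calibration).
#' @param config template config.
#' @param seed study seed.
#' @return list with `r` and `p` vectors and the `slope` used.
#' @export
covariate_recovery_study <- function(n_reps = 100, target_r = -0.5,
                                     config = synthetic_config(),
                                     seed = 1L) {
  slope <- if (target_r == 0) 0 else {
    slope_for_target_r(target_r, config, n_reps = 60,
                       seed = derive_seed(seed, 41))
  }
  config$covariate_slope <- slope
  r_est <- p_est <- numeric(n_reps)
  for (k in seq_len(n_reps)) {
    config$seed <- derive_seed(seed, 42, k)
    se <- simulate_condition_edges(config)
    cc <- component_mean_connectivity(se$stacked,
                                      se$truth$planted_edge_rows)
    yu <- se$subjects$years_urban[
      match(se$stacked$subjects, se$subjects$subject_id)]
    # gate opened: we score the estimate itself, not the follow-up
    ct <- stats::cor.test(yu, cc$mean_r[, "natural"])
    r_est[k] <- unname(ct$estimate)
    p_est[k] <- ct$p.value
  }
  list(r = r_est, p = p_est, slope = slope)
}

#' AUC permutation-test calibration study
#'
#' Simulates null datasets (no condition effect), computes per-subject
#' measure-curve AUCs for both conditions, and runs the paired AUC
#' permutation test; returns the replicate x measure p-value matrix, which
#' should be uniform under the null.
#'
#' @param n_reps replicates.
#' @param n_perm sign-flip permutations per test.
#' @param config template config (delta_r / slope zeroed).
#' @param k_grid cost grid (default: atlas default).
#' @param n_swaps rewiring swaps (default: atlas default).
#' @param seed study seed.
#' @export
auc_null_calibration <- function(n_reps = 200, n_perm = 500,
                                 config = synthetic_config(),
                                 k_grid = NULL, n_swaps = NULL, seed = 1L) {
  config$delta_r <- 0
  config$covariate_slope <- 0
  k_grid <- k_grid %||% default_cost_grid(config$atlas$name)
  n_swaps <- n_swaps %||% default_n_swaps(config$atlas$name)
  measures <- c("B", "T", "A", "Geff", "S")
  pmat <- matrix(NA_real_, n_reps, length(measures),
                 dimnames = list(NULL, measures))
  for (r in seq_len(n_reps)) {
    config$seed <- derive_seed(seed, 51, r)
    se <- simulate_condition_edges(config)
    n <- length(se$stacked$subjects)
    auc_n <- auc_b <- matrix(NA_real_, n, length(measures),
                             dimnames = list(NULL, measures))
    for (s in seq_len(n)) {
      for (cond in c("natural", "built")) {
        ev <- se$stacked$conditions[[cond]][s, ]
        cm <- edge_to_matrix(ev, config$atlas$n_rois, diag_value = 1)
        mc <- measure_curves(cm, k_grid = k_grid, n_swaps = n_swaps,
                             seed = derive_seed(seed, 52, r, s,
                                                cond == "natural"))
        if (cond == "natural") auc_n[s, ] <- mc$auc else auc_b[s, ] <- mc$auc
      }
    }
    cmp <- suppressWarnings(
      compare_conditions_auc(auc_n, auc_b, n_perm = n_perm,
                             seed = derive_seed(seed, 53, r)))
    pmat[r, ] <- cmp$p_value
  }
  pmat
}
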