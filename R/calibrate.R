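# Effect-size calibration for the synthetic generator.  The planted
# condition effect is specified either directly on the correlation scale
# (delta_r) or in Cohen's d units relative to the sampling noise of the
# paired edge difference; the covariate slope is specified via the target
# population correlation.  Both helpers estimate the relevant sampling SD
# by Monte Carlo under the generator's own conditions (same series length,
# band, noise, and preprocessing) so the calibration tracks the config.

# simulate paired natural/built planted-edge differences with no planted
# covariate dependence, through the exact study path (generator with
# motion, discard, nuisance regression, band-pass, Pearson): returns a
# (replicate*subject) x planted-edge matrix of differences and a vector
# of natural-condition mean planted r.  The preserved delta_r keeps the
# natural condition at its analysed correlation level so the sampling
# noise is estimated where the analysis operates.
simulate_null_edge_noise <- function(config, n_reps = 60, seed = 1L) {
  cfg <- config
  cfg$covariate_slope <- 0
  cfg$n_subjects <- 2L
  n_batches <- ceiling(n_reps / cfg$n_subjects)
  rows <- planted_edge_rows(config$atlas, config$planted_edges)
  diffs <- NULL
  nat_mean <- numeric(0)
  for (b in seq_len(n_batches)) {
    cfg$seed <- derive_seed(seed, 11, b)
    se <- simulate_condition_edges(cfg)
    d <- se$stacked$conditions$natural - se$stacked$conditions$built
    diffs <- rbind(diffs, d[, rows, drop = FALSE])
    nat_mean <- c(nat_mean,
                  rowMeans(se$stacked$conditions$natural[, rows,
                                                         drop = FALSE]))
  }
  list(diffs = diffs[seq_len(n_reps), , drop = FALSE],
       nat_mean = nat_mean[seq_len(n_reps)])
}

#' Planted-effect size delta_r for a target Cohen's d
#'
#' Estimates the sampling SD of the paired (natural - built) sample
#' correlation at the planted edges under the config's conditions and
#' returns `d * SD`, i.e. the correlation-scale effect whose standardised
#' paired effect size is d.  The estimation runs the full study path
#' (generator including motion, preprocessing, Pearson matrices) so the
#' returned value reflects the noise the analysis actually sees.
#'
#' @param d target Cohen's d of the paired edge difference.
#' @param config a `synthetic_config`; its delta_r sets the correlation
#'   level at which the sampling noise is estimated.
#' @param n_reps Monte-Carlo replicates (default 60).
#' @param seed RNG seed.
#' @export
delta_for_cohens_d <- function(d, config = synthetic_config(), n_reps = 60,
                               seed = 1L) {
  sim <- simulate_null_edge_noise(config, n_reps, seed)
  d * mean(apply(sim$diffs, 2, stats::sd))
}

#' Covariate slope for a target population correlation
#'
#' The generator places a linear dependence of the natural-condition
#' planted-edge correlation on centred years of urban upbringing.  The
#' observable correlation between the covariate and the *sample* mean
#' planted-edge connectivity is attenuated by sampling noise; with
#' per-subject noise SD sigma_e and covariate SD sigma_u, the slope
#' achieving population correlation rho is
#' `rho / sqrt(1 - rho^2) * sigma_e / sigma_u`.  sigma_e is estimated by
#' Monte Carlo under the config's own conditions.
#'
#' @param target_r desired population correlation (e.g. -0.47).
#' @param config a `synthetic_config`.
#' @param n_reps Monte-Carlo replicates (default 60).
#' @param seed RNG seed.
#' @export
slope_for_target_r <- function(target_r, config = synthetic_config(),
                               n_reps = 60, seed = 1L) {
  stopifnot(abs(target_r) < 1)
  sim <- simulate_null_edge_noise(config, n_reps, seed)
  sigma_e <- stats::sd(sim$nat_mean)
  target_r / sqrt(1 - target_r^2) * sigma_e / config$years_sd
}
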