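#' Configuration of the synthetic study generator
#'
#' Emulates the data structure of a paired two-condition (natural vs built
#' viewing) resting-state study: 24 subjects, two 5-minute runs at
#' TR = 2 s (150 volumes of which the first 10 are discardable), ROI
#' signals band-limited to 0.01-0.09 Hz with block correlation structure
#' over the seven canonical networks, a planted condition effect on
#' specific between-network edges, and a planted negative dependence of
#' the natural-condition planted-edge connectivity on years of urban
#' upbringing.
#'
#' @param n_subjects number of subjects (default 24).
#' @param atlas an `atlas_spec` (default [yeo7_atlas()]); its network
#'   labels define the community structure (for the 7-node atlas each node
#'   is its own community).
#' @param n_volumes volumes per run including the discardable lead-in
#'   (default 150).
#' @param tr_seconds repetition time (default 2).
#' @param base_within_r target correlation within a community (default 0.5;
#'   irrelevant for the 7-node atlas where communities are single nodes).
#' @param base_between_r target correlation between communities
#'   (default 0.1).
#' @param planted_edges character matrix / 2-column data of community
#'   pairs carrying the condition effect; default DMN-DAN, DMN-Somatomotor,
#'   DAN-VAN.
#' @param delta_r condition effect on the planted edges, natural minus
#'   built, on the correlation scale (default 0.3).
#' @param covariate_slope change in natural-condition planted-edge
#'   correlation per centred year of urban upbringing; the default is
#'   calibrated so the population correlation between years and mean
#'   planted-edge connectivity is close to -0.47 under the default config
#'   (see [slope_for_target_r()]).
#' @param years_mean,years_sd target moments of the years-of-urban-
#'   upbringing distribution on [0, 15] (defaults 7.65 and 6.29); matched
#'   exactly by a scaled Beta law.
#' @param noise_sd white observation noise SD relative to unit signal SD
#'   (default 0.2).
#' @param motion_scale mm scale of the simulated realignment random walk
#'   (default 0.026; with the per-run lognormal scale heterogeneity this
#'   yields mean FD near 0.125 mm with between-subject SD near 0.07 mm).
#' @param band passband in Hz (default c(0.01, 0.09)).
#' @param seed RNG seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 24, atlas = yeo7_atlas(),
                             n_volumes = 150, tr_seconds = 2,
                             base_within_r = 0.5, base_between_r = 0.1,
                             planted_edges = default_planted_edges(),
                             delta_r = 0.3, covariate_slope = -0.010,
                             years_mean = 7.65, years_sd = 6.29,
                             noise_sd = 0.2, motion_scale = 0.026,
                             band = c(0.01, 0.09), seed = 1L) {
  cfg <- structure(
    list(n_subjects = as.integer(n_subjects), atlas = atlas,
         n_volumes = as.integer(n_volumes), tr_seconds = tr_seconds,
         base_within_r = base_within_r, base_between_r = base_between_r,
         planted_edges = as.matrix(planted_edges), delta_r = delta_r,
         covariate_slope = covariate_slope, years_mean = years_mean,
         years_sd = years_sd, noise_sd = noise_sd,
         motion_scale = motion_scale, band = band, seed = as.integer(seed)),
    class = "synthetic_config"
  )
  validate_synthetic_config(cfg)
  cfg
}

#' Default planted community pairs (DMN-DAN, DMN-Somatomotor, DAN-VAN)
#' @export
default_planted_edges <- function() {
  rbind(c("Default", "DorsalAttention"),
        c("Default", "Somatomotor"),
        c("DorsalAttention", "VentralAttention"))
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 2, cfg$n_volumes >= 30, cfg$tr_seconds > 0,
            cfg$noise_sd >= 0, cfg$motion_scale >= 0,
            ncol(cfg$planted_edges) == 2)
  rng <- c(cfg$base_within_r, cfg$base_between_r,
           cfg$base_between_r + cfg$delta_r)
  # planted correlations at the covariate extremes must stay in (-1, 1)
  ymax_dev <- max(abs(c(0, 15) - cfg$years_mean))
  rng <- c(rng, cfg$base_between_r + cfg$delta_r +
             cfg$covariate_slope * c(-1, 1) * ymax_dev)
  if (any(rng <= -1 | rng >= 1)) {
    stop("base/planted correlations leave (-1, 1): ",
         paste(round(rng, 3), collapse = ", "))
  }
  invisible(cfg)
}

#' Population covariance (correlation) matrix for one subject-condition
#'
#' Block structure: `base_within_r` within a community, `base_between_r`
#' between communities, and — in the natural condition only — the planted
#' community pairs raised by `delta_r + covariate_slope * (years_urban -
#' years_mean)`.  Unit diagonal (correlation-scale construction).  The
#' matrix must be positive definite or the config is rejected.
#'
#' @param config a `synthetic_config`.
#' @param years_urban the subject's years of urban upbringing (enters the
#'   natural condition only).
#' @param condition `"natural"` or `"built"`.
#' @return N x N positive-definite correlation matrix.
#' @export
build_population_covariance <- function(config, years_urban,
                                        condition = c("natural", "built")) {
  condition <- match.arg(condition)
  net <- config$atlas$network_of
  n <- config$atlas$n_rois
  same <- outer(net, net, "==")
  cov <- ifelse(same, config$base_within_r, config$base_between_r)
  if (condition == "natural") {
    bump <- config$delta_r +
      config$covariate_slope * (years_urban - config$years_mean)
    for (k in seq_len(nrow(config$planted_edges))) {
      a <- config$planted_edges[k, 1]; b <- config$planted_edges[k, 2]
      sel <- (net == a) %o% (net == b) | (net == b) %o% (net == a)
      cov[sel] <- cov[sel] + bump
    }
  }
  diag(cov) <- 1
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop(sprintf(
      "implied %s-condition correlation matrix is not positive definite (min eigenvalue %.3g); adjust base/delta/slope",
      condition, min(ev)))
  }
  cov
}

#' Sample a band-limited correlated ROI timeseries
#'
#' Draws i.i.d. Gaussian vectors with the given covariance, band-limits
#' each column with the preprocessing module's zero-phase filter (the same
#' filter used downstream), rescales to unit variance, and adds white
#' observation noise.  Identical filtering of every column preserves the
#' contemporaneous correlation structure, so the expected sample
#' correlation converges to the implied correlation of `cov` as the series
#' lengthens (exactly for `noise_sd = 0`; attenuated by
#' 1/(1 + noise_sd^2) otherwise).
#'
#' @param cov positive-definite covariance/correlation matrix.
#' @param n_volumes series length (at least 20).
#' @param tr_seconds repetition time.
#' @param band passband in Hz.
#' @param noise_sd white-noise SD.
#' @param seed RNG seed.
#' @param roi_names optional column labels.
#' @return a `roi_timeseries`.
#' @export
sample_timeseries <- function(cov, n_volumes, tr_seconds = 2,
                              band = c(0.01, 0.09), noise_sd = 0,
                              seed = 1L, roi_names = NULL) {
  if (n_volumes < 20) stop("n_volumes < 20: correlation estimates meaningless")
  n <- nrow(cov)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("covariance is not positive definite")
  set.seed(seed)
  z <- matrix(stats::rnorm(n_volumes * n), n_volumes, n) %*% chol(cov)
  bf <- bandpass_coefs(tr_seconds, band[1], band[2])
  x <- apply(z, 2, function(col) filtfilt_padded(bf, col))
  # restore unit scale after filtering (per-column empirical SD; leaves
  # correlations untouched)
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1
  x <- sweep(x, 2, sds, "/")
  if (noise_sd > 0) {
    x <- x + matrix(stats::rnorm(n_volumes * n, sd = noise_sd),
                    n_volumes, n)
  }
  roi_timeseries(x, tr_seconds = tr_seconds, roi_names = roi_names)
}

#' Simulate a six-parameter realignment trace
#'
#' Small-step Gaussian random walk on the three translations (mm) and
#' three rotations (radians; rotation steps scaled by 1/50 so their arc
#' length on the 50 mm sphere matches the translation scale).  The default
#' scale yields mean FD around 0.125 mm, inside the range typical of
#' compliant adults and below the 0.5 mm inclusion threshold; the dataset
#' generator additionally draws a per-run lognormal scale multiplier so
#' subjects differ in overall motion.
#'
#' @param n_volumes number of frames.
#' @param motion_scale per-step SD in mm (default 0.026).
#' @param tr_seconds repetition time.
#' @param seed RNG seed.
#' @return a `motion_trace`.
#' @export
sample_motion <- function(n_volumes, motion_scale = 0.026, tr_seconds = 2,
                          seed = 1L) {
  stopifnot(motion_scale >= 0)
  set.seed(seed)
  steps <- matrix(stats::rnorm(n_volumes * 6, sd = motion_scale),
                  n_volumes, 6)
  steps[1, ] <- 0
  steps[, 4:6] <- steps[, 4:6] / 50
  motion_trace(apply(steps, 2, cumsum), tr_seconds = tr_seconds)
}

#' Sample years of urban upbringing on [0, 15]
#'
#' Scaled Beta law with shape parameters solved from the target mean and
#' SD by the method of moments.  The printed moments (mean 7.65,
#' SD 6.29 on a 0-15 range) imply a U-shaped distribution — most people
#' spent either none or all of their first 15 years in a major city —
#' which the Beta family represents exactly.
#'
#' @param n number of subjects.
#' @param mean_years,sd_years target moments.
#' @param seed RNG seed.
#' @export
sample_years_urban <- function(n, mean_years = 7.65, sd_years = 6.29,
                               seed = 1L) {
  mu <- mean_years / 15
  v <- (sd_years / 15)^2
  stopifnot(v < mu * (1 - mu))
  s <- mu * (1 - mu) / v - 1
  set.seed(seed)
  15 * stats::rbeta(n, mu * s, (1 - mu) * s)
}

#' Generate a full synthetic dataset
#'
#' Per subject and condition: a raw ROI timeseries (including the
#' discardable lead-in volumes) and a motion trace; per subject: years of
#' urban upbringing and post-condition ratings (PSS, rumination, valence,
#' arousal, dominance on a 0-100 slider, generated with zero true
#' condition effect).  The returned `truth` record carries the planted
#' edges and effect sizes so recovery can be scored without the config.
#'
#' @param config a [synthetic_config()].
#' @return object of class `synthetic_dataset`: `timeseries[[subject]][[condition]]`,
#'   `motion[[subject]][[condition]]`, `subjects` (data frame), `truth`,
#'   `config`.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  n <- config$n_subjects
  ids <- sprintf("sub%02d", seq_len(n))
  years <- sample_years_urban(n, config$years_mean, config$years_sd,
                              seed = derive_seed(config$seed, 1))
  conditions <- c("natural", "built")
  timeseries <- motion <- stats::setNames(vector("list", n), ids)
  for (s in seq_len(n)) {
    timeseries[[s]] <- motion[[s]] <- stats::setNames(
      vector("list", 2), conditions)
    for (ci in 1:2) {
      cond <- conditions[ci]
      cov <- build_population_covariance(config, years[s], cond)
      ts <- sample_timeseries(
        cov, config$n_volumes, config$tr_seconds, config$band,
        noise_sd = config$noise_sd,
        seed = derive_seed(config$seed, 2, s, ci),
        roi_names = config$atlas$roi_names)
      ts$subject_id <- ids[s]; ts$condition <- cond
      timeseries[[s]][[cond]] <- ts
      # per-run lognormal scale heterogeneity (unit mean): subjects and
      # runs differ in how much they move, as real cohorts do
      set.seed(derive_seed(config$seed, 5, s, ci))
      run_scale <- config$motion_scale * stats::rlnorm(1, -0.125, 0.5)
      motion[[s]][[cond]] <- sample_motion(
        config$n_volumes, run_scale, config$tr_seconds,
        seed = derive_seed(config$seed, 3, s, ci))
    }
  }
  set.seed(derive_seed(config$seed, 4))
  rating_names <- c("pss", "rumination", "valence", "arousal", "dominance")
  ratings <- list()
  for (cond in conditions) {
    for (r in rating_names) {
      ratings[[paste(r, cond, sep = "_")]] <-
        pmin(100, pmax(0, stats::rnorm(n, mean = 50, sd = 15)))
    }
  }
  subjects <- data.frame(subject_id = ids, years_urban = years, ratings,
                         stringsAsFactors = FALSE)
  truth <- list(planted_edges = config$planted_edges,
                delta_r = config$delta_r,
                covariate_slope = config$covariate_slope,
                planted_edge_rows = planted_edge_rows(config$atlas,
                                                      config$planted_edges))
  structure(list(timeseries = timeseries, motion = motion,
                 subjects = subjects, truth = truth, config = config),
            class = "synthetic_dataset")
}

#' Canonical edge-vector rows of the planted community pairs
#' @param atlas an `atlas_spec`.
#' @param planted_edges 2-column matrix of community pairs.
#' @return integer vector of row indices into [edge_index()].
#' @export
planted_edge_rows <- function(atlas, planted_edges) {
  idx <- edge_index(atlas$n_rois)
  rows <- integer(0)
  for (k in seq_len(nrow(planted_edges))) {
    pe <- network_pair_edges(atlas, planted_edges[k, 1], planted_edges[k, 2])
    rows <- c(rows, match(
      paste(pe[, "i"], pe[, "j"]), paste(idx[, "i"], idx[, "j"])))
  }
  sort(unique(rows))
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d subjects x 2 conditions, %d ROIs (%s), %d volumes\n",
              x$config$n_subjects, x$config$atlas$n_rois,
              x$config$atlas$name, x$config$n_volumes))
  invisible(x)
}
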