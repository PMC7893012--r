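#' Pipeline configuration
#'
#' One structured config drives the whole analysis:
#' simulate -> prep -> connectome -> nbs -> graph -> stats.  A serialised
#' copy of the resolved config is written into every stage's output
#' directory; a global seed deterministically spawns per-stage and
#' per-subject substreams (so adding subjects leaves earlier subjects'
#' draws untouched).
#'
#' @param out_dir output directory root.
#' @param synth a [synthetic_config()]; its `seed` is overridden by the
#'   pipeline seed.
#' @param fd_threshold motion inclusion threshold (mm).
#' @param discard leading volumes dropped in prep.
#' @param nbs_threshold,nbs_n_perm,nbs_alpha NBS parameters.
#' @param k_grid cost grid for the graph stage (default: atlas default).
#' @param n_swaps rewiring swaps (default: atlas default).
#' @param graph_n_perm AUC permutation count.
#' @param seed global seed.
#' @export
pipeline_config <- function(out_dir, synth = synthetic_config(),
                            fd_threshold = 0.5, discard = 10,
                            nbs_threshold = 2.5, nbs_n_perm = 10000,
                            nbs_alpha = 0.05, k_grid = NULL,
                            n_swaps = NULL, graph_n_perm = 10000,
                            seed = 1L) {
  synth$seed <- derive_seed(seed, 100)
  structure(
    list(out_dir = out_dir, synth = synth, fd_threshold = fd_threshold,
         discard = discard, nbs_threshold = nbs_threshold,
         nbs_n_perm = as.integer(nbs_n_perm), nbs_alpha = nbs_alpha,
         k_grid = k_grid %||% default_cost_grid(synth$atlas$name),
         n_swaps = n_swaps %||% default_n_swaps(synth$atlas$name),
         graph_n_perm = as.integer(graph_n_perm), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

pipeline_stages <- function() {
  c("simulate", "prep", "connectome", "nbs", "graph", "stats")
}

stage_dir <- function(config, stage) {
  d <- file.path(config$out_dir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(stage = stage, seed = config$seed,
         fd_threshold = config$fd_threshold, discard = config$discard,
         nbs_threshold = config$nbs_threshold,
         nbs_n_perm = config$nbs_n_perm, nbs_alpha = config$nbs_alpha,
         k_grid = config$k_grid, n_swaps = config$n_swaps,
         graph_n_perm = config$graph_n_perm,
         synth_atlas = config$synth$atlas$name,
         synth_seed = config$synth$seed),
    file.path(d, "config.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  d
}

# stacked matrices + motion summary from the prep/connectome stage outputs
load_stacked <- function(config) {
  atlas <- config$synth$atlas
  cd <- file.path(config$out_dir, "connectome")
  ms <- utils::read.csv(file.path(config$out_dir, "prep",
                                  "motion_summary.csv"))
  mats <- lapply(seq_len(nrow(ms)), function(k) {
    read_connectivity_matrix(
      file.path(cd, paste0(ms$subject[k], "_", ms$condition[k], ".tsv")),
      atlas, subject_id = ms$subject[k], condition = ms$condition[k])
  })
  list(stacked = stack_condition_matrices(mats), motion = ms)
}

#' Run one pipeline stage on the previous stage's on-disk outputs
#'
#' Stages: `simulate` (generate and serialise the synthetic dataset),
#' `prep` (FD, inclusion rule, discard / nuisance / band-pass),
#' `connectome` (Pearson matrices), `nbs` (both one-sided NBS contrasts
#' with the mean-FD-difference covariate), `graph` (measure curves, AUC
#' permutation tests, FDR), `stats` (ratings tests, component
#' connectivity, covariate correlation, urbanicity split ANOVA, GSF
#' confound check).
#'
#' @param config a [pipeline_config()].
#' @param stage stage name.
#' @return the stage output directory, invisibly.
#' @export
run_stage <- function(config, stage) {
  stopifnot(inherits(config, "pipeline_config"),
            stage %in% pipeline_stages())
  d <- stage_dir(config, stage)
  fun <- switch(stage, simulate = stage_simulate, prep = stage_prep,
                connectome = stage_connectome, nbs = stage_nbs,
                graph = stage_graph, stats = stage_stats)
  tryCatch(fun(config, d), error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(d)
}

stage_simulate <- function(config, d) {
  ds <- simulate_dataset(config$synth)
  write_dataset(ds, d)
}

stage_prep <- function(config, d) {
  ds <- read_dataset(file.path(config$out_dir, "simulate"))
  conditions <- c("natural", "built")
  fd <- lapply(ds$motion, function(by_cond) {
    lapply(by_cond, framewise_displacement)
  })
  incl <- apply_inclusion_rule(fd, threshold = config$fd_threshold)
  rows <- list()
  for (s in incl$kept) {
    for (cond in conditions) {
      ts <- preprocess_run(ds$timeseries[[s]][[cond]],
                           motion = ds$motion[[s]][[cond]],
                           discard = config$discard,
                           low_hz = config$synth$band[1],
                           high_hz = config$synth$band[2])
      write_timeseries(ts, file.path(d, paste0(s, "_", cond, ".tsv")))
      rows[[paste(s, cond)]] <- data.frame(
        subject = s, condition = cond,
        mean_fd = fd[[s]][[cond]]$mean_fd,
        gsf = global_signal_fluctuation(ts))
    }
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(d, "motion_summary.csv"), row.names = FALSE)
  utils::write.csv(data.frame(subject = incl$excluded),
                   file.path(d, "excluded.csv"), row.names = FALSE)
}

stage_connectome <- function(config, d) {
  atlas <- config$synth$atlas
  pd <- file.path(config$out_dir, "prep")
  ms <- utils::read.csv(file.path(pd, "motion_summary.csv"))
  for (k in seq_len(nrow(ms))) {
    s <- ms$subject[k]; cond <- ms$condition[k]
    ts <- read_timeseries(file.path(pd, paste0(s, "_", cond, ".tsv")),
                          tr_seconds = config$synth$tr_seconds,
                          subject_id = s, condition = cond)
    cm <- pearson_matrix(ts, atlas)
    write_connectivity_matrix(cm, file.path(d, paste0(s, "_", cond,
                                                      ".tsv")))
  }
}

stage_nbs <- function(config, d) {
  atlas <- config$synth$atlas
  ld <- load_stacked(config)
  wide <- stats::reshape(ld$motion[, c("subject", "condition", "mean_fd")],
                         idvar = "subject", timevar = "condition",
                         direction = "wide")
  wide <- wide[match(ld$stacked$subjects, wide$subject), ]
  fd_diff <- wide$mean_fd.natural - wide$mean_fd.built
  for (dir_label in c("greater", "less")) {
    res <- nbs_permutation(
      ld$stacked$conditions$natural, ld$stacked$conditions$built,
      nbs_config(primary_threshold = config$nbs_threshold,
                 n_permutations = config$nbs_n_perm,
                 alpha = config$nbs_alpha, covariate = fd_diff,
                 direction = dir_label,
                 seed = derive_seed(config$seed, 400,
                                    dir_label == "greater")))
    write_nbs_result(res, atlas, file.path(d, paste0("nbs_", dir_label)))
  }
}

stage_graph <- function(config, d) {
  atlas <- config$synth$atlas
  ld <- load_stacked(config)
  cd <- file.path(config$out_dir, "connectome")
  curves <- list()
  for (k in seq_len(nrow(ld$motion))) {
    s <- ld$motion$subject[k]; cond <- ld$motion$condition[k]
    cm <- read_connectivity_matrix(
      file.path(cd, paste0(s, "_", cond, ".tsv")), atlas,
      subject_id = s, condition = cond)
    curves[[k]] <- measure_curves(
      cm, k_grid = config$k_grid, n_swaps = config$n_swaps,
      seed = derive_seed(config$seed, 500, k))
  }
  auc <- write_measure_tables(curves, file.path(d, "curves.csv"),
                              file.path(d, "auc.csv"))
  measures <- c("B", "T", "A", "Geff", "S")
  nat <- as.matrix(auc[auc$condition == "natural", measures])
  rownames(nat) <- auc$subject[auc$condition == "natural"]
  blt <- as.matrix(auc[auc$condition == "built", measures])
  blt <- blt[match(rownames(nat), auc$subject[auc$condition == "built"]), ,
             drop = FALSE]
  cmp <- suppressWarnings(
    compare_conditions_auc(nat, blt, n_perm = config$graph_n_perm,
                           seed = derive_seed(config$seed, 501)))
  fdr <- fdr_correct(cmp$p_value)
  cmp$p_adjusted <- fdr$p_adjusted
  cmp$significant <- fdr$significant
  jsonlite::write_json(cmp, file.path(d, "auc_tests.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

stage_stats <- function(config, d) {
  atlas <- config$synth$atlas
  ds <- read_dataset(file.path(config$out_dir, "simulate"))
  ld <- load_stacked(config)
  kept <- ld$stacked$subjects
  subjects <- ds$subjects[match(kept, ds$subjects$subject_id), ]
  results <- list(ratings = paired_ratings_tests(subjects))
  nbs_summary <- jsonlite::read_json(
    file.path(config$out_dir, "nbs", "nbs_greater_summary.json"),
    simplifyVector = FALSE)
  sig <- Filter(function(cmp) cmp$p_fwe <= config$nbs_alpha,
                nbs_summary$components)
  if (length(sig) > 0) {
    comp_tab <- utils::read.csv(
      file.path(config$out_dir, "nbs", "nbs_greater_components.csv"))
    idx <- ld$stacked$edge_index
    nm <- atlas$roi_names
    comp_rows <- match(
      paste(match(comp_tab$roi_i, nm), match(comp_tab$roi_j, nm)),
      paste(idx[, "i"], idx[, "j"]))
    cc <- component_mean_connectivity(ld$stacked, comp_rows)
    corr <- covariate_correlation(cc, subjects$years_urban, "natural")
    results$covariate_correlation <- corr[c("r", "df", "p", "n")]
    if (!is.null(corr$per_edge)) results$per_edge <- corr$per_edge
    results$urban_split_anova <-
      tryCatch(urban_split_anova(cc, subjects$years_urban),
               error = function(e) conditionMessage(e))
    gsf_wide <- stats::reshape(ld$motion[, c("subject", "condition",
                                             "gsf")],
                               idvar = "subject", timevar = "condition",
                               direction = "wide")
    gsf_wide <- gsf_wide[match(kept, gsf_wide$subject), ]
    results$gsf_confound <- gsf_confound_check(
      gsf_wide[, c("gsf.natural", "gsf.built")], subjects$years_urban)
    utils::write.csv(data.frame(subject = kept, cc$mean_r),
                     file.path(d, "component_connectivity.csv"),
                     row.names = FALSE)
  } else {
    results$covariate_correlation <- "no significant NBS component"
  }
  jsonlite::write_json(results, file.path(d, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

#' Run the full pipeline on synthetic data
#'
#' Executes every stage in order, writing each stage's artifacts under
#' `out_dir/<stage>/` and returning a manifest of per-stage output hashes
#' and seeds.  Each stage reads the previous stage's on-disk outputs, so
#' every stage is also runnable standalone via [run_stage()].  Re-running
#' with the same config and seed reproduces byte-identical outputs (the
#' manifest records content hashes, not wall-clock times, so manifests
#' are byte-identical too).
#'
#' @param config a [pipeline_config()].
#' @return the manifest (also written to `out_dir/manifest.json`): per
#'   stage, a named list of file MD5 hashes, plus seeds and the package
#'   version.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(package_version =
                     as.character(utils::packageVersion("connstate")),
                   seed = config$seed, stages = list())
  for (stage in pipeline_stages()) {
    d <- run_stage(config, stage)
    files <- sort(list.files(d, recursive = TRUE, full.names = TRUE))
    h <- tools::md5sum(files)
    names(h) <- substring(names(h), nchar(config$out_dir) + 2)
    manifest$stages[[stage]] <- as.list(h)
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
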