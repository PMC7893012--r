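# Plain-text readers and writers for every artifact the pipeline exchanges
# between stages: tab-delimited timeseries, rp-style motion files,
# subject tables, connectivity matrices, component tables, and JSON
# summaries.  Numeric values are written with 17 significant digits so
# round-trips are lossless at double precision.

fmt_num <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)

#' Write / read an ROI timeseries as tab-delimited text
#'
#' T rows x N columns with a header row of ROI names.
#' @param ts a `roi_timeseries`.
#' @param path output file.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  df <- as.data.frame(apply(ts$data, 2, fmt_num))
  names(df) <- ts$roi_names
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @param tr_seconds repetition time to attach.
#' @param subject_id,condition identifiers to attach.
#' @param volumes_discarded lead-in volumes already removed upstream.
#' @export
read_timeseries <- function(path, tr_seconds = 2,
                            subject_id = NA_character_,
                            condition = NA_character_,
                            volumes_discarded = 0L) {
  df <- utils::read.delim(path, check.names = FALSE)
  roi_timeseries(as.matrix(df), tr_seconds = tr_seconds,
                 roi_names = names(df), subject_id = subject_id,
                 condition = condition,
                 volumes_discarded = volumes_discarded)
}

#' Write / read a motion trace as 6-column whitespace-delimited text
#'
#' rp-file convention: columns 1-3 translations (mm), 4-6 rotations
#' (radians), no header.
#' @param motion a `motion_trace`.
#' @param path output file.
#' @export
write_motion <- function(motion, path) {
  stopifnot(inherits(motion, "motion_trace"))
  utils::write.table(apply(motion$params, 2, fmt_num), path, sep = "  ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_motion
#' @param tr_seconds repetition time to attach.
#' @export
read_motion <- function(path, tr_seconds = 2) {
  m <- as.matrix(utils::read.table(path))
  motion_trace(unname(m), tr_seconds = tr_seconds)
}

#' Write / read a connectivity matrix as tab-delimited N x N text
#' @param conn a `connectivity_matrix`.
#' @param path output file.
#' @export
write_connectivity_matrix <- function(conn, path) {
  stopifnot(inherits(conn, "connectivity_matrix"))
  df <- as.data.frame(apply(conn$values, 2, fmt_num))
  names(df) <- conn$atlas$roi_names
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectivity_matrix
#' @param atlas the `atlas_spec` the matrix belongs to.
#' @param subject_id,condition identifiers to attach.
#' @export
read_connectivity_matrix <- function(path, atlas,
                                     subject_id = NA_character_,
                                     condition = NA_character_) {
  df <- utils::read.delim(path, check.names = FALSE)
  v <- unname(as.matrix(df))
  stopifnot(nrow(v) == atlas$n_rois, ncol(v) == atlas$n_rois)
  dimnames(v) <- list(atlas$roi_names, atlas$roi_names)
  structure(list(values = v, subject_id = subject_id,
                 condition = condition, atlas = atlas),
            class = "connectivity_matrix")
}

#' Write an NBS result: component CSV, JSON summary, viewer files
#'
#' `<prefix>_components.csv` lists every component edge (roi_i, roi_j, t);
#' `<prefix>_summary.json` carries extents and FWE p-values;
#' `<prefix>.node` / `<prefix>.edge` are a glass-brain-viewer-compatible
#' text pair (nodes on a unit circle, node size = suprathreshold degree,
#' edge matrix of component t-values).
#'
#' @param result an `nbs_result`.
#' @param atlas the `atlas_spec` used.
#' @param prefix output path prefix.
#' @export
write_nbs_result <- function(result, atlas, prefix) {
  comps <- result$components
  rows <- list()
  for (k in seq_along(comps)) {
    e <- comps[[k]]$edges
    rows[[k]] <- data.frame(
      component = k,
      roi_i = atlas$roi_names[result$edge_index[e, "i"]],
      roi_j = atlas$roi_names[result$edge_index[e, "j"]],
      t = result$edge_t[e])
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(component = integer(0), roi_i = character(0),
               roi_j = character(0), t = numeric(0))
  utils::write.csv(tab, paste0(prefix, "_components.csv"), row.names = FALSE)
  summary <- list(
    primary_threshold = result$config$primary_threshold,
    n_permutations = result$config$n_permutations,
    direction = result$config$direction,
    components = lapply(comps, function(cmp) {
      list(extent = cmp$extent, p_fwe = cmp$p_fwe,
           nodes = atlas$roi_names[cmp$nodes])
    }))
  jsonlite::write_json(summary, paste0(prefix, "_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  n <- atlas$n_rois
  theta <- 2 * pi * (seq_len(n) - 1) / n
  deg <- tabulate(c(result$edge_index[unlist(lapply(comps, `[[`, "edges")), ]),
                  nbins = n)
  node <- data.frame(x = round(cos(theta), 4), y = round(sin(theta), 4),
                     z = 0, color = as.integer(deg > 0), size = deg,
                     label = atlas$roi_names)
  utils::write.table(node, paste0(prefix, ".node"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  em <- matrix(0, n, n)
  for (cmp in comps) {
    ij <- result$edge_index[cmp$edges, , drop = FALSE]
    em[ij] <- result$edge_t[cmp$edges]
    em[ij[, c(2, 1), drop = FALSE]] <- result$edge_t[cmp$edges]
  }
  utils::write.table(em, paste0(prefix, ".edge"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Write measure curves and AUCs as tidy CSVs
#'
#' Long-format curve table (subject, condition, measure, K, value) and a
#' wide AUC table (subject, condition, one column per measure).
#'
#' @param curves list of `measure_curves` objects.
#' @param curve_path,auc_path output CSV paths.
#' @export
write_measure_tables <- function(curves, curve_path, auc_path) {
  long <- do.call(rbind, lapply(curves, function(mc) {
    data.frame(subject = mc$subject_id, condition = mc$condition,
               measure = rep(colnames(mc$values), each = length(mc$k_grid)),
               K = rep(mc$k_grid, ncol(mc$values)),
               value = as.vector(mc$values))
  }))
  utils::write.csv(long, curve_path, row.names = FALSE)
  auc <- do.call(rbind, lapply(curves, function(mc) {
    cbind(data.frame(subject = mc$subject_id, condition = mc$condition),
          as.data.frame(t(mc$auc)))
  }))
  utils::write.csv(auc, auc_path, row.names = FALSE)
  invisible(auc)
}

#' Serialise a synthetic dataset to a directory
#'
#' Layout: `timeseries/<subject>_<condition>.tsv`,
#' `motion/<subject>_<condition>.txt`, `subjects.csv`, `truth.json`,
#' `config.json`.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(file.path(dir, "timeseries"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "motion"), recursive = TRUE,
             showWarnings = FALSE)
  for (s in names(dataset$timeseries)) {
    for (cond in names(dataset$timeseries[[s]])) {
      write_timeseries(dataset$timeseries[[s]][[cond]],
                       file.path(dir, "timeseries",
                                 paste0(s, "_", cond, ".tsv")))
      write_motion(dataset$motion[[s]][[cond]],
                   file.path(dir, "motion", paste0(s, "_", cond, ".txt")))
    }
  }
  utils::write.csv(dataset$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  truth <- dataset$truth
  truth$planted_edges <- apply(truth$planted_edges, 1, paste,
                               collapse = "--")
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_config_json(dataset$config, file.path(dir, "config.json"))
  invisible(dir)
}

#' Read a serialised dataset directory back
#'
#' @param dir directory written by [write_dataset()].
#' @param config the generating `synthetic_config` (re-read from
#'   `config.json` when omitted; the atlas is reconstructed by name).
#' @export
read_dataset <- function(dir, config = NULL) {
  if (is.null(config)) config <- read_config_json(file.path(dir, "config.json"))
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                              stringsAsFactors = FALSE)
  ids <- subjects$subject_id
  conditions <- c("natural", "built")
  timeseries <- motion <- stats::setNames(vector("list", length(ids)), ids)
  for (s in ids) {
    timeseries[[s]] <- motion[[s]] <- stats::setNames(vector("list", 2),
                                                      conditions)
    for (cond in conditions) {
      timeseries[[s]][[cond]] <- read_timeseries(
        file.path(dir, "timeseries", paste0(s, "_", cond, ".tsv")),
        tr_seconds = config$tr_seconds, subject_id = s, condition = cond)
      motion[[s]][[cond]] <- read_motion(
        file.path(dir, "motion", paste0(s, "_", cond, ".txt")),
        tr_seconds = config$tr_seconds)
    }
  }
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  truth$planted_edges <- do.call(rbind,
                                 strsplit(truth$planted_edges, "--"))
  structure(list(timeseries = timeseries, motion = motion,
                 subjects = subjects, truth = truth, config = config),
            class = "synthetic_dataset")
}

write_config_json <- function(config, path) {
  out <- config
  out$atlas <- config$atlas$name
  out$planted_edges <- apply(config$planted_edges, 1, paste,
                             collapse = "--")
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

read_config_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  synthetic_config(
    n_subjects = raw$n_subjects, atlas = get_atlas(raw$atlas),
    n_volumes = raw$n_volumes, tr_seconds = raw$tr_seconds,
    base_within_r = raw$base_within_r, base_between_r = raw$base_between_r,
    planted_edges = do.call(rbind, strsplit(raw$planted_edges, "--")),
    delta_r = raw$delta_r, covariate_slope = raw$covariate_slope,
    years_mean = raw$years_mean, years_sd = raw$years_sd,
    noise_sd = raw$noise_sd, motion_scale = raw$motion_scale,
    band = raw$band, seed = raw$seed)
}
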