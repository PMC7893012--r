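#' Pearson connectivity matrix from ROI timeseries
#'
#' Edge weight between two ROIs is the sample Pearson correlation of their
#' timeseries; the matrix is symmetric with unit diagonal.  Raw r is used
#' (no Fisher z by default; the downstream component test is
#' permutation-calibrated, so the monotone transform does not change it —
#' set `fisher_z = TRUE` to work on z values instead).
#'
#' @param ts a `roi_timeseries`.
#' @param atlas an `atlas_spec` whose size matches the series.
#' @param fisher_z apply atanh to the off-diagonal entries.
#' @return object of class `connectivity_matrix` with fields `values`,
#'   `subject_id`, `condition`, `atlas`.
#' @export
pearson_matrix <- function(ts, atlas, fisher_z = FALSE) {
  stopifnot(inherits(ts, "roi_timeseries"), inherits(atlas, "atlas_spec"))
  if (ncol(ts$data) != atlas$n_rois) {
    stop("timeseries has ", ncol(ts$data), " ROIs; atlas ", atlas$name,
         " expects ", atlas$n_rois)
  }
  sds <- apply(ts$data, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance ROI(s): ",
         paste(ts$roi_names[sds == 0], collapse = ", "))
  }
  v <- stats::cor(ts$data)
  if (fisher_z) {
    z <- atanh(v)
    diag(z) <- 1
    v <- z
  }
  dimnames(v) <- list(atlas$roi_names, atlas$roi_names)
  structure(
    list(values = v, subject_id = ts$subject_id, condition = ts$condition,
         atlas = atlas),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s/%s: %d x %d (%s)\n",
              x$subject_id, x$condition, nrow(x$values), ncol(x$values),
              x$atlas$name))
  invisible(x)
}

#' Stack per-condition connectivity matrices into subject x edge arrays
#'
#' Aligns every subject's two matrices and flattens each to the canonical
#' upper-triangle edge vector, giving one subject x edge matrix per
#' condition — the input layout of the NBS edge tests.
#'
#' @param matrices list of `connectivity_matrix` objects (one per
#'   subject-condition; subject and condition read from each object).
#' @param conditions the two condition labels, in (treatment, reference)
#'   order; defaults to `c("natural", "built")`.
#' @return list with `conditions` (named list of subject x edge matrices,
#'   rows in common subject order), `subjects`, `edge_index`, `atlas`.
#' @export
stack_condition_matrices <- function(matrices,
                                     conditions = c("natural", "built")) {
  stopifnot(length(matrices) > 0)
  atlas <- matrices[[1]]$atlas
  for (m in matrices) {
    stopifnot(inherits(m, "connectivity_matrix"))
    if (!identical(m$atlas$roi_names, atlas$roi_names)) {
      stop("matrices mix atlases")
    }
  }
  subj <- vapply(matrices, function(m) m$subject_id, character(1))
  cond <- vapply(matrices, function(m) m$condition, character(1))
  subjects <- unique(subj)
  out <- list()
  for (cc in conditions) {
    rows <- lapply(subjects, function(s) {
      k <- which(subj == s & cond == cc)
      if (length(k) != 1) {
        stop("subject ", s, " has ", length(k), " matrices for condition '",
             cc, "' (need exactly 1)")
      }
      edge_vector(matrices[[k]]$values)
    })
    out[[cc]] <- do.call(rbind, rows)
    rownames(out[[cc]]) <- subjects
  }
  list(conditions = out, subjects = subjects,
       edge_index = edge_index(atlas$n_rois), atlas = atlas)
}
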