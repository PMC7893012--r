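#' Cost grid for a threshold range
#'
#' Inclusive start at `lower`, step `step`, last point strictly below
#' `upper` (the documented endpoint convention for the printed open
#' ranges).  Defaults per atlas: 0.05 <= K < 0.9 for the 90-node atlas,
#' 0.15 <= K < 0.85 for the 7-node atlas, step 0.02.
#'
#' @param lower,upper range bounds.
#' @param step grid step (default 0.02).
#' @export
cost_grid <- function(lower, upper, step = 0.02) {
  stopifnot(lower > 0, upper < 1, lower < upper, step > 0)
  g <- seq(lower, upper + step / 2, by = step)
  round(g[g < upper - 1e-12], 10)
}

#' Default cost grid for an atlas
#' @param atlas_name `"yeo7"` or `"aal90"`.
#' @export
default_cost_grid <- function(atlas_name) {
  switch(atlas_name,
    aal90 = cost_grid(0.05, 0.90),
    yeo7 = cost_grid(0.15, 0.85),
    stop("unknown atlas: ", atlas_name)
  )
}

#' Default rewiring swap count for an atlas
#' @param atlas_name `"yeo7"` or `"aal90"`.
#' @export
default_n_swaps <- function(atlas_name) {
  switch(atlas_name, aal90 = 10000L, yeo7 = 500L,
         stop("unknown atlas: ", atlas_name))
}

#' Graph measure curves and AUCs over a cost grid
#'
#' Binarises the connectivity matrix at every cost K on the grid and
#' computes the five measures: mean betweenness fraction (B), transitivity
#' (T), assortativity (A), global efficiency (Geff) and small-worldness
#' (S).  Each measure's AUC is the trapezoidal integral over the grid,
#' dropping grid points where the measure is undefined (A on regular
#' graphs, S when clustering vanishes) pairwise.
#'
#' @param conn a `connectivity_matrix` or plain symmetric matrix.
#' @param k_grid cost grid (default: the atlas default when `conn` is a
#'   `connectivity_matrix`).
#' @param n_swaps rewiring swap attempts for the small-world null.
#' @param n_null null realisations per graph (default 1).
#' @param seed RNG seed for the rewiring.
#' @return object of class `measure_curves`: `k_grid`, `values` (matrix
#'   K x measure), `auc` (named vector), `subject_id`, `condition`.
#' @export
measure_curves <- function(conn, k_grid = NULL, n_swaps = NULL, n_null = 1,
                           seed = 1L) {
  is_cm <- inherits(conn, "connectivity_matrix")
  if (is.null(k_grid)) {
    if (!is_cm) stop("k_grid required for a plain matrix")
    k_grid <- default_cost_grid(conn$atlas$name)
  }
  if (is.null(n_swaps)) {
    n_swaps <- if (is_cm) default_n_swaps(conn$atlas$name) else 100L
  }
  stopifnot(all(k_grid > 0 & k_grid < 1), !is.unsorted(k_grid, strictly = TRUE))
  measures <- c("B", "T", "A", "Geff", "S")
  vals <- matrix(NA_real_, length(k_grid), length(measures),
                 dimnames = list(NULL, measures))
  for (g in seq_along(k_grid)) {
    bg <- proportional_threshold(conn, k_grid[g])
    vals[g, "B"] <- betweenness(bg)$mean
    vals[g, "T"] <- transitivity(bg)
    vals[g, "A"] <- assortativity(bg)
    vals[g, "Geff"] <- global_efficiency(bg)
    vals[g, "S"] <- small_worldness(bg, n_swaps = n_swaps, n_null = n_null,
                                    seed = derive_seed(seed, g))$S
  }
  auc <- vapply(measures, function(m) trapezoid_auc(k_grid, vals[, m]),
                numeric(1))
  structure(
    list(k_grid = k_grid, values = vals, auc = auc,
         subject_id = if (is_cm) conn$subject_id else NA_character_,
         condition = if (is_cm) conn$condition else NA_character_),
    class = "measure_curves"
  )
}

#' @export
print.measure_curves <- function(x, ...) {
  cat(sprintf("<measure_curves> %s/%s: %d costs\n  AUC: %s\n",
              x$subject_id, x$condition, length(x$k_grid),
              paste(sprintf("%s=%.4g", names(x$auc), x$auc),
                    collapse = ", ")))
  invisible(x)
}

#' Paired permutation test on per-measure AUC differences
#'
#' Statistic: mean paired AUC difference (treatment - reference).  Null:
#' independent per-subject sign flips.  Two-sided p with the add-one
#' estimator.  Subjects with an undefined AUC for a measure are dropped
#' for that measure with a warning.
#'
#' @param treatment,reference subject x measure AUC matrices, aligned rows.
#' @param n_perm number of sign-flip permutations (default 10000).
#' @param seed RNG seed.
#' @return data frame: measure, n_subjects, mean_diff, p_value.
#' @export
compare_conditions_auc <- function(treatment, reference, n_perm = 10000,
                                   seed = 1L) {
  treatment <- as.matrix(treatment); reference <- as.matrix(reference)
  stopifnot(identical(dim(treatment), dim(reference)))
  measures <- colnames(treatment) %||% paste0("m", seq_len(ncol(treatment)))
  set.seed(seed)
  out <- lapply(seq_along(measures), function(j) {
    d <- treatment[, j] - reference[, j]
    ok <- is.finite(d)
    if (!all(ok)) {
      warning(sum(!ok), " subject(s) dropped for measure ", measures[j],
              " (undefined AUC)")
    }
    d <- d[ok]
    n <- length(d)
    if (n < 3) {
      return(data.frame(measure = measures[j], n_subjects = n,
                        mean_diff = NA_real_, p_value = NA_real_))
    }
    obs <- mean(d)
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    null_stat <- as.vector(S %*% d) / n
    p <- (1 + sum(abs(null_stat) >= abs(obs) - 1e-15)) / (1 + n_perm)
    data.frame(measure = measures[j], n_subjects = n, mean_diff = obs,
               p_value = p)
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up correction over the supplied p-values (here the five graph
#' measures); adjusted p-values via [stats::p.adjust()] with
#' `method = "BH"`.
#'
#' @param p_values numeric vector.
#' @param q FDR level (default 0.05).
#' @return data frame: p, p_adjusted, significant.
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) stop("empty p-value vector")
  adj <- stats::p.adjust(p_values, method = "BH")
  data.frame(p = p_values, p_adjusted = adj, significant = adj <= q)
}
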