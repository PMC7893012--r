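#' @keywords internal
"_PACKAGE"

#' Upper-triangle edge index table
#'
#' Fixed edge ordering used by every module: pairs (i, j) with i < j,
#' row-major (1-2, 1-3, ..., 1-N, 2-3, ...).
#'
#' @param n_nodes number of nodes.
#' @return two-column integer matrix with one row per edge, columns `i`, `j`.
#' @export
edge_index <- function(n_nodes) {
  stopifnot(n_nodes >= 2)
  idx <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  storage.mode(idx) <- "integer"
  idx
}

#' Extract upper-triangle edge weights in the canonical ordering
#' @param m symmetric matrix.
#' @return numeric vector of length n(n-1)/2.
#' @export
edge_vector <- function(m) {
  idx <- edge_index(nrow(m))
  m[idx]
}

#' Rebuild a symmetric matrix from an edge vector
#' @param v edge vector in canonical ordering.
#' @param n_nodes number of nodes.
#' @param diag_value value placed on the diagonal (default 0).
#' @export
edge_to_matrix <- function(v, n_nodes, diag_value = 0) {
  idx <- edge_index(n_nodes)
  stopifnot(length(v) == nrow(idx))
  m <- matrix(0, n_nodes, n_nodes)
  m[idx] <- v
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Trapezoidal area under a curve, skipping non-finite values pairwise
#'
#' Grid points where the measure is undefined (NaN/NA/Inf) are dropped and
#' the integral taken over the remaining points.
#'
#' @param x strictly increasing grid.
#' @param y values at the grid points.
#' @return scalar AUC, or NA if fewer than 2 finite points remain.
#' @export
trapezoid_auc <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(y)
  if (sum(keep) < 2) return(NA_real_)
  x <- x[keep]; y <- y[keep]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Deterministic substream seeds: one global seed spawns per-stage /
# per-subject / per-condition seeds so adding subjects leaves earlier
# subjects' draws untouched.  Kept below 2^31 - 1.
derive_seed <- function(seed, ...) {
  parts <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (p in parts) {
    h <- (h * 48271 + as.double(p) + 1) %% 2147483647
  }
  as.integer(h)
}

# round-half-away-from-zero (base round() is banker's rounding)
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
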