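#' NBS configuration
#'
#' @param primary_threshold edge-level t threshold defining suprathreshold
#'   edges (default 2.5).
#' @param n_permutations number of sign-flip permutations (default 10000).
#' @param alpha component-level FWE significance level (default 0.05).
#' @param covariate optional per-subject nuisance values (e.g. the
#'   condition difference in mean FD); centred and regressed out of the
#'   paired differences before testing.
#' @param direction `"greater"` tests treatment > reference (the headline
#'   contrast); `"less"` the reverse.
#' @param seed RNG seed for the permutations.
#' @export
nbs_config <- function(primary_threshold = 2.5, n_permutations = 10000,
                       alpha = 0.05, covariate = NULL,
                       direction = c("greater", "less"), seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(primary_threshold > 0, n_permutations >= 100,
            alpha > 0, alpha < 1)
  structure(
    list(primary_threshold = primary_threshold,
         n_permutations = as.integer(n_permutations), alpha = alpha,
         covariate = covariate, direction = direction,
         seed = as.integer(seed)),
    class = "nbs_config"
  )
}

#' Edge-wise paired t statistics
#'
#' For each edge, tests the per-subject condition difference
#' d_s = treatment_s - reference_s against zero.  Without a covariate this
#' is a one-sample t on d (df = n - 1).  With a covariate, d is modelled as
#' intercept + centred covariate and the intercept is tested (df = n - 2),
#' so between-subject nuisance variation (e.g. motion differences) is
#' removed from the error term.
#'
#' @param treatment,reference aligned subject x edge matrices.
#' @param covariate optional per-subject values.
#' @return list with `t` (per-edge statistic), `df`, and `d` (the
#'   difference matrix).  Edges with zero-variance differences get t = 0
#'   with a warning.
#' @export
edgewise_paired_t <- function(treatment, reference, covariate = NULL) {
  stopifnot(identical(dim(treatment), dim(reference)))
  n <- nrow(treatment)
  if (n < 3) stop("need at least 3 subjects for a paired t-test")
  d <- treatment - reference
  res <- t_from_differences(d, covariate)
  list(t = res$t, df = res$df, d = d)
}

# core t computation on a difference matrix; vectorised over edges,
# reusable for every sign-flip permutation
t_from_differences <- function(d, covariate = NULL) {
  n <- nrow(d)
  if (is.null(covariate)) {
    m <- colMeans(d)
    v <- (colSums(d * d) - n * m^2) / (n - 1)
    df <- n - 1
    se <- sqrt(v / n)
  } else {
    stopifnot(length(covariate) == n)
    cc <- covariate - mean(covariate)
    if (sum(cc^2) == 0) {
      # constant covariate carries no information: same as no covariate
      return(t_from_differences(d, NULL))
    }
    b1 <- colSums(d * cc) / sum(cc^2)
    b0 <- colMeans(d)
    rss <- colSums(d * d) - n * b0^2 - sum(cc^2) * b1^2
    rss[rss < 0] <- 0   # numerical guard
    df <- n - 2
    se <- sqrt(rss / df / n)
    m <- b0
  }
  t <- ifelse(se == 0, 0, m / se)
  zero_var <- se == 0 & m != 0
  if (any(zero_var)) {
    warning(sum(zero_var),
            " edge(s) with zero-variance nonzero differences; t set to 0")
  }
  list(t = t, df = df)
}

#' Connected components of suprathreshold edges
#'
#' Edges with t above `threshold` (one-sided) form a graph; breadth-first
#' search over that graph yields connected components, each reported with
#' its extent (number of edges).
#'
#' @param edge_t per-edge t statistics in canonical edge order.
#' @param threshold primary t threshold.
#' @param n_nodes number of nodes.
#' @return list of components, each a list with `edges` (row indices into
#'   [edge_index()]), `nodes`, `extent`.  Empty list when no edge passes.
#' @export
suprathreshold_components <- function(edge_t, threshold, n_nodes) {
  idx <- edge_index(n_nodes)
  stopifnot(length(edge_t) == nrow(idx))
  sup <- which(edge_t > threshold)
  if (length(sup) == 0) return(list())
  ei <- idx[sup, "i"]; ej <- idx[sup, "j"]
  comp_of <- bfs_node_components(ei, ej, n_nodes)
  comp_ids <- sort(unique(comp_of[ei]))
  lapply(comp_ids, function(cid) {
    in_comp <- comp_of[ei] == cid
    list(edges = sup[in_comp],
         nodes = sort(unique(c(ei[in_comp], ej[in_comp]))),
         extent = sum(in_comp))
  })
}

# label nodes touched by the given edges with a component id (BFS)
bfs_node_components <- function(ei, ej, n_nodes) {
  adj <- vector("list", n_nodes)
  for (k in seq_along(ei)) {
    adj[[ei[k]]] <- c(adj[[ei[k]]], ej[k])
    adj[[ej[k]]] <- c(adj[[ej[k]]], ei[k])
  }
  comp <- rep(NA_integer_, n_nodes)
  cid <- 0L
  for (s in sort(unique(c(ei, ej)))) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[is.na(comp[nb])]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }
  comp
}

# max component extent for one suprathreshold edge set (internal fast path)
max_extent <- function(sup_i, sup_j, n_nodes) {
  if (length(sup_i) == 0) return(0L)
  comp <- bfs_node_components(sup_i, sup_j, n_nodes)
  max(tabulate(comp[sup_i]))
}

#' NBS: permutation FWE test on suprathreshold components
#'
#' Observed edge t statistics are thresholded and their connected
#' components extracted; under the paired-design null, each subject's
#' difference vector is sign-flipped independently (covariate
#' re-residualised per permutation), and the maximal component extent per
#' permutation forms the null distribution.  Component p-values use the
#' add-one estimator p = (1 + #{null >= observed}) / (1 + n_permutations).
#'
#' @param treatment,reference aligned subject x edge matrices (see
#'   [stack_condition_matrices()]).
#' @param config an [nbs_config()].
#' @param n_nodes number of nodes (inferred from edge count if omitted).
#' @return object of class `nbs_result`: `edge_t`, `df`, `components`
#'   (each with `edges`, `nodes`, `extent`, `p_fwe`), `null_max_extent`,
#'   `config`.
#' @export
nbs_permutation <- function(treatment, reference, config = nbs_config(),
                            n_nodes = NULL) {
  stopifnot(inherits(config, "nbs_config"))
  n_edges <- ncol(treatment)
  if (is.null(n_nodes)) {
    n_nodes <- round((1 + sqrt(1 + 8 * n_edges)) / 2)
  }
  stopifnot(n_nodes * (n_nodes - 1) / 2 == n_edges)
  n <- nrow(treatment)
  if (n < 5) {
    warning("only ", n, " subjects: sign-flip null has just 2^", n,
            " distinct patterns; permutation resolution is coarse")
  }
  sgn <- if (config$direction == "greater") 1 else -1
  d <- sgn * (treatment - reference)
  obs <- t_from_differences(d, config$covariate)
  comps <- suprathreshold_components(obs$t, config$primary_threshold, n_nodes)

  idx <- edge_index(n_nodes)
  P <- config$n_permutations
  set.seed(config$seed)
  null_max <- integer(P)
  thr <- config$primary_threshold
  cov <- config$covariate
  chunk <- max(1L, min(P, as.integer(2e7 / n_edges)))
  done <- 0L
  ss <- colSums(d * d)           # invariant under sign flips
  cc <- if (!is.null(cov)) cov - mean(cov) else NULL
  if (!is.null(cc) && sum(cc^2) == 0) cc <- NULL
  while (done < P) {
    p_here <- min(chunk, P - done)
    S <- matrix(sample(c(-1, 1), p_here * n, replace = TRUE), p_here, n)
    M <- (S %*% d) / n                               # perm x edge means
    if (is.null(cc)) {
      V <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
      V[V < 0] <- 0
      Tm <- M / sqrt(V / n)
    } else {
      B1 <- (sweep(S, 2, cc, "*") %*% d) / sum(cc^2)
      RSS <- sweep(-n * M^2 - sum(cc^2) * B1^2, 2, ss, "+")
      RSS[RSS < 0] <- 0
      Tm <- M / sqrt(RSS / (n - 2) / n)
    }
    Tm[!is.finite(Tm)] <- 0
    for (p in seq_len(p_here)) {
      sup <- which(Tm[p, ] > thr)
      null_max[done + p] <- max_extent(idx[sup, "i"], idx[sup, "j"], n_nodes)
    }
    done <- done + p_here
  }

  for (k in seq_along(comps)) {
    comps[[k]]$p_fwe <- (1 + sum(null_max >= comps[[k]]$extent)) / (1 + P)
  }
  structure(
    list(edge_t = obs$t, df = obs$df, components = comps,
         null_max_extent = null_max, config = config,
         edge_index = idx, n_nodes = n_nodes),
    class = "nbs_result"
  )
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> threshold %g, %d permutations, direction %s\n",
              x$config$primary_threshold, x$config$n_permutations,
              x$config$direction))
  if (length(x$components) == 0) {
    cat("  no suprathreshold components\n")
  } else {
    for (k in seq_along(x$components)) {
      cmp <- x$components[[k]]
      cat(sprintf("  component %d: extent %d, p_fwe = %.4g\n",
                  k, cmp$extent, cmp$p_fwe))
    }
  }
  invisible(x)
}

#' Significant components of an NBS result
#' @param result an `nbs_result`.
#' @param alpha significance level (default: the config's alpha).
#' @export
significant_components <- function(result, alpha = NULL) {
  alpha <- alpha %||% result$config$alpha
  Filter(function(cmp) cmp$p_fwe <= alpha, result$components)
}
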