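#' Degree-preserving rewired null network (Maslov-Sneppen double swaps)
#'
#' Repeats `n_swaps` times: draw two edges (i1, j1), (i2, j2) with four
#' distinct endpoints; if neither (i1, j2) nor (i2, j1) already exists,
#' replace the pair with them.  The degree sequence is preserved exactly
#' and no self-loop or multi-edge is ever created.  Attempts whose
#' endpoints collide or whose replacement edges exist count as a draw but
#' make no change (the standard scheme).
#'
#' @param graph a `binary_graph` or 0/1 adjacency matrix.
#' @param n_swaps number of swap attempts (500 for the 7-node atlas,
#'   10000 for the 90-node atlas in the default analysis).
#' @param seed RNG seed.
#' @return a `binary_graph` with the same degree sequence.
#' @export
rewire_null <- function(graph, n_swaps, seed = 1L) {
  adj <- as_adjacency(graph)
  cost <- if (inherits(graph, "binary_graph")) graph$cost else NA_real_
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  m <- nrow(idx)
  if (m < 2) {
    warning("fewer than 2 edges; returning the graph unchanged")
    return(structure(list(adjacency = adj, cost = cost, n_edges = m),
                     class = "binary_graph"))
  }
  # a complete (or otherwise swap-saturated) graph admits no legal swap
  n <- nrow(adj)
  if (m == n * (n - 1) / 2) {
    warning("graph is complete; no legal swap exists, returning a copy")
    return(structure(list(adjacency = adj, cost = cost, n_edges = m),
                     class = "binary_graph"))
  }
  set.seed(seed)
  ei <- idx[, 1]; ej <- idx[, 2]
  picks <- matrix(sample.int(m, 2 * n_swaps, replace = TRUE), ncol = 2)
  # random orientation of each drawn edge: without it the chain is biased
  # (always pairing the lexicographically smaller endpoints under-samples
  # one of the two legal replacements)
  flips <- matrix(stats::runif(2 * n_swaps) < 0.5, ncol = 2)
  for (s in seq_len(n_swaps)) {
    a <- picks[s, 1]; b <- picks[s, 2]
    i1 <- ei[a]; j1 <- ej[a]; i2 <- ei[b]; j2 <- ej[b]
    if (flips[s, 1]) { tmp <- i1; i1 <- j1; j1 <- tmp }
    if (flips[s, 2]) { tmp <- i2; i2 <- j2; j2 <- tmp }
    if (i1 == i2 || i1 == j2 || j1 == i2 || j1 == j2) next
    if (adj[i1, j2] == 1 || adj[i2, j1] == 1) next
    adj[i1, j1] <- 0; adj[j1, i1] <- 0
    adj[i2, j2] <- 0; adj[j2, i2] <- 0
    adj[i1, j2] <- 1; adj[j2, i1] <- 1
    adj[i2, j1] <- 1; adj[j1, i2] <- 1
    ei[a] <- min(i1, j2); ej[a] <- max(i1, j2)
    ei[b] <- min(i2, j1); ej[b] <- max(i2, j1)
  }
  structure(list(adjacency = adj, cost = cost, n_edges = m),
            class = "binary_graph")
}

#' Small-worldness against a degree-preserving null
#'
#' S = (C / Crand) / (L / Lrand), where C is the mean nodal clustering
#' coefficient and L the characteristic path length of the graph, and
#' Crand, Lrand are the same quantities averaged over `n_null` rewired
#' realisations.  S >> 1 indicates high clustering with near-random path
#' length.  When any part is zero or non-finite, S is NaN (and is later
#' excluded pairwise from AUC integration).
#'
#' @param graph a `binary_graph` or adjacency matrix.
#' @param n_swaps swap attempts per null realisation.
#' @param n_null number of null realisations averaged (default 1, matching
#'   one random network per subject; raise for stability).
#' @param seed RNG seed.
#' @return list with `C`, `L`, `Crand`, `Lrand`, `S`, `disconnected`.
#' @export
small_worldness <- function(graph, n_swaps, n_null = 1, seed = 1L) {
  adj <- as_adjacency(graph)
  C <- clustering_coefficient(adj)
  pl <- characteristic_path_length(adj)
  Cr <- Lr <- numeric(n_null)
  for (k in seq_len(n_null)) {
    nullg <- suppressWarnings(
      rewire_null(adj, n_swaps, seed = derive_seed(seed, k)))
    Cr[k] <- clustering_coefficient(nullg)
    Lr[k] <- characteristic_path_length(nullg)$L
  }
  Crand <- mean(Cr); Lrand <- mean(Lr)
  S <- if (!is.finite(C) || !is.finite(pl$L) || !is.finite(Crand) ||
           !is.finite(Lrand) || Crand == 0 || Lrand == 0 || pl$L == 0) {
    NaN
  } else {
    (C / Crand) / (pl$L / Lrand)
  }
  list(C = C, L = pl$L, Crand = Crand, Lrand = Lrand, S = S,
       disconnected = pl$disconnected)
}
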