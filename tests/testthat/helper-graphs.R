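# Graph constructors and independent brute-force oracles used across the
# graph-measure tests.  The oracles use Floyd-Warshall distances and
# explicit path counting so they share no code path with the package's
# BFS/Brandes implementations.

complete_graph <- function(n) {
  a <- matrix(1L, n, n); diag(a) <- 0L; a
}

star_graph <- function(n) {
  a <- matrix(0L, n, n); a[1, 2:n] <- 1L; a + t(a)
}

path_graph <- function(n) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- 1L
  a + t(a)
}

ring_lattice <- function(n, k) {
  stopifnot(k %% 2 == 0)
  a <- matrix(0L, n, n)
  for (i in seq_len(n)) for (d in seq_len(k / 2)) {
    j <- ((i - 1 + d) %% n) + 1
    a[i, j] <- 1L; a[j, i] <- 1L
  }
  a
}

erdos_renyi <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  a + t(a)
}

# Watts-Strogatz: ring lattice with each edge rewired to a uniform random
# non-duplicate endpoint with probability beta
watts_strogatz <- function(n, k, beta, seed) {
  set.seed(seed)
  a <- ring_lattice(n, k)
  idx <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
  for (e in seq_len(nrow(idx))) {
    if (stats::runif(1) < beta) {
      i <- idx[e, 1]; j <- idx[e, 2]
      cand <- which(a[i, ] == 0)
      cand <- setdiff(cand, i)
      if (length(cand)) {
        jn <- cand[sample.int(length(cand), 1)]
        a[i, j] <- 0L; a[j, i] <- 0L
        a[i, jn] <- 1L; a[jn, i] <- 1L
      }
    }
  }
  a
}

# Floyd-Warshall all-pairs distances
bf_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a > 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

bf_global_efficiency <- function(a) {
  n <- nrow(a)
  d <- bf_distances(a)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

bf_transitivity <- function(a) {
  n <- nrow(a)
  tri <- 0; triples <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i != j && j != k && i != k) {
      if (a[i, j] && a[j, k]) {
        triples <- triples + 1
        if (a[i, k]) tri <- tri + 1
      }
    }
  }
  if (triples == 0) 0 else tri / triples
}

# shortest-path counts via DP on Floyd-Warshall distances
bf_path_counts <- function(a) {
  n <- nrow(a)
  d <- bf_distances(a)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  ord <- order(d[is.finite(d)])
  pairs <- which(is.finite(d), arr.ind = TRUE)
  pairs <- pairs[order(d[pairs]), , drop = FALSE]
  for (r in seq_len(nrow(pairs))) {
    s <- pairs[r, 1]; t <- pairs[r, 2]
    if (s == t) next
    if (d[s, t] == 1) { sigma[s, t] <- 1; next }
    preds <- which(a[, t] > 0 & d[s, ] == d[s, t] - 1)
    sigma[s, t] <- sum(sigma[s, preds])
  }
  list(d = d, sigma = sigma)
}

bf_betweenness <- function(a) {
  n <- nrow(a)
  pc <- bf_path_counts(a)
  d <- pc$d; sigma <- pc$sigma
  bc <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s != t && s != v && t != v && is.finite(d[s, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
        acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
    bc[v] <- acc
  }
  bc / ((n - 1) * (n - 2))
}

bf_assortativity <- function(a) {
  deg <- rowSums(a)
  idx <- which(a > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NaN)
  x <- deg[idx[, 1]]; y <- deg[idx[, 2]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NaN)
  stats::cor(x, y)
}

degree_multiset <- function(g) sort(rowSums(as_adj(g)))
as_adj <- function(g) if (inherits(g, "binary_graph")) g$adjacency else g
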