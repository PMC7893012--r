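# Graph-theoretic measures on binary undirected graphs, computed on dense
# adjacency matrices.  N here is at most 90, so dense matrix algebra and
# per-source BFS are both exact and fast; conventions (ordered-pair
# betweenness fraction, finite-pair path length, NaN for undefined
# assortativity) are fixed below and cross-checked against brute-force and
# igraph oracles in the test suite.

check_adjacency <- function(adj) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  if (any(adj != 0 & adj != 1)) stop("adjacency must be 0/1")
  if (any(diag(adj) != 0)) stop("adjacency has self-loops")
  if (any(adj != t(adj))) stop("adjacency must be symmetric")
  invisible(adj)
}

#' Binary graph from a connectivity matrix by proportional threshold
#'
#' Self-connections are removed, edges ranked by absolute weight, and the
#' strongest `round(cost * E_total)` edges set to 1 (round half away from
#' zero).  Every subject and condition thresholded at the same cost K
#' therefore has exactly the same number of edges.  Ties at the boundary
#' are broken by (i, j) lexicographic order so runs are reproducible.
#'
#' @param conn a `connectivity_matrix` or a plain symmetric matrix.
#' @param cost K, the fraction of possible edges retained, in (0, 1).
#' @return list of class `binary_graph`: `adjacency`, `cost`, `n_edges`.
#' @export
proportional_threshold <- function(conn, cost) {
  m <- if (inherits(conn, "connectivity_matrix")) conn$values else conn
  stopifnot(cost > 0, cost < 1)
  n <- nrow(m)
  idx <- edge_index(n)
  w <- abs(m[idx])
  e_total <- nrow(idx)
  k <- as.integer(round_half_up(cost * e_total))
  if (k < 1) stop("cost ", cost, " retains zero edges")
  # order by |r| descending, ties by (i, j) lexicographic
  ord <- order(-w, idx[, "i"], idx[, "j"])
  keep <- ord[seq_len(k)]
  adj <- matrix(0L, n, n)
  adj[idx[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  structure(list(adjacency = adj, cost = cost, n_edges = k),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d edges (cost %g)\n",
              nrow(x$adjacency), x$n_edges, x$cost))
  invisible(x)
}

as_adjacency <- function(graph) {
  if (inherits(graph, "binary_graph")) graph$adjacency
  else check_adjacency(graph)
}

# all-pairs shortest path lengths by BFS level expansion (unweighted);
# Inf for disconnected pairs
shortest_path_lengths <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[adj > 0] <- 1
  reach <- adj > 0
  diag(reach) <- TRUE
  k <- 1
  repeat {
    new_reach <- (reach %*% adj) > 0 | reach
    newly <- new_reach & !reach
    if (!any(newly)) break
    k <- k + 1
    D[newly] <- k
    reach <- new_reach
  }
  D
}

#' Betweenness centrality (fraction form)
#'
#' For each node v, the sum over ordered pairs (s, t), s != t != v, of the
#' fraction of shortest s-t paths passing through v, normalised by
#' (N-1)(N-2) so values lie in [0, 1].  Disconnected pairs contribute 0.
#' Brandes' accumulation over BFS shortest-path DAGs.
#'
#' @param graph a `binary_graph` or 0/1 adjacency matrix.
#' @return list with `per_node` and `mean`.
#' @export
betweenness <- function(graph) {
  adj <- as_adjacency(graph)
  n <- nrow(adj)
  nbrs <- apply(adj, 1, function(r) which(r > 0), simplify = FALSE)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    order_visited <- integer(0)
    frontier <- s
    while (length(frontier)) {
      order_visited <- c(order_visited, frontier)
      nxt <- integer(0)
      for (v in frontier) {
        for (w in nbrs[[v]]) {
          if (dist[w] < 0) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1L) sigma[w] <- sigma[w] + sigma[v]
        }
      }
      frontier <- unique(nxt)
    }
    delta <- numeric(n)
    for (v in rev(order_visited)) {
      for (w in nbrs[[v]]) {
        if (dist[w] == dist[v] + 1L) {
          delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
        }
      }
      if (v != s) bc[v] <- bc[v] + delta[v]
    }
  }
  per_node <- bc / ((n - 1) * (n - 2))
  list(per_node = per_node, mean = mean(per_node))
}

#' Transitivity (global clustering)
#'
#' 3 x triangles / connected triples; 0 when the graph has no connected
#' triple.
#' @param graph a `binary_graph` or adjacency matrix.
#' @export
transitivity <- function(graph) {
  adj <- as_adjacency(graph)
  deg <- rowSums(adj)
  triples2 <- sum(deg * (deg - 1))          # ordered paths of length 2
  if (triples2 == 0) return(0)
  closed2 <- sum(diag(adj %*% adj %*% adj)) # 6 x triangles
  closed2 / triples2
}

#' Degree assortativity
#'
#' Pearson correlation between the degrees at the two endpoints of each
#' edge, with every edge counted in both orientations.  Undefined (NaN)
#' when endpoint degrees have zero variance (regular graphs).
#' @param graph a `binary_graph` or adjacency matrix.
#' @export
assortativity <- function(graph) {
  adj <- as_adjacency(graph)
  deg <- rowSums(adj)
  idx <- which(adj > 0, arr.ind = TRUE)     # both orientations
  if (nrow(idx) == 0) return(NaN)
  x <- deg[idx[, 1]]; y <- deg[idx[, 2]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NaN)
  stats::cor(x, y)
}

#' Global efficiency
#'
#' Mean over unordered node pairs of the inverse shortest path length,
#' with 1/Inf = 0 for disconnected pairs.
#' @param graph a `binary_graph` or adjacency matrix.
#' @export
global_efficiency <- function(graph) {
  adj <- as_adjacency(graph)
  n <- nrow(adj)
  if (n < 2) return(0)
  D <- shortest_path_lengths(adj)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Mean nodal clustering coefficient
#'
#' Watts-Strogatz clustering: per node, the fraction of neighbour pairs
#' that are themselves connected (0 for degree < 2); averaged over nodes.
#' Distinct from [transitivity()].
#' @param graph a `binary_graph` or adjacency matrix.
#' @export
clustering_coefficient <- function(graph) {
  adj <- as_adjacency(graph)
  deg <- rowSums(adj)
  tri2 <- diag(adj %*% adj %*% adj)         # 2 x triangles at each node
  ci <- ifelse(deg < 2, 0, tri2 / (deg * (deg - 1)))
  mean(ci)
}

#' Characteristic path length
#'
#' Mean shortest path length over connected node pairs (self pairs
#' excluded).  When the graph is disconnected, only finite pairs enter the
#' mean and `disconnected = TRUE` is flagged; NaN if no pair is connected.
#' @param graph a `binary_graph` or adjacency matrix.
#' @return list with `L` and `disconnected`.
#' @export
characteristic_path_length <- function(graph) {
  adj <- as_adjacency(graph)
  D <- shortest_path_lengths(adj)
  off <- D[upper.tri(D)]
  finite <- off[is.finite(off)]
  list(L = if (length(finite)) mean(finite) else NaN,
       disconnected = any(!is.finite(off)))
}
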