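# Independent oracles and graph fixtures used across the suite.
# The oracles deliberately use different algorithms from the package:
# Floyd-Warshall for distances, brute-force 1/d sums for efficiencies,
# and repeated subgraph peeling for core membership.

# random undirected graph as a dense adjacency matrix
rand_adj <- function(n, p) {
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  on <- up[runif(length(up)) < p]
  a[on] <- 1L
  a + t(a)
}

adj_to_graph <- function(a, ...) {
  idx <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  voxgraph::brain_graph_from_edges(nrow(a), idx, ...)
}

graph_to_adj <- function(g) {
  a <- matrix(0L, g$n, g$n)
  e <- voxgraph::graph_edges(g)
  a[cbind(e$i, e$j)] <- 1L
  a + t(a)
}

# Floyd-Warshall all-pairs shortest paths on a dense adjacency
fw_dist <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      nd <- d[i, k] + d[k, ]
      upd <- nd < d[i, ]
      d[i, upd] <- nd[upd]
    }
  }
  d
}

oracle_eglob <- function(a) {
  d <- fw_dist(a)
  n <- nrow(a)
  inv <- 1 / d
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

oracle_eloc <- function(a) {
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub <- a[nb, nb, drop = FALSE]
    d <- fw_dist(sub)
    inv <- 1 / d
    diag(inv) <- 0
    out[i] <- sum(inv) / (k * (k - 1))
  }
  out
}

# core numbers by explicit membership testing: for each k, find the
# maximal subgraph of minimum degree >= k by repeated deletion
oracle_kcore <- function(a) {
  n <- nrow(a)
  core <- integer(n)
  for (k in seq_len(max(rowSums(a)) + 1)) {
    alive <- rep(TRUE, n)
    repeat {
      deg <- rowSums(a[, alive, drop = FALSE])[alive]
      drop_nodes <- which(alive)[deg < k]
      if (!length(drop_nodes)) break
      alive[drop_nodes] <- FALSE
    }
    core[alive] <- k
    if (!any(alive)) break
  }
  core
}

# small named fixtures
graph_path3 <- function() voxgraph::brain_graph_from_edges(3, rbind(c(1, 2), c(2, 3)))
graph_star <- function(n = 5) {
  voxgraph::brain_graph_from_edges(n, cbind(1, 2:n))
}
graph_complete <- function(n) {
  e <- t(utils::combn(n, 2))
  voxgraph::brain_graph_from_edges(n, e)
}
graph_cycle <- function(n) {
  voxgraph::brain_graph_from_edges(n, cbind(seq_len(n), c(2:n, 1)))
}
graph_triangle_pendant <- function() {
  voxgraph::brain_graph_from_edges(4, rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 4)))
}
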