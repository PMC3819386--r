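# Density-matched binary graph construction.
#
# Networks are matched across subjects through S = log(N)/log(K): fixing S
# fixes the mean degree K = N^(1/S) and hence the edge count
# M = round(N * N^(1/S) / 2), so every subject's graph has identical
# density regardless of the shape of its correlation distribution.

#' Pearson correlation matrix over voxel nodes
#'
#' @param series Node-by-time matrix with at least 3 time points.
#' @return Symmetric correlation matrix with unit diagonal.  Zero-variance
#'   nodes yield `NA` rows/columns (excluded from edge ranking downstream)
#'   and are listed in the `"zero_variance"` attribute.
#' @export
pearson_matrix <- function(series) {
  stopifnot(is.matrix(series))
  if (ncol(series) < 3) abort("At least 3 time points are required.")
  s <- apply(series, 1, sd)
  zv <- which(s == 0)
  cm <- suppressWarnings(cor(t(series)))
  diag(cm) <- 1
  structure(cm, zero_variance = zv)
}

#' Density-matched target mean degree
#'
#' Inverts `S = log(N)/log(K)`: `K = N^(1/S)`.
#'
#' @param n Node count (>= 2).
#' @param s Density-matching threshold (> 0).
#' @return Real-valued target mean degree.
#' @examples
#' target_degree(16, 2)      # 4
#' target_degree(30000, 2.5) # ~61.8
#' @export
target_degree <- function(n, s) {
  if (n < 2) abort("`n` must be at least 2.")
  if (s <= 0) abort("`s` must be positive.")
  n^(1 / s)
}

#' Threshold a correlation matrix to a density-matched binary graph
#'
#' Ranks unique node pairs by correlation (descending; ties broken by
#' ascending `(i, j)` node index for determinism) and keeps the top
#' `M = round(N * N^(1/S) / 2)` pairs as edges.  Negative or zero
#' correlations are never eligible: if the M-th ranked pair is not
#' positive, the call errors and suggests increasing S.  `NA` entries
#' (zero-variance nodes) are excluded, leaving those nodes isolated so maps
#' stay voxel-aligned.
#'
#' @param corr Symmetric correlation matrix (e.g. [pearson_matrix()]).
#' @param s_target Density threshold S (> 1).
#' @param node_map Optional tibble (node, x, y, z) carried on the graph for
#'   spatial operations.
#' @return Object of class `brain_graph`.
#' @export
threshold_to_density <- function(corr, s_target, node_map = NULL) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (s_target <= 1) abort("`s_target` must exceed 1.")
  n <- nrow(corr)
  m <- round_half_up(n * target_degree(n, s_target) / 2)
  ut <- which(upper.tri(corr))
  vals <- corr[ut]
  ok <- !is.na(vals)
  ut <- ut[ok]
  vals <- vals[ok]
  if (length(vals) < m) {
    abort("Not enough defined node pairs to supply the edge budget.")
  }
  ii <- ((ut - 1L) %% n) + 1L
  jj <- ((ut - 1L) %/% n) + 1L
  ord <- order(-vals, ii, jj)
  keep <- ord[seq_len(m)]
  cutoff <- vals[keep[m]]
  if (cutoff <= 0) {
    abort(paste0(
      "Fewer than M = ", m, " positive-correlation pairs are available; ",
      "increase S (sparser network) or supply longer series."
    ))
  }
  brain_graph_from_edges(n, cbind(ii[keep], jj[keep]),
                         s_target = s_target, cutoff = cutoff,
                         node_map = node_map)
}

#' Construct a brain graph from an explicit edge list
#'
#' @param n Node count.
#' @param edges Two-column matrix of node pairs (1-based, any order).
#' @param s_target Density target recorded on the graph (optional).
#' @param cutoff Correlation cutoff recorded for audit (optional).
#' @param node_map Optional node-to-voxel tibble.
#' @return Object of class `brain_graph` holding a CSR adjacency
#'   (0-based `ptr`/`idx`), the achieved mean degree and achieved S.
#' @export
brain_graph_from_edges <- function(n, edges, s_target = NA_real_,
                                   cutoff = NA_real_, node_map = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    stopifnot(all(edges >= 1), all(edges <= n),
              all(edges[, 1] != edges[, 2]))
    a <- pmin(edges[, 1], edges[, 2])
    b <- pmax(edges[, 1], edges[, 2])
    dup <- duplicated(cbind(a, b))
    a <- a[!dup]; b <- b[!dup]
  } else {
    a <- integer(0); b <- integer(0)
  }
  from <- c(a, b)
  to <- c(b, a)
  o <- order(from, to)
  deg <- tabulate(from, nbins = n)
  g <- structure(
    list(n = as.integer(n),
         ptr = c(0L, cumsum(deg)),
         idx = to[o] - 1L,
         m = length(a),
         s_target = s_target,
         cutoff = cutoff,
         node_map = node_map),
    class = "brain_graph"
  )
  g$k_bar <- 2 * g$m / n
  g$s_achieved <- if (g$k_bar > 1) log(n) / log(g$k_bar) else NA_real_
  g
}

#' @export
print.brain_graph <- function(x, ...) {
  cat("<brain_graph> ", x$n, " nodes, ", x$m, " edges, mean degree ",
      signif(x$k_bar, 4), if (!is.na(x$s_target))
        paste0(", S target ", x$s_target, " achieved ",
               signif(x$s_achieved, 4)) else "", "\n", sep = "")
  invisible(x)
}

#' Achieved density-matching threshold of a graph
#'
#' @param graph A `brain_graph` with mean degree above 1.
#' @return `log(N)/log(K_bar)`.
#' @export
achieved_S <- function(graph) {
  stopifnot(inherits(graph, "brain_graph"))
  if (graph$k_bar <= 1) abort("Achieved S requires mean degree above 1.")
  log(graph$n) / log(graph$k_bar)
}

#' Edge list of a brain graph
#'
#' @param graph A `brain_graph`.
#' @return Tibble of unique edges `(i, j)` with `i < j`, 1-based.
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "brain_graph"))
  from <- rep(seq_len(graph$n), diff(graph$ptr))
  to <- graph$idx + 1L
  keep <- from < to
  tibble(i = from[keep], j = to[keep])
}

#' @export
glance.brain_graph <- function(x, ...) {
  tibble(n = x$n, edges = x$m, k_bar = x$k_bar,
         s_target = x$s_target, s_achieved = x$s_achieved,
         cutoff = x$cutoff)
}

#' Erdos-Renyi random graph at a target mean degree
#'
#' Draws `round(n * mean_degree / 2)` distinct edges uniformly at random.
#' Used for the density-matching rationale: S approximates the expected
#' path length of an Erdos-Renyi network with the same N and K.
#'
#' @param n Node count.
#' @param mean_degree Target mean degree.
#' @return A `brain_graph`.
#' @export
erdos_renyi_graph <- function(n, mean_degree) {
  m <- round_half_up(n * mean_degree / 2)
  max_m <- n * (n - 1) / 2
  if (m > max_m) abort("Requested mean degree exceeds the complete graph.")
  pick <- sample.int(max_m, m)
  # map linear upper-triangle index (column-major) to (i, j)
  jj <- ceiling((sqrt(8 * pick + 1) + 1) / 2)
  ii <- pick - (jj - 1) * (jj - 2) / 2
  brain_graph_from_edges(n, cbind(ii, jj))
}

#' Mean finite shortest-path length of a graph
#'
#' Average BFS distance over all ordered node pairs with a finite path
#' (pairs in different components are excluded rather than imputed).
#'
#' @param graph A `brain_graph`.
#' @return Mean finite geodesic distance.
#' @export
mean_path_length <- function(graph) {
  stopifnot(inherits(graph, "brain_graph"))
  s <- cpp_distance_summary(graph$ptr, graph$idx, graph$n)
  tot <- sum(s$sum)
  cnt <- sum(s$count)
  if (cnt == 0) return(NA_real_)
  tot / cnt
}
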