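# Nodal graph metrics on binary undirected graphs: degree, global
# efficiency, local efficiency, core number.  Distances are BFS distances
# (identical to Dijkstra on a unit-weight graph); unreachable pairs
# contribute 0 to the efficiencies, which is precisely why efficiency is
# preferred over path length for graphs with isolated nodes.

#' Shortest-path distances from one node
#'
#' @param graph A `brain_graph`.
#' @param source Source node (1-based).
#' @return Numeric vector of geodesic edge counts; unreachable nodes are
#'   `Inf`, the source itself 0.
#' @export
shortest_path_lengths <- function(graph, source) {
  stopifnot(inherits(graph, "brain_graph"))
  if (source < 1 || source > graph$n) abort("`source` is out of range.")
  d <- cpp_bfs_distances(graph$ptr, graph$idx, graph$n, source - 1L)
  d[d < 0] <- Inf
  as.numeric(d)
}

#' Nodal degree
#'
#' @param graph A `brain_graph`.
#' @return Integer vector: number of edges incident to each node.
#' @export
nodal_degree <- function(graph) {
  stopifnot(inherits(graph, "brain_graph"))
  as.integer(diff(graph$ptr))
}

#' Nodal global efficiency
#'
#' `Eglob(i) = (1/(N-1)) * sum_{j != i} 1/d_ij` with `1/Inf = 0`; values
#' lie in `[0, 1]` and reach 1 only for a node adjacent to every other.
#'
#' @param graph A `brain_graph` with at least 2 nodes.
#' @return Numeric vector of per-node global efficiency.
#' @export
nodal_global_efficiency <- function(graph) {
  stopifnot(inherits(graph, "brain_graph"))
  if (graph$n < 2) abort("Global efficiency requires at least 2 nodes.")
  cpp_eglob(graph$ptr, graph$idx, graph$n)
}

#' Nodal local efficiency
#'
#' Global efficiency computed inside the subgraph induced by each node's
#' direct neighbors, the node itself excluded: the mean of `1/d` over
#' ordered neighbor pairs, with distances measured within that subgraph.
#' Nodes of degree below 2 score 0.
#'
#' @param graph A `brain_graph` with at least 2 nodes.
#' @return Numeric vector of per-node local efficiency.
#' @export
nodal_local_efficiency <- function(graph) {
  stopifnot(inherits(graph, "brain_graph"))
  if (graph$n < 2) abort("Local efficiency requires at least 2 nodes.")
  cpp_eloc(graph$ptr, graph$idx, graph$n)
}

#' Nodal core numbers (k-core decomposition)
#'
#' Iteratively deletes nodes of degree below k for k = 1, 2, ...; a node's
#' core number is the largest k at which it survives the peeling.
#'
#' @param graph A `brain_graph`.
#' @return Integer vector of per-node core numbers.
#' @export
kcore_numbers <- function(graph) {
  stopifnot(inherits(graph, "brain_graph"))
  as.integer(cpp_kcore(graph$ptr, graph$idx, graph$n))
}

#' All four nodal metric maps for one subject graph
#'
#' Computes degree, global efficiency, local efficiency and core number and
#' returns them in long format aligned to the graph's node index (and hence
#' to the gray-matter mask).  Isolated nodes score 0 on every metric.
#'
#' @param graph A `brain_graph`.
#' @param subject Subject identifier stored in the output.
#' @param s S level stored in the output (defaults to the graph's target).
#' @return Tibble with columns `subject`, `s`, `metric`
#'   (degree/eglob/eloc/kcore), `node`, `value`.
#' @export
subject_metric_maps <- function(graph, subject = NA_character_, s = NULL) {
  stopifnot(inherits(graph, "brain_graph"))
  s <- s %||% graph$s_target
  vals <- list(
    degree = as.numeric(nodal_degree(graph)),
    eglob = nodal_global_efficiency(graph),
    eloc = nodal_local_efficiency(graph),
    kcore = as.numeric(kcore_numbers(graph))
  )
  purrr::imap_dfr(vals, function(v, nm) {
    tibble(subject = subject, s = s, metric = nm,
           node = seq_len(graph$n), value = v)
  })
}
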