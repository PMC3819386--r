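# Cross-subject topology: top-fraction masks, overlap maps, group
# difference maps, metric-conjunction ROIs, and seed-connectivity QC.

#' Top-fraction node mask of a metric map
#'
#' Selects the `round(fraction * N)` nodes with the highest metric values.
#' Ties at the cut are broken by ascending node index, so the selection is
#' a deterministic function of the map.  An all-equal map still returns the
#' first `round(fraction * N)` indices, with a degenerate-map warning.
#'
#' @param values Per-node numeric metric values.
#' @param fraction Fraction of nodes to select, in (0, 1); default 0.20.
#' @return Logical vector marking selected nodes.
#' @export
top_fraction_mask <- function(values, fraction = 0.20) {
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1).")
  n <- length(values)
  k <- round_half_up(fraction * n)
  if (k < 1) abort("The requested fraction selects no nodes.")
  if (length(unique(values)) == 1L) {
    warn("Degenerate metric map (all values equal); selecting the first nodes.")
  }
  ord <- order(-values, seq_len(n))
  out <- logical(n)
  out[ord[seq_len(k)]] <- TRUE
  out
}

#' Cross-subject overlap map
#'
#' Per node, the percentage of subjects whose top-fraction mask includes
#' that node.  With `n` subjects the values live on the lattice
#' `{0, 100/n, 200/n, ..., 100}`.
#'
#' @param masks A list of equal-length logical vectors (one per subject) or
#'   a subjects-by-node logical matrix.
#' @return Tibble with columns `node`, `overlap` (percent), and the subject
#'   count as attribute `"n_subjects"`.
#' @export
overlap_map <- function(masks) {
  if (is.list(masks)) {
    len <- vapply(masks, length, integer(1))
    if (length(unique(len)) != 1) abort("All masks must share a length.")
    masks <- do.call(rbind, lapply(masks, as.logical))
  }
  stopifnot(is.matrix(masks), nrow(masks) >= 1)
  pct <- 100 * colMeans(masks)
  structure(tibble(node = seq_len(ncol(masks)), overlap = pct),
            n_subjects = nrow(masks))
}

#' Display-threshold an overlap map
#'
#' Values below the cutoff are zeroed; values at or above pass through.
#'
#' @param map Tibble with columns `node`, `overlap` (see [overlap_map()]).
#' @param cutoff Overlap percentage cutoff in `[0, 100]`; default 50.
#' @return Tibble of the same shape.
#' @export
threshold_overlap <- function(map, cutoff = 50) {
  stopifnot(all(c("node", "overlap") %in% names(map)))
  if (cutoff < 0 || cutoff > 100) abort("`cutoff` must be in [0, 100].")
  mutate(map, overlap = ifelse(.data$overlap >= cutoff, .data$overlap, 0))
}

#' Between-group overlap difference map
#'
#' Signed per-node difference `a - b` in overlap percentage, with
#' directional flags where the difference strictly exceeds the criterion.
#'
#' @param a,b Overlap maps ([overlap_map()]) over aligned nodes.
#' @param criterion Percentage-point criterion (strict `>`); default 25.
#' @return Tibble with columns `node`, `diff`, `flag_a_gt_b`, `flag_b_gt_a`.
#' @export
difference_map <- function(a, b, criterion = 25) {
  stopifnot(all(c("node", "overlap") %in% names(a)),
            all(c("node", "overlap") %in% names(b)))
  if (criterion <= 0 || criterion >= 100) {
    abort("`criterion` must be in (0, 100).")
  }
  if (nrow(a) != nrow(b) || any(a$node != b$node)) {
    abort("Overlap maps are not aligned on the same nodes.")
  }
  d <- a$overlap - b$overlap
  tibble(node = a$node, diff = d,
         flag_a_gt_b = d > criterion, flag_b_gt_a = -d > criterion)
}

# connected components of a voxel set under 26-connectivity
components_26 <- function(nodes, node_map) {
  co <- node_map[match(nodes, node_map$node), c("x", "y", "z")]
  key <- function(x, y, z) paste(x, y, z, sep = ",")
  lookup <- setNames(seq_along(nodes), key(co$x, co$y, co$z))
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offsets <- offsets[!(offsets$dx == 0 & offsets$dy == 0 & offsets$dz == 0), ]
  comp <- integer(length(nodes))
  cur <- 0L
  for (i in seq_along(nodes)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb_keys <- key(co$x[v] + offsets$dx, co$y[v] + offsets$dy,
                     co$z[v] + offsets$dz)
      hits <- lookup[nb_keys]
      hits <- hits[!is.na(hits)]
      new <- hits[comp[hits] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' Metric-conjunction regions of interest
#'
#' Intersects the directional flags of several difference maps (typically
#' degree, global efficiency and core number at one S level): a node enters
#' the conjunction only if it is flagged in the same direction in every
#' map.  Conjunction nodes are then grouped into spatially contiguous ROIs
#' under 26-connectivity, and ROIs below the minimum size are dropped.  An
#' empty conjunction yields an empty ROI set with a warning, not an error.
#'
#' @param diffs List of difference maps ([difference_map()]) over aligned
#'   nodes.
#' @param node_map Tibble (node, x, y, z) giving voxel coordinates.
#' @param min_size Minimum ROI size in voxels (default 2).
#' @param labels Direction labels for `a > b` and `b > a` flags.
#' @return Tibble of class `vg_roiset` with columns `roi`, `direction`,
#'   `node`, `x`, `y`, `z`.
#' @export
conjunction_rois <- function(diffs, node_map, min_size = 2,
                             labels = c("a>b", "b>a")) {
  stopifnot(is.list(diffs), length(diffs) >= 1)
  nodes <- diffs[[1]]$node
  for (d in diffs) {
    if (nrow(d) != length(nodes) || any(d$node != nodes)) {
      abort("Difference maps are not aligned on the same nodes.")
    }
  }
  flag_ab <- Reduce(`&`, lapply(diffs, function(d) d$flag_a_gt_b))
  flag_ba <- Reduce(`&`, lapply(diffs, function(d) d$flag_b_gt_a))
  build_dir <- function(flag, label, offset) {
    sel <- nodes[flag]
    if (!length(sel)) return(NULL)
    comp <- components_26(sel, node_map)
    keep_comp <- as.integer(names(table(comp)))[table(comp) >= min_size]
    sel <- sel[comp %in% keep_comp]
    comp <- comp[comp %in% keep_comp]
    if (!length(sel)) return(NULL)
    comp <- as.integer(factor(comp))
    co <- node_map[match(sel, node_map$node), c("x", "y", "z")]
    tibble(roi = paste0(label, "_", comp + offset), direction = label,
           node = sel, x = co$x, y = co$y, z = co$z)
  }
  out <- bind_rows(build_dir(flag_ab, labels[1], 0L),
                   build_dir(flag_ba, labels[2], 0L))
  if (!nrow(out)) {
    warn("Empty conjunction: no node is flagged in the same direction in all maps.")
    out <- tibble(roi = character(), direction = character(),
                  node = integer(), x = integer(), y = integer(),
                  z = integer())
  }
  class(out) <- c("vg_roiset", class(out))
  out
}

#' Mean metric value over an ROI
#'
#' @param values Per-node metric values.
#' @param nodes Node indices of the ROI (non-empty).
#' @return Arithmetic mean of the metric over the ROI.
#' @export
roi_mean_metric <- function(values, nodes) {
  if (!length(nodes)) abort("The ROI is empty.")
  if (any(nodes < 1 | nodes > length(values))) {
    abort("ROI nodes are out of range.")
  }
  mean(values[nodes])
}

#' Subject-by-ROI table of mean metric values
#'
#' Averages one metric over each ROI for every subject, producing the long
#' table consumed by the MANOVA / repeated-measures / regression
#' operations.
#'
#' @param metric_maps Long tibble from [subject_metric_maps()] rows
#'   (columns subject, s, metric, node, value), possibly many subjects.
#' @param rois ROI set from [conjunction_rois()].
#' @param metric Metric name to extract.
#' @param s S level to extract (default: all present, kept as a column).
#' @return Tibble with columns `subject`, `s`, `metric`, `roi`,
#'   `direction`, `value`.
#' @export
roi_metric_table <- function(metric_maps, rois, metric, s = NULL) {
  stopifnot(all(c("subject", "s", "metric", "node", "value") %in%
                  names(metric_maps)))
  mm <- filter(metric_maps, .data$metric == !!metric)
  if (!is.null(s)) mm <- filter(mm, .data$s == !!s)
  if (!nrow(mm)) abort("No metric rows match the requested metric/S.")
  rois |>
    select("roi", "direction", "node") |>
    left_join(mm, by = "node", relationship = "many-to-many") |>
    group_by(.data$subject, .data$s, .data$metric, .data$roi,
             .data$direction) |>
    summarise(value = mean(.data$value), .groups = "drop")
}

#' Seed-based connectivity z map
#'
#' Correlates the mean time series of a seed ROI with every node, Fisher-z
#' transforms the correlations and scales by `sqrt(T - 3)` (the normal
#' approximation to the correlation null), zeroing nodes below the height
#' threshold.  Seed-internal nodes are reported but flagged; degenerate
#' correlations (|r| = 1, e.g. a single-voxel seed with itself) are capped
#' at `|z| = atanh(1 - 1e-7) * sqrt(T - 3)` and noted in the
#' `"z_cap"` attribute.
#'
#' @param series Node-by-time matrix with at least 10 time points.
#' @param seed_nodes Node indices of the seed ROI.
#' @param z_cutoff Height threshold; default 2.33.
#' @return Tibble with columns `node`, `r`, `z_raw`, `z` (0 where `|z_raw|`
#'   is below the cutoff) and `in_seed`.
#' @export
seed_connectivity <- function(series, seed_nodes, z_cutoff = 2.33) {
  stopifnot(is.matrix(series))
  t_len <- ncol(series)
  if (t_len < 10) abort("At least 10 time points are required.")
  if (!length(seed_nodes) || any(seed_nodes < 1 | seed_nodes > nrow(series))) {
    abort("`seed_nodes` must be valid node indices.")
  }
  seed_ts <- colMeans(series[seed_nodes, , drop = FALSE])
  r <- suppressWarnings(as.numeric(cor(seed_ts, t(series))))
  r_cap <- 1 - 1e-7
  z <- atanh(pmin(pmax(r, -r_cap), r_cap)) * sqrt(t_len - 3)
  z[is.na(z)] <- 0
  z_thr <- ifelse(abs(z) >= z_cutoff, z, 0)
  structure(
    tibble(node = seq_len(nrow(series)), r = r, z_raw = z, z = z_thr,
           in_seed = seq_len(nrow(series)) %in% seed_nodes),
    z_cap = atanh(r_cap) * sqrt(t_len - 3)
  )
}
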