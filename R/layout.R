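#' Modular community layout on a voxel grid
#'
#' Tiles a 3D voxel grid into equally sized rectangular modules and assigns
#' community roles emulating large-scale functional brain systems: one
#' DMN-like module (a cortical association community whose within-module
#' coupling is reduced in the old group by default), one SAL-like module
#' (a subcortical/limbic community carrying the designated hub nodes), one
#' FP-like module, and two tiers of background modules - a "high" tier of
#' strongly coherent modules and a weakly coherent "sea".
#'
#' The high tier is sized so that the planted communities plus the high
#' tier just fill the default top-20% of nodes: membership of the top
#' fraction is then essentially deterministic for background voxels, which
#' keeps spurious between-group overlap differences rare.  The first
#' high-tier module also serves as the coupling target of the hub nodes
#' (hub integration reaches into a coherent, well-connected community).
#'
#' @param grid_dims Integer vector of 3 voxel-grid dimensions.
#' @param block_dims Integer vector of 3 module-tile dimensions; must divide
#'   `grid_dims` exactly.
#' @param rho_high,rho_sea Within-module correlations of the two background
#'   tiers.
#' @param top_fraction Top fraction the tier sizing targets (default 0.20).
#' @param n_hubs Number of hub nodes inside the SAL-like module (defaults to
#'   the whole module).
#' @return An object of class `community_layout`: a list with `node_map`
#'   (tibble: node, x, y, z, module, community, is_hub), `modules` (tibble:
#'   module, community, tier, rho_background), `grid_dims`, plus the ids of
#'   the special modules.
#' @export
community_layout <- function(grid_dims = c(12, 12, 12),
                             block_dims = c(4, 4, 4),
                             rho_high = 0.34, rho_sea = 0.16,
                             top_fraction = 0.20,
                             n_hubs = NULL) {
  stopifnot(length(grid_dims) == 3, length(block_dims) == 3,
            all(grid_dims >= 1), all(block_dims >= 1))
  if (any(grid_dims %% block_dims != 0)) {
    abort("`block_dims` must divide `grid_dims` exactly.")
  }
  nb <- grid_dims %/% block_dims
  n_modules <- prod(nb)
  if (n_modules < 6) {
    abort("The grid must tile into at least 6 modules to host all communities.")
  }
  coords <- expand.grid(x = seq_len(grid_dims[1]),
                        y = seq_len(grid_dims[2]),
                        z = seq_len(grid_dims[3]))  # x fastest: raster order
  module <- 1L +
    (coords$x - 1L) %/% block_dims[1] +
    nb[1] * ((coords$y - 1L) %/% block_dims[2]) +
    nb[1] * nb[2] * ((coords$z - 1L) %/% block_dims[3])

  dmn_module <- 1L
  sal_module <- as.integer(n_modules)
  fp_module <- as.integer(ceiling(n_modules / 2))
  bg_modules <- setdiff(seq_len(n_modules),
                        c(dmn_module, sal_module, fp_module))
  msize <- prod(block_dims)
  n_nodes <- nrow(coords)
  # high tier fills the top fraction together with one planted community
  n_high <- max(1, min(length(bg_modules) - 1,
                       floor((top_fraction * n_nodes - msize) / msize)))
  high_modules <- bg_modules[seq_len(n_high)]

  modules <- tibble(
    module = seq_len(n_modules),
    community = "background",
    tier = "sea",
    rho_background = NA_real_
  )
  modules$community[dmn_module] <- "dmn"
  modules$community[sal_module] <- "sal"
  modules$community[fp_module] <- "fp"
  modules$tier[c(dmn_module, sal_module, fp_module)] <- NA_character_
  modules$tier[high_modules] <- "high"
  modules$rho_background[bg_modules] <-
    ifelse(bg_modules %in% high_modules, rho_high, rho_sea)

  node_map <- tibble(
    node = seq_len(nrow(coords)),
    x = as.integer(coords$x), y = as.integer(coords$y),
    z = as.integer(coords$z),
    module = as.integer(module)
  )
  node_map$community <- modules$community[node_map$module]

  sal_nodes <- node_map$node[node_map$community == "sal"]
  if (is.null(n_hubs)) n_hubs <- length(sal_nodes)
  if (n_hubs < 1 || n_hubs > length(sal_nodes)) {
    abort("`n_hubs` must be between 1 and the SAL-like module size.")
  }
  hub_nodes <- sal_nodes[seq_len(n_hubs)]  # contiguous raster prefix
  node_map$is_hub <- node_map$node %in% hub_nodes

  structure(
    list(
      node_map = node_map,
      modules = modules,
      grid_dims = as.integer(grid_dims),
      block_dims = as.integer(block_dims),
      dmn_module = dmn_module,
      sal_module = sal_module,
      fp_module = fp_module,
      high_modules = high_modules,
      hub_target_module = high_modules[1],
      hub_nodes = hub_nodes
    ),
    class = "community_layout"
  )
}

#' @export
print.community_layout <- function(x, ...) {
  cat("<community_layout> ", paste(x$grid_dims, collapse = "x"),
      " grid, ", nrow(x$node_map), " voxels, ",
      nrow(x$modules), " modules (",
      sum(x$modules$community == "background"), " background), ",
      length(x$hub_nodes), " hub nodes\n", sep = "")
  invisible(x)
}

#' Planted group effects and behavioral couplings
#'
#' Parameterizes the group-specific correlation structure of the synthetic
#' cohort.  Within-community correlations are the squared loadings on the
#' community factor; `hub_boost_*` is the squared loading of hub nodes onto
#' the factor of the first high-tier background module, producing
#' hub-to-target correlations of `sqrt(boost * rho_high)` without altering
#' the target module itself.  `dmn_bridge_corr` pairs every DMN-like node
#' with a distinct sea-tier voxel at that correlation in *both* groups, so
#' the DMN-like community stays connected to the rest of the network
#' without introducing a group difference of its own.
#'
#' Defaults plant the two topology effects the analysis is designed to
#' recover: loss of DMN-like within-module integration in the old group and
#' a gain of SAL-like hub integration (coherence plus cross-module
#' coupling) in the old group, sized so that per-voxel top-20% overlap gaps
#' exceed 40 percentage points at the default cohort size.
#'
#' @param within_young,within_old Named vectors of within-community
#'   correlations for `dmn`, `fp`, `sal`.
#' @param dmn_bridge_corr Correlation of each DMN-like node with its
#'   dedicated sea-tier bridge partner (both groups).
#' @param hub_boost_young,hub_boost_old Squared loading of hub nodes on the
#'   hub-target (first high-tier) module factor.
#' @param long_range_corr Correlation of matched long-range voxel pairs (a
#'   sparse backbone keeping the graph connected); pairs are drawn once per
#'   cohort among non-DMN, non-SAL voxels.
#' @param subject_sd Between-subject SD of the varying within-community
#'   correlations (DMN-like and SAL-like); the standard-normal subject
#'   latents behind this variation also drive the behavioral couplings.
#' @param swls Coupling of SWLS (old group) to the SAL integration latent:
#'   list with `target_r`, `mean`, `sd`.
#' @param rt Coupling of single-task RT to the DMN integration latent: list
#'   with `beta` (standardized), `young_mean`, `old_mean`, `sd` (ms).
#' @param motion Group lognormal moments (mm) of the mean relative
#'   displacement covariate.
#' @param global_amp Amplitude of the shared global signal component.
#' @param motion_gain Amplitude of motion-coupled noise per 0.1 mm of the
#'   subject's motion covariate.
#' @param task_bump If `TRUE`, adds a residual low-frequency (0.025 Hz)
#'   task-like oscillation to the FP-like module for PSD QC exercises.
#' @return Object of class `effect_spec` (a validated list).
#' @export
effect_spec <- function(within_young = c(dmn = 0.42, fp = 0.16, sal = 0.22),
                        within_old = c(dmn = 0.15, fp = 0.16, sal = 0.38),
                        dmn_bridge_corr = 0.45,
                        hub_boost_young = 0,
                        hub_boost_old = 0.49,
                        long_range_corr = 0.32,
                        subject_sd = 0.04,
                        swls = list(target_r = 0.5, mean = 26.2, sd = 5.5),
                        rt = list(beta = -0.4, young_mean = 600,
                                  old_mean = 800, sd = 100),
                        motion = list(young_mean = 0.0975, young_sd = 0.03,
                                      old_mean = 0.0902, old_sd = 0.01),
                        global_amp = 0.25,
                        motion_gain = 0.3,
                        task_bump = FALSE) {
  req <- c("dmn", "fp", "sal")
  if (!all(req %in% names(within_young)) || !all(req %in% names(within_old))) {
    abort("`within_young` and `within_old` must name dmn, fp and sal.")
  }
  cors <- c(within_young, within_old, long_range_corr, dmn_bridge_corr)
  if (any(cors <= -1) || any(cors >= 1)) {
    abort("Correlations must lie in (-1, 1).")
  }
  if (abs(swls$target_r) >= 1 || abs(rt$beta) >= 1) {
    abort("Behavioral coupling strengths must lie in (-1, 1).")
  }
  structure(
    list(within_young = within_young, within_old = within_old,
         dmn_bridge_corr = dmn_bridge_corr,
         hub_boost_young = hub_boost_young, hub_boost_old = hub_boost_old,
         long_range_corr = long_range_corr, subject_sd = subject_sd,
         swls = swls, rt = rt, motion = motion,
         global_amp = global_amp, motion_gain = motion_gain,
         task_bump = task_bump),
    class = "effect_spec"
  )
}

#' Specification of a synthetic cohort
#'
#' Bundles cohort sizes, acquisition geometry (grid, run lengths, sampling
#' interval), the community layout, the planted effects, the noise level and
#' the seed into a single validated object consumed by [generate_cohort()].
#'
#' @param n_young,n_old Subjects per group.
#' @param grid_dims,block_dims Passed to [community_layout()] when `layout`
#'   is `NULL`.
#' @param run_lengths Time points per functional run.
#' @param tr Sampling interval in seconds.
#' @param layout A [community_layout()]; built from the grid arguments when
#'   omitted.
#' @param effects An [effect_spec()].
#' @param noise_sd Multiplier on the node-level residual noise SD; 1 yields
#'   unit-variance nodes and exact population correlation targets.
#' @param seed Integer seed; a fixed seed reproduces the cohort bit for bit.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_young = 15, n_old = 15,
                        grid_dims = c(12, 12, 12), block_dims = c(4, 4, 4),
                        run_lengths = c(150, 220, 180), tr = 1.5,
                        layout = NULL, effects = effect_spec(),
                        noise_sd = 1, seed = 1L) {
  if (n_young < 1 || n_old < 1) abort("Group sizes must be positive.")
  if (!length(run_lengths) || any(run_lengths < 8)) {
    abort("`run_lengths` must be non-empty with at least 8 time points each.")
  }
  if (tr <= 0) abort("`tr` must be positive.")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (is.null(layout)) layout <- community_layout(grid_dims, block_dims)
  if (!inherits(layout, "community_layout")) {
    abort("`layout` must be a community_layout object.")
  }
  if (!inherits(effects, "effect_spec")) {
    abort("`effects` must be an effect_spec object.")
  }
  structure(
    list(n_young = as.integer(n_young), n_old = as.integer(n_old),
         run_lengths = as.integer(run_lengths), tr = tr,
         layout = layout, effects = effects,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$n_young, " young + ", x$n_old, " old subjects, ",
      nrow(x$layout$node_map), " voxels, runs ",
      paste(x$run_lengths, collapse = "/"), " @ TR=", x$tr,
      " s, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
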