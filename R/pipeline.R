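# End-to-end pipeline: simulate -> preprocess -> network/metrics ->
# group maps -> stats -> report.  Every stage writes its outputs under the
# configured output directory together with a sentinel recording the stage
# hash (stage parameters plus the upstream hash); a rerun with an
# unchanged hash skips the stage, so changing e.g. only the S levels
# re-executes the network stage onward while the simulation cache is kept.
# All randomness flows from the single cohort seed.

#' Pipeline configuration
#'
#' @param out_dir Output directory (created on demand).
#' @param cohort A [cohort_spec()] describing the input cohort.
#' @param s_levels Density thresholds to analyze (default 2.5 and 3.0).
#' @param top_fraction Top fraction for overlap maps (default 0.20).
#' @param overlap_cutoff Display threshold for overlap maps (default 50).
#' @param diff_criterion Group-difference criterion in percentage points
#'   (default 25).
#' @param lo_hz,hi_hz Band-pass limits in Hz.
#' @param min_roi_size Minimum conjunction-ROI size in voxels.
#' @param make_figures Write PNG figures in the report stage.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, cohort = cohort_spec(),
                            s_levels = c(2.5, 3.0), top_fraction = 0.20,
                            overlap_cutoff = 50, diff_criterion = 25,
                            lo_hz = 0.008, hi_hz = 0.08,
                            min_roi_size = 2, make_figures = FALSE) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (any(s_levels <= 1)) abort("S levels must exceed 1.")
  if (top_fraction <= 0 || top_fraction >= 1) {
    abort("`top_fraction` must be in (0, 1).")
  }
  if (overlap_cutoff < 0 || overlap_cutoff > 100) {
    abort("`overlap_cutoff` must be in [0, 100].")
  }
  if (diff_criterion <= 0 || diff_criterion >= 100) {
    abort("`diff_criterion` must be in (0, 100).")
  }
  structure(
    list(out_dir = out_dir, cohort = cohort, s_levels = s_levels,
         top_fraction = top_fraction, overlap_cutoff = overlap_cutoff,
         diff_criterion = diff_criterion, lo_hz = lo_hz, hi_hz = hi_hz,
         min_roi_size = min_roi_size, make_figures = make_figures),
    class = "pipeline_config"
  )
}

config_fingerprint <- function(config) {
  co <- config$cohort
  list(cohort = list(n_young = co$n_young, n_old = co$n_old,
                     run_lengths = co$run_lengths, tr = co$tr,
                     grid = co$layout$grid_dims, block = co$layout$block_dims,
                     effects = unclass(co$effects), noise_sd = co$noise_sd,
                     seed = co$seed),
       s_levels = config$s_levels, top_fraction = config$top_fraction,
       overlap_cutoff = config$overlap_cutoff,
       diff_criterion = config$diff_criterion,
       lo_hz = config$lo_hz, hi_hz = config$hi_hz,
       min_roi_size = config$min_roi_size)
}

stage_dir <- function(config, stage) file.path(config$out_dir, stage)

stage_current <- function(config, stage, hash) {
  sentinel <- file.path(stage_dir(config, stage), "_stage.json")
  file.exists(sentinel) &&
    identical(jsonlite::read_json(sentinel)$hash, hash)
}

stage_finish <- function(config, stage, hash) {
  dir <- stage_dir(config, stage)
  jsonlite::write_json(list(hash = hash), file.path(dir, "_stage.json"),
                       auto_unbox = TRUE)
  log_file <- file.path(config$out_dir, "provenance.jsonl")
  rec <- jsonlite::toJSON(list(
    stage = stage, hash = hash,
    version = tryCatch(as.character(utils::packageVersion("voxgraph")),
                       error = function(e) "unknown"),
    seed = config$cohort$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")
  ), auto_unbox = TRUE)
  cat(rec, "\n", sep = "", file = log_file, append = TRUE)
}

run_stage <- function(config, stage, hash, fun) {
  dir <- stage_dir(config, stage)
  if (stage_current(config, stage, hash)) {
    message("[", stage, "] cached, skipping")
    return(invisible(FALSE))
  }
  message("[", stage, "] running")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    fun(dir)
    TRUE
  }, error = function(e) {
    abort(paste0("Stage '", stage, "' failed (hash ", substr(hash, 1, 8),
                 "): ", conditionMessage(e)))
  })
  stage_finish(config, stage, hash)
  invisible(ok)
}

#' Run the full analysis pipeline
#'
#' Executes simulate, preprocess, network/metrics, group maps, stats and
#' report in order, caching each stage by its parameter hash.  Identical
#' configuration and seed reproduce identical result tables.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- config_fingerprint(config)
  co <- config$cohort
  lay <- co$layout

  h_sim <- rlang::hash(list("simulate", fp$cohort))
  run_stage(config, "simulate", h_sim, function(dir) {
    cohort <- generate_cohort(co)
    saveRDS(cohort, file.path(dir, "cohort.rds"))
    behavior <- cohort |>
      select("subject", "group", "sex", "motion", "single_task_rt",
             "local_cost", "global_cost", "spwm_rt", "spwm_accuracy",
             "wm_composite", "swls_total")
    readr::write_tsv(behavior, file.path(dir, "behavior.tsv"))
  })

  h_pre <- rlang::hash(list("preprocess", h_sim, config$lo_hz, config$hi_hz))
  run_stage(config, "preprocess", h_pre, function(dir) {
    cohort <- readRDS(file.path(stage_dir(config, "simulate"), "cohort.rds"))
    clean <- purrr::map2(cohort$runs, cohort$nuisance, function(r, d) {
      preprocess_subject(r, d, config$lo_hz, config$hi_hz, co$tr)
    })
    names(clean) <- cohort$subject
    saveRDS(clean, file.path(dir, "clean.rds"))
    psd <- purrr::imap_dfr(clean, function(x, nm) {
      voxelwise_psd(unclass(x), tr = co$tr) |>
        group_by(.data$band, .data$lo_hz, .data$hi_hz) |>
        summarise(power = mean(.data$power), .groups = "drop") |>
        mutate(subject = nm)
    })
    readr::write_tsv(psd, file.path(dir, "psd_qc.tsv"))
  })

  h_net <- rlang::hash(list("network", h_pre, config$s_levels))
  run_stage(config, "network", h_net, function(dir) {
    clean <- readRDS(file.path(stage_dir(config, "preprocess"), "clean.rds"))
    maps <- list()
    summaries <- list()
    for (nm in names(clean)) {
      cm <- pearson_matrix(unclass(clean[[nm]]))
      for (s in config$s_levels) {
        g <- threshold_to_density(cm, s, node_map = lay$node_map)
        maps[[paste(nm, s)]] <- subject_metric_maps(g, subject = nm, s = s)
        summaries[[paste(nm, s)]] <- mutate(glance(g), subject = nm)
      }
    }
    saveRDS(bind_rows(maps), file.path(dir, "metric_maps.rds"))
    readr::write_tsv(bind_rows(summaries),
                     file.path(dir, "graph_summary.tsv"))
  })

  h_maps <- rlang::hash(list("groupmaps", h_net, config$top_fraction,
                             config$overlap_cutoff, config$diff_criterion,
                             config$min_roi_size))
  run_stage(config, "groupmaps", h_maps, function(dir) {
    cohort <- readRDS(file.path(stage_dir(config, "simulate"), "cohort.rds"))
    metric_maps <- readRDS(file.path(stage_dir(config, "network"),
                                     "metric_maps.rds"))
    grp <- setNames(as.character(cohort$group), cohort$subject)
    res <- group_topology_maps(
      metric_maps, grp, node_map = lay$node_map,
      top_fraction = config$top_fraction,
      diff_criterion = config$diff_criterion,
      min_roi_size = config$min_roi_size
    )
    readr::write_tsv(res$overlap, file.path(dir, "overlap.tsv"))
    readr::write_tsv(res$difference, file.path(dir, "difference.tsv"))
    readr::write_tsv(res$rois, file.path(dir, "rois.tsv"))
    saveRDS(res, file.path(dir, "groupmaps.rds"))
  })

  h_stats <- rlang::hash(list("stats", h_maps))
  run_stage(config, "stats", h_stats, function(dir) {
    cohort <- readRDS(file.path(stage_dir(config, "simulate"), "cohort.rds"))
    metric_maps <- readRDS(file.path(stage_dir(config, "network"),
                                     "metric_maps.rds"))
    gm <- readRDS(file.path(stage_dir(config, "groupmaps"), "groupmaps.rds"))
    out <- pipeline_stats(cohort, metric_maps, gm$rois, config$s_levels)
    for (nm in names(out)) {
      readr::write_tsv(out[[nm]], file.path(dir, paste0(nm, ".tsv")))
    }
  })

  h_rep <- rlang::hash(list("report", h_stats, config$make_figures))
  run_stage(config, "report", h_rep, function(dir) {
    export_report(config$out_dir, report_dir = dir,
                  make_figures = config$make_figures)
  })

  invisible(config$out_dir)
}

#' Group overlap, difference and conjunction-ROI maps
#'
#' Builds, for every metric and S level, the per-group top-fraction overlap
#' maps, the young-minus-old difference maps with the criterion flags, and
#' the conjunction ROIs over the integration metrics (degree, global
#' efficiency, core number).
#'
#' @param metric_maps Long metric tibble ([subject_metric_maps()] rows for
#'   all subjects).
#' @param groups Named character vector mapping subject id to group
#'   (`"young"`/`"old"`).
#' @param node_map Tibble (node, x, y, z).
#' @param top_fraction,diff_criterion,min_roi_size See [pipeline_config()].
#' @return List with tibbles `overlap`, `difference` and `rois`.
#' @export
group_topology_maps <- function(metric_maps, groups, node_map,
                                top_fraction = 0.20, diff_criterion = 25,
                                min_roi_size = 2) {
  combos <- distinct(metric_maps, .data$s, .data$metric)
  overlap_rows <- list()
  diff_rows <- list()
  roi_rows <- list()
  for (i in seq_len(nrow(combos))) {
    s_i <- combos$s[i]
    m_i <- combos$metric[i]
    sub_maps <- filter(metric_maps, .data$s == s_i, .data$metric == m_i)
    ov <- list()
    for (g in c("young", "old")) {
      subs <- names(groups)[groups == g]
      masks <- lapply(subs, function(sb) {
        v <- arrange(filter(sub_maps, .data$subject == sb), .data$node)$value
        top_fraction_mask(v, top_fraction)
      })
      ov[[g]] <- overlap_map(masks)
      overlap_rows[[paste(s_i, m_i, g)]] <-
        mutate(ov[[g]], s = s_i, metric = m_i, group = g,
               top_fraction = top_fraction)
    }
    dm <- difference_map(ov$young, ov$old, criterion = diff_criterion)
    diff_rows[[paste(s_i, m_i)]] <- mutate(dm, s = s_i, metric = m_i)
  }
  difference <- bind_rows(diff_rows) |>
    rename(flag_young_gt_old = "flag_a_gt_b",
           flag_old_gt_young = "flag_b_gt_a")
  for (s_i in unique(combos$s)) {
    integ <- lapply(c("degree", "eglob", "kcore"), function(m_i) {
      filter(difference, .data$s == s_i, .data$metric == m_i) |>
        rename(flag_a_gt_b = "flag_young_gt_old",
               flag_b_gt_a = "flag_old_gt_young")
    })
    rois <- suppressWarnings(
      conjunction_rois(integ, node_map, min_size = min_roi_size,
                       labels = c("young>old", "old>young"))
    )
    if (nrow(rois)) roi_rows[[as.character(s_i)]] <- mutate(rois, s = s_i)
  }
  rois <- if (length(roi_rows)) bind_rows(roi_rows) else
    tibble(roi = character(), direction = character(), node = integer(),
           x = integer(), y = integer(), z = integer(), s = numeric())
  list(overlap = bind_rows(overlap_rows), difference = difference,
       rois = rois)
}

# Stats stage: MANOVAs per direction, per-ROI ANOVAs, the group-by-ROI
# interaction, brain-behavior hierarchical regressions with the dual-S
# rule, and SWLS correlations in old>young regions (old group only).
pipeline_stats <- function(cohort, metric_maps, rois, s_levels) {
  grp_tbl <- select(as_tibble(cohort), "subject", "group", "sex",
                    "single_task_rt", "swls_total")
  manova_rows <- list()
  anova_rows <- list()
  inter_rows <- list()
  reg_rows <- list()
  swls_rows <- list()

  for (s_i in s_levels) {
    rois_s <- filter(rois, .data$s == s_i)
    if (!nrow(rois_s)) next
    for (metric_i in c("eglob", "eloc")) {
      tab <- roi_metric_table(metric_maps, rois_s, metric_i, s = s_i) |>
        left_join(grp_tbl, by = "subject")
      wide <- tab |>
        select("subject", "group", "roi", "value") |>
        tidyr::pivot_wider(names_from = "roi", values_from = "value")
      # MANOVA per direction (DMN/FP-style young>old set and old>young set)
      for (dir_i in unique(rois_s$direction)) {
        roi_ids <- unique(rois_s$roi[rois_s$direction == dir_i])
        if (length(roi_ids) < 1) next
        n_err <- nrow(wide) - 2
        if (length(roi_ids) >= n_err) next
        mv <- manova_pillai(wide, dvs = roi_ids)
        manova_rows[[paste(s_i, metric_i, dir_i)]] <-
          mutate(mv, s = s_i, metric = metric_i, contrast = dir_i,
                 n_rois = length(roi_ids))
      }
      # post-hoc univariate ANOVAs per ROI
      for (roi_i in unique(rois_s$roi)) {
        av <- univariate_anova(filter(tab, .data$roi == roi_i), "value")
        anova_rows[[paste(s_i, metric_i, roi_i)]] <-
          mutate(av, s = s_i, metric = metric_i, roi = roi_i)
      }
      # group x ROI repeated-measures interaction
      if (length(unique(tab$roi)) >= 2) {
        it <- rm_group_by_roi_interaction(tab)
        inter_rows[[paste(s_i, metric_i)]] <-
          mutate(it, s = s_i, metric = metric_i)
      }
      # hierarchical regression per ROI: RT ~ group + sex | metric | gxm
      for (roi_i in unique(rois_s$roi)) {
        dat <- filter(tab, .data$roi == roi_i) |>
          select("subject", "group", "sex", "single_task_rt", "value") |>
          rename(metric_value = "value")
        blocks <- list(c("group", "sex"), "metric_value",
                       "group:metric_value")
        if (length(unique(dat$sex)) < 2) blocks[[1]] <- "group"
        hr <- hierarchical_regression(dat, "single_task_rt", blocks)
        cf <- tidy(hr) |>
          filter(.data$step == length(blocks)) |>
          mutate(s = s_i, metric = metric_i, roi = roi_i,
                 r_squared = glance(hr)$r_squared)
        reg_rows[[paste(s_i, metric_i, roi_i)]] <- cf
      }
    }
    # SWLS vs regional Eglob in old>young regions, old group only
    old_ids <- grp_tbl$subject[grp_tbl$group == "old" &
                                 !is.na(grp_tbl$swls_total)]
    oy <- filter(rois_s, .data$direction == "old>young")
    if (nrow(oy) && length(old_ids) >= 4) {
      tab <- roi_metric_table(metric_maps, oy, "eglob", s = s_i) |>
        filter(.data$subject %in% old_ids) |>
        left_join(grp_tbl, by = "subject")
      for (roi_i in unique(oy$roi)) {
        d <- filter(tab, .data$roi == roi_i)
        if (nrow(d) >= 4 && sd(d$value) > 0) {
          pc <- pearson_correlation(d$value, d$swls_total)
          swls_rows[[paste(s_i, roi_i)]] <-
            mutate(pc, s = s_i, roi = roi_i, metric = "eglob")
        }
      }
    }
  }
  empty <- function(...) tibble(...)
  list(
    stats_manova = bind_rows(manova_rows),
    stats_anova = bind_rows(anova_rows),
    stats_interaction = bind_rows(inter_rows),
    stats_regression = bind_rows(reg_rows),
    stats_swls = bind_rows(swls_rows)
  )
}

#' Assemble the report stage from a pipeline output tree
#'
#' Collects the stats-stage tables into one tidy summary (analysis id, S,
#' statistic, value, dfs, p, effect size) and optionally writes the
#' efficiency-by-group and SWLS scatter figures.
#'
#' @param out_dir Pipeline output directory containing a `stats/` stage.
#' @param report_dir Where to write the report (default `out_dir/report`).
#' @param make_figures Write PNG figures alongside the tables.
#' @return Invisibly, the summary tibble.
#' @export
export_report <- function(out_dir, report_dir = file.path(out_dir, "report"),
                          make_figures = FALSE) {
  stats_d <- file.path(out_dir, "stats")
  if (!dir.exists(stats_d)) {
    abort(paste0("No stats stage found under '", out_dir,
                 "'; run the pipeline through the stats stage first."))
  }
  dir.create(report_dir, recursive = TRUE, showWarnings = FALSE)
  read_or_null <- function(nm) {
    f <- file.path(stats_d, paste0(nm, ".tsv"))
    if (!file.exists(f)) return(NULL)
    df <- readr::read_tsv(f, show_col_types = FALSE)
    if (!nrow(df)) NULL else df
  }
  mv <- read_or_null("stats_manova")
  av <- read_or_null("stats_anova")
  it <- read_or_null("stats_interaction")
  rg <- read_or_null("stats_regression")
  sw <- read_or_null("stats_swls")
  rows <- list()
  if (!is.null(mv)) {
    rows$manova <- tibble(analysis = paste0("manova_", mv$metric, "_",
                                            mv$contrast),
                          s = mv$s, statistic = "pillai_V", value = mv$value,
                          df1 = mv$df1, df2 = mv$df2, p = mv$p,
                          effect_size = mv$partial_eta_sq)
  }
  if (!is.null(av)) {
    rows$anova <- tibble(analysis = paste0("anova_", av$metric, "_", av$roi),
                         s = av$s, statistic = "F", value = av$value,
                         df1 = av$df1, df2 = av$df2, p = av$p,
                         effect_size = av$eta_sq)
  }
  if (!is.null(it)) {
    rows$interaction <- tibble(analysis = paste0("interaction_", it$metric),
                               s = it$s, statistic = "F", value = it$value,
                               df1 = it$df1, df2 = it$df2, p = it$p,
                               effect_size = it$partial_eta_sq)
  }
  if (!is.null(rg)) {
    rg_i <- filter(rg, grepl(":", .data$term))
    rows$regression <- tibble(analysis = paste0("regression_", rg_i$metric,
                                                "_", rg_i$roi, "_",
                                                rg_i$term),
                              s = rg_i$s, statistic = "std_beta",
                              value = rg_i$std_beta, df1 = NA_real_,
                              df2 = NA_real_, p = rg_i$p,
                              effect_size = rg_i$std_beta)
  }
  if (!is.null(sw)) {
    rows$swls <- tibble(analysis = paste0("swls_", sw$metric, "_", sw$roi),
                        s = sw$s, statistic = "r", value = sw$r,
                        df1 = sw$df, df2 = NA_real_, p = sw$p,
                        effect_size = sw$r)
  }
  summary_tbl <- bind_rows(rows)
  readr::write_tsv(summary_tbl, file.path(report_dir, "report_summary.tsv"))

  if (make_figures && !is.null(av)) {
    p1 <- ggplot2::ggplot(av, ggplot2::aes(x = .data$roi, y = .data$eta_sq,
                                           fill = .data$metric)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::facet_wrap(~s) +
      ggplot2::labs(x = NULL, y = "eta squared",
                    title = "Group effects per ROI") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
    ggplot2::ggsave(file.path(report_dir, "anova_effects.png"), p1,
                    width = 8, height = 5, dpi = 120)
  }
  invisible(summary_tbl)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path Path to a NIfTI-1 file.
#' @return Numeric array (3D or 4D) with the NIfTI header attached by
#'   RNifti.
#' @export
read_volume <- function(path) {
  RNifti::readNifti(path)
}

#' Write an array as a NIfTI-1 volume
#'
#' The affine/pixel dimensions of a template image are preserved when
#' supplied; write-then-read restores the data array exactly at the stored
#' precision.
#'
#' @param x Numeric array (3D volume or 4D series) or an RNifti image.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param template Optional image or path whose header/affine to reuse.
#' @param datatype NIfTI storage type, e.g. `"float64"` or `"uint8"`.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(x, path, template = NULL, datatype = "float64") {
  img <- if (is.null(template)) RNifti::asNifti(x) else
    RNifti::asNifti(x, reference = RNifti::asNifti(template))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Export per-node values as a NIfTI map in voxel space
#'
#' @param values Per-node vector aligned to the mask.
#' @param mask A `gm_mask`.
#' @param path Output path.
#' @param datatype NIfTI storage type.
#' @return Invisibly, `path`.
#' @export
write_metric_nifti <- function(values, mask, path, datatype = "float64") {
  write_volume(unmask(values, mask), path, datatype = datatype)
}
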