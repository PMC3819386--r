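# Synthetic multi-subject cohort generation.
#
# Signal model: each voxel is a unit-variance mixture of (i) its module
# factor, (ii) optional cross-community loadings (DMN bridging, hub boost),
# (iii) an optional long-range pair factor, and (iv) white residual noise,
# plus nuisance components (global signal, motion-coupled noise) that the
# preprocessing stage removes.  Because the model is an explicit factor
# decomposition, the implied covariance is positive semi-definite by
# construction; the generator refuses configurations whose per-node loading
# budget exceeds the unit variance.

# Per-subject within-community correlations (squared community loadings).
subject_rho <- function(spec, group, z_dmn = 0, z_sal = 0) {
  ef <- spec$effects
  w <- if (group == "young") ef$within_young else ef$within_old
  rho <- spec$layout$modules$rho_background
  rho[spec$layout$dmn_module] <-
    min(max(w[["dmn"]] + ef$subject_sd * z_dmn, 0.02), 0.90)
  rho[spec$layout$sal_module] <-
    min(max(w[["sal"]] + ef$subject_sd * z_sal, 0.02), 0.90)
  rho[spec$layout$fp_module] <- w[["fp"]]
  rho
}

# Sparse loading matrix for one subject:
# N x (n_modules + n_lr_pairs + n_bridge_pairs).
# Returns the matrix and the per-node squared-loading budget.
build_loadings <- function(spec, group, z_dmn, z_sal, structure) {
  lay <- spec$layout
  ef <- spec$effects
  nm <- lay$node_map
  n <- nrow(nm)
  n_mod <- nrow(lay$modules)
  rho <- subject_rho(spec, group, z_dmn, z_sal)

  ii <- nm$node
  jj <- nm$module
  xx <- sqrt(rho[nm$module])

  boost <- if (group == "young") ef$hub_boost_young else ef$hub_boost_old
  if (boost > 0) {
    ii <- c(ii, lay$hub_nodes)
    jj <- c(jj, rep(lay$hub_target_module, length(lay$hub_nodes)))
    xx <- c(xx, rep(sqrt(boost), length(lay$hub_nodes)))
  }
  lr_pairs <- structure$lr_pairs
  n_lr <- nrow(lr_pairs)
  if (n_lr > 0 && ef$long_range_corr > 0) {
    lr_load <- sqrt(ef$long_range_corr)
    ii <- c(ii, lr_pairs$a, lr_pairs$b)
    jj <- c(jj, rep(n_mod + seq_len(n_lr), 2))
    xx <- c(xx, rep(lr_load, 2 * n_lr))
  }
  bridge_pairs <- structure$bridge_pairs
  n_br <- nrow(bridge_pairs)
  if (n_br > 0 && ef$dmn_bridge_corr > 0) {
    br_load <- sqrt(ef$dmn_bridge_corr)
    ii <- c(ii, bridge_pairs$a, bridge_pairs$b)
    jj <- c(jj, rep(n_mod + n_lr + seq_len(n_br), 2))
    xx <- c(xx, rep(br_load, 2 * n_br))
  }
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(n, n_mod + n_lr + n_br))
  budget <- Matrix::rowSums(L^2)
  if (any(budget > 0.98)) {
    abort(paste0(
      "Implied covariance is not a valid unit-variance factor model: ",
      sum(budget > 0.98), " node(s) have squared-loading budget > 0.98. ",
      "Reduce within-community correlations, bridge/boost loadings, or ",
      "the long-range correlation."
    ))
  }
  list(L = L, budget = as.numeric(budget))
}

# Cohort-level wiring drawn once per cohort so it is identical across
# subjects and groups: the long-range backbone (one matched pair per
# eligible non-DMN/non-SAL voxel) and the DMN bridge partners (one
# dedicated sea-tier voxel per DMN-like node).
draw_structure <- function(layout) {
  nm <- layout$node_map
  eligible <- nm$node[!(nm$community %in% c("dmn", "sal"))]
  eligible <- sample(eligible)
  k <- length(eligible) %/% 2
  lr_pairs <- tibble(a = eligible[seq_len(k)], b = eligible[k + seq_len(k)])

  dmn_nodes <- nm$node[nm$community == "dmn"]
  sea <- nm$node[nm$module %in%
                   layout$modules$module[layout$modules$tier %in% "sea"]]
  if (length(sea) < length(dmn_nodes)) {
    abort("Not enough sea-tier voxels to host the DMN bridge partners.")
  }
  partners <- sample(sea, length(dmn_nodes))
  list(lr_pairs = lr_pairs,
       bridge_pairs = tibble(a = dmn_nodes, b = partners))
}

ar1_series <- function(t, phi = 0.9) {
  x <- as.numeric(stats::filter(rnorm(t), phi, method = "recursive"))
  x / sd(x)
}

rlnorm_moments <- function(n, mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Distribute a target SWLS total over five 1-7 items.
swls_items_from_total <- function(total) {
  total <- as.integer(round(min(max(total, 5), 35)))
  items <- pmin(pmax(round(total / 5 + rnorm(5, 0, 0.7)), 1L), 7L)
  gap <- total - sum(items)
  while (gap != 0) {
    step <- sign(gap)
    room <- if (step > 0) which(items < 7L) else which(items > 1L)
    pick <- room[sample.int(length(room), 1L)]
    items[pick] <- items[pick] + step
    gap <- gap - step
  }
  as.integer(items)
}

#' Generate a synthetic multi-subject cohort
#'
#' Simulates `n_young + n_old` subjects sharing one community layout.  Each
#' subject carries multi-run node-by-time series (with global-signal and
#' motion-coupled nuisance components plus matching nuisance designs), a
#' motion covariate, and a behavioral record (SWLS items and total for the
#' old group, task-switching trials and costs, spatial working-memory trials
#' and composite) whose planted couplings follow the cohort's
#' [effect_spec()].  The cohort is a deterministic function of the spec:
#' rerunning with the same seed reproduces it bit for bit.
#'
#' @param spec A [cohort_spec()].
#' @param runs If `FALSE`, skip the (expensive) time-series simulation and
#'   return only group structure, latents, motion and behavior - useful for
#'   behavioral Monte-Carlo studies.
#' @return A tibble with one row per subject (list-columns `runs` and
#'   `nuisance` hold the per-run matrices/designs), carrying the layout,
#'   spec and long-range pair table as attributes.
#' @export
generate_cohort <- function(spec, runs = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, generate_cohort_impl(spec, runs))
}

generate_cohort_impl <- function(spec, make_runs) {
  lay <- spec$layout
  ef <- spec$effects
  n_sub <- spec$n_young + spec$n_old
  group <- factor(rep(c("young", "old"), c(spec$n_young, spec$n_old)),
                  levels = c("young", "old"))
  wiring <- draw_structure(lay)

  sex <- factor(ifelse(runif(n_sub) < 0.84, "F", "M"), levels = c("F", "M"))
  z_dmn <- pmin(pmax(rnorm(n_sub), -2), 2)
  z_sal <- pmin(pmax(rnorm(n_sub), -2), 2)
  motion <- ifelse(
    group == "young",
    rlnorm_moments(n_sub, ef$motion$young_mean, ef$motion$young_sd),
    rlnorm_moments(n_sub, ef$motion$old_mean, ef$motion$old_sd)
  )

  subjects <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    g <- as.character(group[s])
    run_list <- NULL
    design_list <- NULL
    if (make_runs) {
      ld <- build_loadings(spec, g, z_dmn[s], z_sal[s], wiring)
      noise_sd_v <- sqrt(pmax(1 - ld$budget, 0)) * spec$noise_sd
      n_fact <- ncol(ld$L)
      n_nodes <- nrow(ld$L)
      gw <- ef$global_amp * (1 + 0.1 * rnorm(n_nodes))
      mw <- matrix(rnorm(n_nodes * 6), n_nodes, 6) / sqrt(6) *
        (motion[s] / 0.1) * ef$motion_gain
      run_list <- vector("list", length(spec$run_lengths))
      design_list <- vector("list", length(spec$run_lengths))
      for (r in seq_along(spec$run_lengths)) {
        t_r <- spec$run_lengths[r]
        eta <- matrix(rnorm(n_fact * t_r), n_fact, t_r)
        x <- as.matrix(ld$L %*% eta) +
          matrix(rnorm(n_nodes * t_r), n_nodes, t_r) * noise_sd_v
        gsig <- rnorm(t_r)
        msig <- vapply(1:6, function(k) ar1_series(t_r), numeric(t_r))
        x <- x + tcrossprod(gw, gsig) + mw %*% t(msig)
        if (isTRUE(ef$task_bump)) {
          bump <- 0.4 * sin(2 * pi * 0.025 * spec$tr * seq_len(t_r))
          fp_nodes <- lay$node_map$community == "fp"
          x[fp_nodes, ] <- x[fp_nodes, ] + rep(bump, each = sum(fp_nodes))
        }
        design <- cbind(intercept = 1, global = gsig, msig)
        colnames(design) <- c("intercept", "global", paste0("motion", 1:6))
        run_list[[r]] <- x
        design_list[[r]] <- design
      }
    }

    # behavior ------------------------------------------------------------
    rt_mu <- if (g == "young") ef$rt$young_mean else ef$rt$old_mean
    beta <- ef$rt$beta
    rt_i <- rt_mu + ef$rt$sd *
      (beta * z_dmn[s] + sqrt(1 - beta^2) * rnorm(1))
    gc_i <- 300 + rnorm(1, 0, 60)
    lc_i <- 250 + rnorm(1, 0, 50)
    switch_trials <- tibble(
      condition = rep(c("single", "mixed_switch", "mixed_nonswitch"),
                      c(96, 60, 60)),
      rt = pmax(c(rnorm(96, rt_i, 120),
                  rnorm(60, rt_i + gc_i + lc_i / 2, 150),
                  rnorm(60, rt_i + gc_i - lc_i / 2, 150)), 150)
    )
    costs <- switch_costs(switch_trials)
    ability <- rnorm(1)
    spwm_trials <- tibble(
      set_size = rep(1:3, each = 40),
      rt = pmax(rnorm(120, 0.9 * rt_i + 60 * rep(1:3, each = 40), 130), 150),
      correct = rbinom(120, 1,
                       pmin(pmax(0.93 - 0.03 * rep(1:3, each = 40) +
                                   0.04 * ability, 0.5), 1))
    )
    if (g == "old") {
      r_swls <- ef$swls$target_r
      total <- ef$swls$mean + ef$swls$sd *
        (r_swls * z_sal[s] + sqrt(1 - r_swls^2) * rnorm(1))
      swls_items <- swls_items_from_total(total)
      swls_total <- score_swls(swls_items)
    } else {
      swls_items <- rep(NA_integer_, 5)
      swls_total <- NA_integer_
    }

    subjects[[s]] <- tibble(
      subject = sprintf("S%03d", s),
      group = group[s], sex = sex[s], motion = motion[s],
      z_dmn = z_dmn[s], z_sal = z_sal[s],
      runs = list(run_list), nuisance = list(design_list),
      single_task_rt = mean(switch_trials$rt[switch_trials$condition ==
                                               "single"]),
      local_cost = costs$local_cost, global_cost = costs$global_cost,
      switch_trials = list(switch_trials),
      spwm_trials = list(spwm_trials),
      swls_items = list(swls_items), swls_total = swls_total
    )
  }
  cohort <- bind_rows(subjects)

  spwm_all <- purrr::map2_dfr(cohort$subject, cohort$spwm_trials,
                              ~ mutate(.y, subject = .x))
  cohort <- left_join(cohort, spatial_wm_composite(spwm_all), by = "subject")

  attr(cohort, "layout") <- lay
  attr(cohort, "spec") <- spec
  attr(cohort, "wiring") <- wiring
  class(cohort) <- c("vg_cohort", class(cohort))
  cohort
}

#' Population covariance implied by a cohort specification
#'
#' Builds the dense node-by-node covariance matrix `L L' + D` of the clean
#' signal model for one group at given subject latents.  Intended for small
#' grids (PSD audits, unit tests); refuses grids above 5000 voxels.
#'
#' @param spec A [cohort_spec()].
#' @param group `"young"` or `"old"`.
#' @param z_dmn,z_sal Subject latents (0 = group-typical subject).
#' @return Dense symmetric covariance matrix.
#' @export
implied_covariance <- function(spec, group = c("young", "old"),
                               z_dmn = 0, z_sal = 0) {
  stopifnot(inherits(spec, "cohort_spec"))
  group <- match.arg(group)
  n <- nrow(spec$layout$node_map)
  if (n > 5000) abort("implied_covariance() is limited to grids <= 5000 voxels.")
  wiring <- withr::with_seed(spec$seed, draw_structure(spec$layout))
  ld <- build_loadings(spec, group, z_dmn, z_sal, wiring)
  sig <- as.matrix(Matrix::tcrossprod(ld$L))
  diag(sig) <- diag(sig) + pmax(1 - ld$budget, 0) * spec$noise_sd^2
  sig
}

#' Simulate a bivariate-normal sample with a planted correlation
#'
#' @param n Sample size.
#' @param rho Population correlation.
#' @return Tibble with standard-normal columns `x`, `y`.
#' @export
simulate_bivariate <- function(n, rho) {
  if (abs(rho) >= 1) abort("`rho` must lie in (-1, 1).")
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  tibble(x = x, y = y)
}

#' Simulate a brain-behavior regression cohort
#'
#' Generates `n` subjects with age group, sex, a standardized regional
#' network metric, and an outcome built so the metric's population
#' standardized coefficient equals `beta` after adjusting for group and sex.
#'
#' @param n Subjects.
#' @param beta Planted standardized coefficient of `metric` on `y`.
#' @param group_effect,sex_effect Coefficients of the +/-0.5-coded group and
#'   sex contrasts.
#' @return Tibble with columns `group`, `sex`, `metric`, `y`.
#' @export
simulate_regression_cohort <- function(n = 62, beta = -0.4,
                                       group_effect = 0.3, sex_effect = 0.1) {
  if (abs(beta) >= 1) abort("`beta` must lie in (-1, 1).")
  group <- factor(rep(c("young", "old"), length.out = n),
                  levels = c("young", "old"))
  sex <- factor(ifelse(runif(n) < 0.5, "F", "M"), levels = c("F", "M"))
  gc <- ifelse(group == "old", 0.5, -0.5)
  sc <- ifelse(sex == "M", 0.5, -0.5)
  metric <- rnorm(n)
  resid_var <- 1 - beta^2 - 0.25 * (group_effect^2 + sex_effect^2)
  if (resid_var <= 0) abort("Effect sizes leave no residual variance.")
  y <- beta * metric + group_effect * gc + sex_effect * sc +
    sqrt(resid_var) * rnorm(n)
  tibble(group = group, sex = sex, metric = metric, y = y)
}

#' Simulate a subject-by-ROI metric table
#'
#' Generates a long table of regional metric values with a subject random
#' intercept, per-ROI means, and optional per-ROI group effects - the input
#' shape consumed by the MANOVA / repeated-measures operations.
#'
#' @param n_young,n_old Subjects per group.
#' @param n_roi Number of regions.
#' @param roi_means Length-`n_roi` vector of ROI means.
#' @param group_effect Length-`n_roi` vector added to the old group.
#' @param subject_sd,noise_sd Random-intercept and residual SDs.
#' @return Tibble with columns `subject`, `group`, `roi`, `value`.
#' @export
simulate_roi_table <- function(n_young = 31, n_old = 31, n_roi = 10,
                               roi_means = seq(0.2, 0.4,
                                               length.out = n_roi),
                               group_effect = rep(0, n_roi),
                               subject_sd = 0.05, noise_sd = 0.05) {
  stopifnot(length(roi_means) == n_roi, length(group_effect) == n_roi)
  n <- n_young + n_old
  group <- factor(rep(c("young", "old"), c(n_young, n_old)),
                  levels = c("young", "old"))
  intercept <- rnorm(n, 0, subject_sd)
  grid <- tidyr::expand_grid(s = seq_len(n), roi = seq_len(n_roi))
  subj_group <- group[grid$s]
  value <- roi_means[grid$roi] +
    ifelse(subj_group == "old", group_effect[grid$roi], 0) +
    intercept[grid$s] + rnorm(nrow(grid), 0, noise_sd)
  tibble(
    subject = sprintf("S%03d", grid$s),
    group = subj_group,
    roi = factor(paste0("roi", grid$roi),
                 levels = paste0("roi", seq_len(n_roi))),
    value = value
  )
}
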