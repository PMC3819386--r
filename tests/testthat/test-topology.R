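grid_map <- function(dims) {
  co <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                    z = seq_len(dims[3]))
  tibble::tibble(node = seq_len(nrow(co)), x = co$x, y = co$y, z = co$z)
}

test_that("top-fraction masks select the highest values deterministically", {
  withr::with_seed(1, {
    v <- sample(1:100, 10)
    m <- top_fraction_mask(v, 0.2)
    expect_equal(sum(m), 2)
    expect_setequal(which(m), order(-v)[1:2])
    # size equals round(fraction * N) on random maps
    for (i in 1:10) {
      n <- sample(20:200, 1)
      vv <- rnorm(n)
      expect_equal(sum(top_fraction_mask(vv, 0.2)), floor(0.2 * n + 0.5))
    }
    # permuting node values permutes the selection identically
    v2 <- rnorm(50)
    perm <- sample(50)
    expect_identical(top_fraction_mask(v2[perm], 0.2),
                     top_fraction_mask(v2, 0.2)[perm])
  })
  expect_warning(m0 <- top_fraction_mask(rep(1, 10), 0.2), "Degenerate")
  expect_identical(which(m0), 1:2)
  expect_error(top_fraction_mask(1:10, 0), "fraction")
})

test_that("overlap maps count subjects in percent on the 100/n lattice", {
  masks <- lapply(1:10, function(i) c(i <= 6, TRUE, FALSE))
  ov <- overlap_map(masks)
  expect_equal(ov$overlap, c(60, 100, 0))  # 6 of 10 subjects -> 60
  expect_equal(attr(ov, "n_subjects"), 10)
  # identical sets give only 0 or 100
  same <- overlap_map(lapply(1:7, function(i) c(TRUE, FALSE, TRUE)))
  expect_setequal(unique(same$overlap), c(0, 100))
  # disjoint per-subject sets give 100/n at flagged voxels
  disj <- overlap_map(lapply(1:5, function(i) seq_len(5) == i))
  expect_equal(disj$overlap, rep(20, 5))
  # general lattice property
  withr::with_seed(2, {
    rnd <- overlap_map(lapply(1:9, function(i) runif(12) > 0.5))
    steps <- rnd$overlap * 9 / 100
    expect_equal(steps, round(steps), tolerance = 1e-9)
  })
})

test_that("overlap display thresholding keeps the boundary value", {
  map <- tibble::tibble(node = 1:3, overlap = c(40, 50, 60))
  expect_equal(threshold_overlap(map, 50)$overlap, c(0, 50, 60))
  expect_equal(threshold_overlap(map, 0)$overlap, map$overlap)
  expect_equal(threshold_overlap(map, 100)$overlap, c(0, 0, 0))
})

test_that("difference maps flag strictly above the criterion, both ways", {
  a <- tibble::tibble(node = 1:3, overlap = c(80, 70, 10))
  b <- tibble::tibble(node = 1:3, overlap = c(50, 50, 60))
  d <- difference_map(a, b, criterion = 25)
  expect_equal(d$diff, c(30, 20, -50))
  expect_equal(d$flag_a_gt_b, c(TRUE, FALSE, FALSE))   # 20 is not > 25
  expect_equal(d$flag_b_gt_a, c(FALSE, FALSE, TRUE))
  # antisymmetry under argument swap
  d2 <- difference_map(b, a, criterion = 25)
  expect_equal(d2$diff, -d$diff)
  expect_equal(d2$flag_a_gt_b, d$flag_b_gt_a)
  expect_equal(d2$flag_b_gt_a, d$flag_a_gt_b)
})

test_that("conjunction ROIs require all maps to agree in direction", {
  nm <- grid_map(c(4, 4, 1))
  mk <- function(flags_ab, flags_ba = rep(FALSE, 16)) {
    tibble::tibble(node = 1:16, diff = 0,
                   flag_a_gt_b = flags_ab, flag_b_gt_a = flags_ba)
  }
  f2 <- seq_len(16) %in% c(1, 2)
  f3 <- seq_len(16) %in% c(1, 2, 3)
  rois <- conjunction_rois(list(mk(f2), mk(f3), mk(f3)), nm)
  expect_setequal(rois$node, c(1, 2))  # node 3 flagged in only 2 of 3 maps
  expect_true(all(rois$direction == "a>b"))

  # relabeling the groups flips every direction tag
  flip <- function(d) tibble::tibble(node = d$node, diff = -d$diff,
                                     flag_a_gt_b = d$flag_b_gt_a,
                                     flag_b_gt_a = d$flag_a_gt_b)
  rois_fl <- conjunction_rois(lapply(list(mk(f2), mk(f3), mk(f3)), flip), nm)
  expect_setequal(rois_fl$node, c(1, 2))
  expect_true(all(rois_fl$direction == "b>a"))

  expect_warning(
    empty <- conjunction_rois(list(mk(rep(FALSE, 16))), nm),
    "Empty conjunction"
  )
  expect_equal(nrow(empty), 0)
})

test_that("ROIs are 26-connected clusters above the minimum size", {
  nm <- grid_map(c(6, 6, 1))
  # two clusters: {(1,1),(2,2)} touch diagonally; {(6,6)} is a singleton
  sel <- nm$node[(nm$x == 1 & nm$y == 1) | (nm$x == 2 & nm$y == 2) |
                   (nm$x == 6 & nm$y == 6)]
  flags <- nm$node %in% sel
  d <- tibble::tibble(node = nm$node, diff = 0, flag_a_gt_b = flags,
                      flag_b_gt_a = FALSE)
  rois <- conjunction_rois(list(d), nm, min_size = 2)
  expect_equal(sort(rois$node), sort(sel[1:2]))  # singleton dropped
  expect_equal(length(unique(rois$roi)), 1)
  rois1 <- conjunction_rois(list(d), nm, min_size = 1)
  expect_equal(length(unique(rois1$roi)), 2)
})

test_that("ROI means match a direct oracle", {
  expect_equal(roi_mean_metric(rep(3.5, 10), 2:5), 3.5)
  expect_equal(roi_mean_metric(c(1, 9, 4), 2), 9)
  withr::with_seed(3, {
    v <- rnorm(50)
    roi <- sample(50, 12)
    expect_equal(roi_mean_metric(v, roi), sum(v[roi]) / 12,
                 tolerance = 1e-12)
  })
  expect_error(roi_mean_metric(1:5, integer(0)), "empty")
})

test_that("roi_metric_table averages the right metric per subject and ROI", {
  g <- graph_complete(4)
  mm <- dplyr::bind_rows(subject_metric_maps(g, "s1", 2.5),
                         subject_metric_maps(g, "s2", 2.5))
  nm <- grid_map(c(4, 1, 1))
  rois <- tibble::tibble(roi = "r1", direction = "a>b", node = 1:2,
                         x = 1:2, y = 1, z = 1)
  tab <- roi_metric_table(mm, rois, "eglob", s = 2.5)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$value, c(1, 1))
  expect_error(roi_metric_table(mm, rois, "nosuch"), "No metric rows")
})

test_that("seed connectivity separates coupled from independent nodes", {
  withr::with_seed(4, {
    t_len <- 200
    seed_ts <- rnorm(t_len)
    coupled <- seed_ts + rnorm(t_len, sd = 0.4)
    indep <- matrix(rnorm(50 * t_len), 50, t_len)
    x <- rbind(seed_ts, coupled, indep)
    res <- seed_connectivity(x, seed_nodes = 1)
    expect_true(res$in_seed[1])
    expect_true(is.finite(res$z_raw[1]))
    expect_equal(res$z_raw[1], attr(res, "z_cap"))  # |r| = 1 capped
    expect_gt(res$z[2], 2.33)
    # under the null, at least 98% of nodes stay below the cutoff
    expect_gte(mean(abs(res$z_raw[-(1:2)]) < 2.33), 0.98)
  })
  expect_error(seed_connectivity(matrix(0, 2, 5), 1), "10 time points")
  expect_error(seed_connectivity(matrix(0, 2, 20), 5), "node indices")
})

test_that("overlap and difference maps ignore subject order within groups", {
  withr::with_seed(21, {
    masks_a <- lapply(1:8, function(i) runif(20) > 0.6)
    masks_b <- lapply(1:8, function(i) runif(20) > 0.6)
    d1 <- difference_map(overlap_map(masks_a), overlap_map(masks_b))
    d2 <- difference_map(overlap_map(sample(masks_a)),
                         overlap_map(rev(masks_b)))
    expect_equal(d1, d2)
  })
})

test_that("a planted 8-voxel hub cluster is recovered as one ROI", {
  # cohort whose only group effect is a cross-module integration boost of
  # 8 designated hub voxels in the old group; the degree/eglob/kcore
  # conjunction at S = 2.5 should return an old>young ROI recovering at
  # least 7 of the 8 planted voxels
  lay <- community_layout(n_hubs = 8)
  ef <- effect_spec(within_young = c(dmn = 0.42, fp = 0.16, sal = 0.22),
                    within_old = c(dmn = 0.42, fp = 0.16, sal = 0.22),
                    hub_boost_young = 0, hub_boost_old = 0.49)
  spec <- cohort_spec(n_young = 10, n_old = 10, layout = lay,
                      effects = ef, seed = 77)
  co <- generate_cohort(spec)
  maps <- lapply(seq_len(nrow(co)), function(i) {
    cs <- preprocess_subject(co$runs[[i]], co$nuisance[[i]])
    g <- threshold_to_density(pearson_matrix(unclass(cs)), 2.5)
    subject_metric_maps(g, co$subject[i], 2.5)
  })
  grp <- setNames(as.character(co$group), co$subject)
  res <- group_topology_maps(dplyr::bind_rows(maps), grp, lay$node_map)
  oy <- dplyr::filter(res$rois, .data$direction == "old>young")
  expect_gte(sum(lay$hub_nodes %in% oy$node), 7)
  expect_equal(length(unique(oy$roi)), 1)
})
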