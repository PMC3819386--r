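small_spec <- function(seed = 7, ...) {
  cohort_spec(n_young = 2, n_old = 2, grid_dims = c(6, 6, 6),
              block_dims = c(2, 2, 2), run_lengths = c(40, 50),
              seed = seed, ...)
}

test_that("a fixed seed reproduces the cohort bit for bit", {
  a <- generate_cohort(small_spec())
  b <- generate_cohort(small_spec())
  expect_identical(a$runs, b$runs)
  expect_identical(a$nuisance, b$nuisance)
  expect_identical(a$motion, b$motion)
  expect_identical(a$swls_total, b$swls_total)
  expect_identical(a$single_task_rt, b$single_task_rt)
  c_ <- generate_cohort(small_spec(seed = 8))
  expect_false(identical(a$runs, c_$runs))
})

test_that("the layout is identical across subjects and groups", {
  co <- generate_cohort(small_spec())
  expect_equal(nrow(co), 4)
  expect_s3_class(attr(co, "layout"), "community_layout")
  dims <- lapply(co$runs, function(r) vapply(r, dim, integer(2)))
  expect_true(all(vapply(dims, function(d) identical(d, dims[[1]]),
                         logical(1))))
})

test_that("equal effect specs give groups that differ only by noise", {
  ef <- effect_spec(within_young = c(dmn = 0.4, fp = 0.16, sal = 0.22),
                    within_old = c(dmn = 0.4, fp = 0.16, sal = 0.22),
                    hub_boost_young = 0, hub_boost_old = 0,
                    global_amp = 0, motion_gain = 0)
  spec <- cohort_spec(n_young = 6, n_old = 6, grid_dims = c(4, 4, 4),
                      block_dims = c(2, 2, 2), run_lengths = c(400),
                      effects = ef, seed = 31)
  co <- generate_cohort(spec)
  mean_corr <- function(rows) {
    cms <- lapply(rows, function(r) pearson_matrix(r[[1]]))
    Reduce(`+`, cms) / length(cms)
  }
  cy <- mean_corr(co$runs[co$group == "young"])
  co_ <- mean_corr(co$runs[co$group == "old"])
  # group-mean correlation matrices agree up to sampling noise
  expect_lt(max(abs(cy - co_)), 6 / sqrt(400 - 3) / sqrt(6))
})

test_that("planted within-community correlations are recovered", {
  # Monte-Carlo over 100+ subjects at T = 550: the mean sample correlation
  # inside the DMN-like block approaches the planted 0.6 (young) and 0.3
  # (old) within a Fisher-z standard error
  ef <- effect_spec(within_young = c(dmn = 0.6, fp = 0.16, sal = 0.22),
                    within_old = c(dmn = 0.3, fp = 0.16, sal = 0.22),
                    dmn_bridge_corr = 0, hub_boost_young = 0,
                    hub_boost_old = 0, subject_sd = 0,
                    global_amp = 0, motion_gain = 0)
  spec <- cohort_spec(n_young = 55, n_old = 55, grid_dims = c(6, 6, 6),
                      block_dims = c(2, 2, 2), run_lengths = c(550),
                      effects = ef, seed = 99)
  co <- generate_cohort(spec)
  lay <- attr(co, "layout")
  dmn <- lay$node_map$node[lay$node_map$community == "dmn"]
  mean_within <- function(rows) {
    vals <- vapply(rows, function(r) {
      cm <- pearson_matrix(r[[1]])[dmn, dmn]
      mean(cm[upper.tri(cm)])
    }, numeric(1))
    mean(vals)
  }
  se_r <- function(r, t_len) (1 - r^2) / sqrt(t_len - 3)
  expect_equal(mean_within(co$runs[co$group == "young"]), 0.6,
               tolerance = se_r(0.6, 550))
  expect_equal(mean_within(co$runs[co$group == "old"]), 0.3,
               tolerance = se_r(0.3, 550))
})

test_that("the implied covariance is symmetric positive semi-definite", {
  spec <- small_spec()
  for (g in c("young", "old")) {
    sig <- implied_covariance(spec, g, z_dmn = 1.5, z_sal = -1.5)
    expect_equal(sig, t(sig))
    ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
    expect_equal(unname(diag(sig)), rep(spec$noise_sd^2, nrow(sig)),
                 tolerance = 1e-12)
  }
})

test_that("an over-budget parameterization raises an explicit error", {
  ef <- effect_spec(within_old = c(dmn = 0.15, fp = 0.16, sal = 0.60),
                    hub_boost_old = 0.60)
  expect_error(generate_cohort(small_spec(effects = ef)),
               "not a valid unit-variance factor model")
})

test_that("SWLS totals carry the planted coupling sign", {
  # planted r = 0.5 with the SAL integration latent, n = 30 old subjects:
  # the recovered correlation has the planted sign in >= 95% of replicates
  hits <- 0
  for (rep in 1:200) {
    spec <- cohort_spec(n_young = 1, n_old = 30, grid_dims = c(6, 6, 6),
                        block_dims = c(2, 2, 2), seed = 5000 + rep)
    co <- generate_cohort(spec, runs = FALSE)
    old <- co[co$group == "old", ]
    hits <- hits + (cor(old$swls_total, old$z_sal) > 0)
  }
  expect_gte(hits / 200, 0.95)
})

test_that("behavior records respect their scales", {
  co <- generate_cohort(small_spec())
  old <- co[co$group == "old", ]
  expect_true(all(vapply(old$swls_items,
                         function(it) all(it %in% 1:7), logical(1))))
  expect_true(all(old$swls_total >= 5 & old$swls_total <= 35))
  expect_true(all(vapply(old$swls_items, sum, numeric(1)) ==
                    old$swls_total))
  expect_true(all(is.na(co$swls_total[co$group == "young"])))
  expect_true(all(co$spwm_accuracy >= 0 & co$spwm_accuracy <= 1))
  expect_true(all(co$motion > 0))
  expect_equal(mean(co$wm_composite), 0, tolerance = 1e-10)
})

test_that("nuisance designs match the runs and carry an intercept", {
  co <- generate_cohort(small_spec())
  for (i in seq_len(nrow(co))) {
    for (r in seq_along(co$runs[[i]])) {
      d <- co$nuisance[[i]][[r]]
      expect_equal(nrow(d), ncol(co$runs[[i]][[r]]))
      expect_true("intercept" %in% colnames(d))
      expect_true(all(d[, "intercept"] == 1))
    }
  }
})

test_that("simulation helpers deliver their planted structure", {
  withr::with_seed(17, {
    bv <- simulate_bivariate(5000, 0.47)
    expect_equal(cor(bv$x, bv$y), 0.47, tolerance = 0.05)

    rc <- simulate_regression_cohort(5000, beta = -0.4)
    fit <- lm(y ~ metric + group + sex, data = rc)
    expect_equal(unname(coef(fit)["metric"]), -0.4, tolerance = 0.05)

    rt <- simulate_roi_table(n_young = 10, n_old = 10, n_roi = 4,
                             group_effect = c(0, 0, 0.5, 0.5))
    expect_equal(nrow(rt), 80)
    m <- tapply(rt$value, list(rt$group, rt$roi), mean)
    expect_gt(m["old", "roi4"] - m["young", "roi4"], 0.2)
  })
})
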