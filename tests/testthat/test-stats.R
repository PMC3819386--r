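test_that("Pillai's trace matches the hand-computed two-group case", {
  d <- tibble::tibble(group = rep(c("a", "b"), each = 3),
                      y = c(1, 2, 3, 4, 5, 6))
  mv <- manova_pillai(d, dvs = "y")
  expect_equal(mv$value, 13.5 / 17.5, tolerance = 1e-12)
  expect_equal(mv$partial_eta_sq, 13.5 / 17.5, tolerance = 1e-12)
  # with one DV, V equals the univariate eta squared
  av <- univariate_anova(d, "y")
  expect_equal(mv$value, av$eta_sq, tolerance = 1e-12)
  expect_equal(av$value, 13.5, tolerance = 1e-12)
  expect_equal(av$df1, 1)
  expect_equal(av$df2, 4)
})

test_that("Pillai's trace agrees with stats::manova on random data", {
  withr::with_seed(123, {
    for (rep in 1:5) {
      n <- 40
      d <- tibble::tibble(group = rep(c("young", "old"), each = n / 2))
      y <- matrix(rnorm(n * 3), n, 3)
      y[d$group == "old", 1] <- y[d$group == "old", 1] + 0.8
      d$v1 <- y[, 1]; d$v2 <- y[, 2]; d$v3 <- y[, 3]
      mv <- manova_pillai(d, dvs = c("v1", "v2", "v3"))
      ref <- summary(stats::manova(y ~ factor(d$group)), test = "Pillai")
      st <- ref$stats
      expect_equal(mv$value, st[1, "Pillai"], tolerance = 1e-8)
      expect_equal(mv$approx_f, st[1, "approx F"], tolerance = 1e-8)
      expect_equal(mv$df1, st[1, "num Df"])
      expect_equal(mv$df2, st[1, "den Df"])
      expect_equal(mv$p, st[1, "Pr(>F)"], tolerance = 1e-8)
      expect_true(mv$value >= 0 && mv$value <= 1)
    }
  })
})

test_that("MANOVA validates its input", {
  d <- tibble::tibble(group = rep(c("a", "b"), each = 3),
                      v1 = c(1, 2, 3, 4, 5, 6))
  d$v2 <- d$v1 * 2  # collinear DVs -> singular within SSCP
  expect_error(manova_pillai(d, dvs = c("v1", "v2")), "singular")
  expect_error(manova_pillai(d[1:3, ], dvs = "v1"), "two groups")
  d4 <- tibble::tibble(group = rep(c("a", "b"), each = 2),
                       v1 = rnorm(4), v2 = rnorm(4), v3 = rnorm(4))
  expect_error(manova_pillai(d4, dvs = c("v1", "v2", "v3")),
               "Too many dependent")
})

test_that("one-way ANOVA agrees with stats::aov and the t-test identity", {
  withr::with_seed(5, {
    d <- tibble::tibble(group = rep(c("a", "b"), c(12, 15)),
                        y = rnorm(27) + rep(c(0, 0.6), c(12, 15)))
    av <- univariate_anova(d, "y")
    ref <- summary(stats::aov(y ~ group, data = d))[[1]]
    expect_equal(av$value, ref["group", "F value"], tolerance = 1e-8)
    expect_equal(av$p, ref["group", "Pr(>F)"], tolerance = 1e-8)
    # two-group F equals the squared pooled-variance t statistic
    tt <- t.test(y ~ group, data = d, var.equal = TRUE)
    expect_equal(av$value, unname(tt$statistic)^2, tolerance = 1e-8)
    # equal group means give F ~ 0
    d0 <- tibble::tibble(group = rep(c("a", "b"), each = 4),
                         y = rep(c(1, 2, 3, 4), 2))
    expect_lt(univariate_anova(d0, "y")$value, 1e-12)
  })
})

test_that("the split-plot interaction has the standard df structure", {
  withr::with_seed(9, {
    tab <- simulate_roi_table(n_young = 31, n_old = 31, n_roi = 10)
    it <- rm_group_by_roi_interaction(tab)
    expect_equal(it$df1, 9)
    expect_equal(it$df2, 540)  # (R-1)(N-G) = 9 * 60
  })
})

test_that("the interaction F agrees with stats::aov on shared fixtures", {
  withr::with_seed(10, {
    tab <- simulate_roi_table(n_young = 8, n_old = 9, n_roi = 4,
                              group_effect = c(0.1, 0, -0.1, 0.2))
    it <- rm_group_by_roi_interaction(tab)
    ref <- summary(stats::aov(value ~ group * roi + Error(subject / roi),
                              data = tab))
    within_tab <- ref[["Error: subject:roi"]][[1]]
    expect_equal(it$value, within_tab["group:roi", "F value"],
                 tolerance = 1e-8)
    expect_equal(it$p, within_tab["group:roi", "Pr(>F)"], tolerance = 1e-8)
    expect_equal(it$df1, within_tab["group:roi", "Df"])
    expect_equal(it$df2, within_tab["Residuals", "Df"])
  })
})

test_that("parallel profiles give a null interaction; crossover a strong one", {
  withr::with_seed(11, {
    # exactly parallel cell profiles: residual noise demeaned within each
    # group x ROI cell so the interaction sum of squares vanishes
    par_tab <- simulate_roi_table(n_young = 15, n_old = 15, n_roi = 5,
                                  group_effect = rep(0.3, 5),
                                  noise_sd = 0.2, subject_sd = 0)
    par_tab <- par_tab |>
      dplyr::group_by(.data$group, .data$roi) |>
      dplyr::mutate(value = .data$value - mean(.data$value) +
                      mean(par_tab$value)) |>
      dplyr::ungroup()
    expect_lt(rm_group_by_roi_interaction(par_tab)$value, 1e-10)
    # planted crossover: group A higher on one set, group B on the other
    cross <- simulate_roi_table(n_young = 15, n_old = 15, n_roi = 6,
                                group_effect = c(0.3, 0.3, 0.3,
                                                 -0.3, -0.3, -0.3),
                                noise_sd = 0.1)
    expect_lt(rm_group_by_roi_interaction(cross)$p, 0.001)
  })
})

test_that("hierarchical regression reports blockwise R2 and betas", {
  withr::with_seed(12, {
    n <- 200
    # mutually orthogonal, zero-mean standardized predictors via QR
    # (orthogonalized against the intercept as well)
    q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4]
    x1 <- q[, 1] / sd(q[, 1]); x2 <- q[, 2] / sd(q[, 2])
    x3 <- q[, 3] / sd(q[, 3])
    y <- 0.5 * x1 + 0.3 * x2 - 0.2 * x3 + rnorm(n, sd = 0.6)
    d <- tibble::tibble(y = y, x1 = x1, x2 = x2, x3 = x3)
    hr <- hierarchical_regression(d, "y", list("x1", "x2", "x3"))
    st <- hreg_steps(hr)
    # final R2 equals the sum of the individual squared correlations
    r2_sum <- cor(y, x1)^2 + cor(y, x2)^2 + cor(y, x3)^2
    expect_equal(st$r_squared[3], r2_sum, tolerance = 1e-10)
    expect_true(all(diff(st$r_squared) >= -1e-12))
    expect_true(all(st$delta_r_squared >= -1e-12))
    expect_equal(sum(st$delta_r_squared), st$r_squared[3],
                 tolerance = 1e-12)
    # standardized betas match a z-scored lm fit
    zfit <- lm(scale(y) ~ scale(x1) + scale(x2) + scale(x3))
    cf <- dplyr::filter(tidy(hr), .data$step == 3)
    expect_equal(cf$std_beta, unname(coef(zfit)[-1]), tolerance = 1e-10)
    gl <- glance(hr)
    expect_equal(gl$r_squared, st$r_squared[3])
    expect_equal(gl$n, n)
  })
})

test_that("a null block contributes ~zero delta R2 and beta", {
  withr::with_seed(13, {
    n <- 2000
    d <- tibble::tibble(
      group = factor(rep(c("young", "old"), each = n / 2)),
      sex = factor(sample(c("F", "M"), n, replace = TRUE)),
      metric = rnorm(n)
    )
    d$y <- ifelse(d$group == "old", 0.4, 0) + rnorm(n)
    hr <- hierarchical_regression(d, "y",
                                  list(c("group", "sex"), "metric",
                                       "group:metric"))
    st <- hreg_steps(hr)
    expect_lt(st$delta_r_squared[2], 0.01)
    cf <- dplyr::filter(tidy(hr), .data$term == "metric", .data$step == 2)
    expect_lt(abs(cf$std_beta), 0.1)
  })
})

test_that("interaction terms use centered metric and contrast-coded group", {
  withr::with_seed(14, {
    n <- 500
    d <- tibble::tibble(
      group = factor(rep(c("young", "old"), each = n / 2),
                     levels = c("young", "old")),
      metric = rnorm(n, mean = 5)
    )
    gc <- ifelse(d$group == "old", 0.5, -0.5)
    d$y <- 0.3 * gc + 0.4 * (d$metric - mean(d$metric)) * gc + rnorm(n)
    hr <- hierarchical_regression(d, "y",
                                  list("group", "metric", "group:metric"))
    cf <- dplyr::filter(tidy(hr), .data$step == 3)
    est <- cf$estimate[cf$term == "group:metric"]
    expect_equal(est, 0.4, tolerance = 0.2)
  })
})

test_that("collinear blocks raise an error naming the step", {
  d <- tibble::tibble(y = rnorm(20), a = rnorm(20))
  d$b <- d$a
  expect_error(hierarchical_regression(d, "y", list(c("a", "b"))),
               "Collinear")
  expect_error(hierarchical_regression(d, "y", list("nosuch")),
               "Unknown predictor")
  d$a[1] <- NA
  expect_error(hierarchical_regression(d, "y", list("a")),
               "Complete cases")
})

test_that("the dual-threshold rule needs both p-values and matching signs", {
  res <- function(p, b) tibble::tibble(p = p, std_beta = b)
  expect_true(dual_threshold_significance(res(0.03, -0.4), res(0.04, -0.3)))
  expect_false(dual_threshold_significance(res(0.03, -0.4), res(0.08, -0.3)))
  expect_warning(
    out <- dual_threshold_significance(res(0.01, -0.4), res(0.01, 0.4)),
    "conflicting"
  )
  expect_false(out)
  # alpha is configurable
  expect_false(dual_threshold_significance(res(0.03, 1), res(0.04, 1),
                                           alpha = 0.01))
})

test_that("Pearson correlation reproduces the t-transform p-value", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  withr::with_seed(15, {
    x <- rnorm(29)
    y <- 0.5 * x + rnorm(29)
    pc <- pearson_correlation(x, y)
    r <- cor(x, y)
    tstat <- r * sqrt(27 / (1 - r^2))
    expect_equal(pc$r, r, tolerance = 1e-12)
    expect_equal(pc$p, 2 * pt(abs(tstat), 27, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_equal(pc$df, 27)
  })
  expect_error(pearson_correlation(1:3, 1:3), "4 complete pairs")
  expect_error(pearson_correlation(rep(1, 10), rnorm(10)), "positive SD")
})

test_that("null correlation p-values are uniform on [0, 1]", {
  withr::with_seed(16, {
    ps <- vapply(1:500, function(i) {
      pearson_correlation(rnorm(29), rnorm(29))$p
    }, numeric(1))
    expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  })
})
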