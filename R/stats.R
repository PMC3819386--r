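# Group and brain-behavior statistics.  Pillai's trace, the one-way ANOVA
# and the split-plot interaction are computed from sums of squares and
# cross-products directly (and cross-checked against stats::manova /
# stats::aov in the test suite); ordinary model fits go through stats::lm,
# and the correlation test through stats::cor.test.

#' Two-group MANOVA with Pillai's trace
#'
#' Computes Pillai's trace V from the between/within SSCP eigenproblem and
#' the standard Pillai-to-F conversion (exact for two groups, where
#' partial eta-squared equals V).
#'
#' @param data Data frame with one row per subject.
#' @param dvs Character vector of dependent-variable column names.
#' @param group Name of the grouping column (>= 2 levels).
#' @return One-row tibble: `statistic` (= "pillai"), `value` (V), `approx_f`,
#'   `df1`, `df2`, `p`, `partial_eta_sq`.
#' @export
manova_pillai <- function(data, dvs, group = "group") {
  stopifnot(is.data.frame(data), all(dvs %in% names(data)),
            group %in% names(data))
  y <- as.matrix(data[, dvs, drop = FALSE])
  if (anyNA(y)) abort("Dependent variables contain missing values.")
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("At least two groups are required.")
  n <- nrow(y)
  p <- ncol(y)
  q <- nlevels(g) - 1
  if (p >= n - nlevels(g)) {
    abort("Too many dependent variables for the available error df.")
  }
  grand <- colMeans(y)
  tot <- crossprod(sweep(y, 2, grand))
  w <- matrix(0, p, p)
  for (lev in levels(g)) {
    yg <- y[g == lev, , drop = FALSE]
    w <- w + crossprod(sweep(yg, 2, colMeans(yg)))
  }
  b <- tot - w
  w_inv <- tryCatch(solve(w), error = function(e) {
    abort(paste("Pooled within-group SSCP is singular; reduce the number",
                "of ROIs entered jointly."))
  })
  lambda <- Re(eigen(w_inv %*% b, only.values = TRUE)$values)
  lambda <- pmax(lambda, 0)
  v <- sum(lambda / (1 + lambda))
  s <- min(p, q)
  m <- (abs(p - q) - 1) / 2
  nn <- (n - nlevels(g) - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  f <- (df2 / df1) * (v / s) / (1 - v / s)
  tibble(statistic = "pillai", value = v, approx_f = f,
         df1 = df1, df2 = df2, p = pf(f, df1, df2, lower.tail = FALSE),
         partial_eta_sq = v / s)
}

#' One-way ANOVA with eta-squared
#'
#' @param data Data frame with one row per subject.
#' @param dv Name of the numeric outcome column.
#' @param group Name of the grouping column.
#' @return One-row tibble: `statistic` (= "F"), `value`, `df1`, `df2`, `p`,
#'   `eta_sq`.
#' @export
univariate_anova <- function(data, dv, group = "group") {
  stopifnot(is.data.frame(data), dv %in% names(data), group %in% names(data))
  y <- data[[dv]]
  g <- factor(data[[group]])
  if (anyNA(y)) abort("The outcome contains missing values.")
  if (any(table(g) < 2)) abort("Each group needs at least 2 subjects.")
  n <- length(y)
  k <- nlevels(g)
  grand <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  sst <- sum((y - grand)^2)
  ssw <- sst - ssb
  df1 <- k - 1
  df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  tibble(statistic = "F", value = f, df1 = df1, df2 = df2,
         p = pf(f, df1, df2, lower.tail = FALSE),
         eta_sq = ssb / sst)
}

#' Group-by-ROI interaction from a split-plot (mixed) ANOVA
#'
#' Repeated-measures analysis with group as the between-subjects factor and
#' ROI as the within-subjects factor; returns the interaction F with
#' df `((R-1)(G-1), (R-1)(N-G))` and partial eta-squared.  No sphericity
#' correction is applied.
#'
#' @param data Long data frame: one row per subject x ROI.
#' @param value,roi,subject,group Column names.
#' @return One-row tibble: `statistic` (= "F_interaction"), `value`, `df1`,
#'   `df2`, `p`, `partial_eta_sq`.
#' @export
rm_group_by_roi_interaction <- function(data, value = "value", roi = "roi",
                                        subject = "subject",
                                        group = "group") {
  stopifnot(is.data.frame(data),
            all(c(value, roi, subject, group) %in% names(data)))
  y <- data[[value]]
  r <- factor(data[[roi]])
  s <- factor(data[[subject]])
  g <- factor(data[[group]])
  if (nlevels(r) < 2) abort("At least 2 ROIs are required.")
  tab <- table(s, r)
  if (any(tab != 1)) abort("Each subject must have exactly one value per ROI.")
  n_sub <- nlevels(s)
  n_roi <- nlevels(r)
  n_grp <- nlevels(g)
  grand <- mean(y)
  subj_means <- tapply(y, s, mean)
  grp_of_subj <- tapply(as.integer(g), s, function(v) v[1])
  grp_sizes <- table(grp_of_subj)
  grp_means <- tapply(y, g, mean)
  roi_means <- tapply(y, r, mean)
  cell_means <- tapply(y, list(g, r), mean)

  ss_between_subj <- n_roi * sum((subj_means - grand)^2)
  ss_group <- n_roi * sum(grp_sizes * (tapply(subj_means, grp_of_subj, mean) -
                                         grand)^2)
  ss_roi <- n_sub * sum((roi_means - grand)^2)
  ss_cells <- sum(as.numeric(grp_sizes) *
                    rowSums((cell_means - grand)^2))
  ss_int <- ss_cells - ss_group - ss_roi
  ss_total <- sum((y - grand)^2)
  ss_err <- ss_total - ss_between_subj - ss_roi - ss_int
  df1 <- (n_roi - 1) * (n_grp - 1)
  df2 <- (n_roi - 1) * (n_sub - n_grp)
  f <- (ss_int / df1) / (ss_err / df2)
  tibble(statistic = "F_interaction", value = f, df1 = df1, df2 = df2,
         p = pf(f, df1, df2, lower.tail = FALSE),
         partial_eta_sq = ss_int / (ss_int + ss_err))
}

# +/-0.5 contrast coding for a two-level factor (second level = +0.5)
contrast_code <- function(x) {
  f <- factor(x)
  if (nlevels(f) != 2) abort("Contrast coding requires exactly two levels.")
  ifelse(f == levels(f)[2], 0.5, -0.5)
}

#' Hierarchical (forced-entry block) regression
#'
#' Refits an ordinary least-squares model at each cumulative block of
#' predictors and reports per-step R-squared, the block's delta R-squared,
#' and each predictor's standardized beta and two-tailed p at every step it
#' appears in.  Two-level factors are contrast coded +/-0.5, continuous
#' predictors are mean-centered, and interaction terms written `"a:b"` are
#' the product of the coded/centered components - so the interaction is
#' built from the mean-centered metric and the group contrast.
#'
#' @param data Data frame of complete cases.
#' @param dv Name of the numeric outcome column.
#' @param blocks List of character vectors of predictor names, in entry
#'   order; interaction terms as `"a:b"`.
#' @return Object of class `vg_hreg`; see [tidy.vg_hreg()] and
#'   [glance.vg_hreg()].
#' @export
hierarchical_regression <- function(data, dv, blocks) {
  stopifnot(is.data.frame(data), dv %in% names(data),
            is.list(blocks), length(blocks) >= 1)
  base_vars <- unique(unlist(strsplit(unlist(blocks), ":")))
  missing_vars <- setdiff(base_vars, names(data))
  if (length(missing_vars)) {
    abort(paste0("Unknown predictor(s): ", paste(missing_vars, collapse = ", ")))
  }
  if (anyNA(data[, unique(c(dv, base_vars))])) {
    abort("Complete cases are required.")
  }
  y <- data[[dv]]
  code_var <- function(nm) {
    v <- data[[nm]]
    if (is.numeric(v)) v - mean(v) else contrast_code(v)
  }
  coded <- lapply(setNames(base_vars, base_vars), code_var)
  term_col <- function(term) {
    parts <- strsplit(term, ":")[[1]]
    Reduce(`*`, coded[parts])
  }
  all_terms <- unlist(blocks)
  x_all <- do.call(cbind, lapply(all_terms, term_col))
  colnames(x_all) <- all_terms

  steps <- vector("list", length(blocks))
  coefs <- list()
  r2_prev <- 0
  for (k in seq_along(blocks)) {
    terms_k <- unlist(blocks[seq_len(k)])
    x <- x_all[, terms_k, drop = FALSE]
    if (qr(cbind(1, x))$rank < ncol(x) + 1) {
      abort(paste0("Collinear predictors in step ", k, ": ",
                   paste(terms_k, collapse = ", ")))
    }
    fit <- lm(y ~ x)
    sm <- summary(fit)
    r2 <- sm$r.squared
    est <- stats::coef(sm)[-1, , drop = FALSE]
    coefs[[k]] <- tibble(
      step = k, term = terms_k,
      estimate = unname(est[, 1]),
      std_beta = unname(est[, 1] * apply(x, 2, sd) / sd(y)),
      p = unname(est[, 4])
    )
    steps[[k]] <- tibble(step = k, terms = paste(terms_k, collapse = " + "),
                         r_squared = r2, delta_r_squared = r2 - r2_prev)
    r2_prev <- r2
  }
  structure(
    list(coefficients = bind_rows(coefs), steps = bind_rows(steps),
         dv = dv, blocks = blocks, n = length(y)),
    class = "vg_hreg"
  )
}

#' @export
print.vg_hreg <- function(x, ...) {
  cat("<hierarchical regression> ", x$dv, " ~ ",
      paste(vapply(x$blocks, paste, "", collapse = " + "),
            collapse = " | "),
      "  (n = ", x$n, ")\n", sep = "")
  print(x$steps)
  invisible(x)
}

#' Tidy a hierarchical regression
#'
#' @param x A `vg_hreg` object.
#' @param ... Unused.
#' @return Tibble of per-step coefficients with standardized betas.
#' @export
tidy.vg_hreg <- function(x, ...) x$coefficients

#' Glance at a hierarchical regression
#'
#' @param x A `vg_hreg` object.
#' @param ... Unused.
#' @return One-row tibble with the final R-squared, step count and n.
#' @export
glance.vg_hreg <- function(x, ...) {
  tibble(r_squared = x$steps$r_squared[nrow(x$steps)],
         n_steps = nrow(x$steps), n = x$n)
}

#' Per-step R-squared summary of a hierarchical regression
#'
#' @param x A `vg_hreg` object.
#' @return Tibble with `step`, `terms`, `r_squared`, `delta_r_squared`.
#' @export
hreg_steps <- function(x) {
  stopifnot(inherits(x, "vg_hreg"))
  x$steps
}

#' Dual-threshold significance rule
#'
#' An association is considered statistically meaningful only if it is
#' significant at both network density levels with agreeing effect signs.
#'
#' @param result_s25,result_s30 One-row result tibbles (or lists) carrying
#'   `p` and a signed effect (`std_beta`, `estimate`, or `r`).
#' @param alpha Significance level; default 0.05.
#' @return `TRUE` iff `p < alpha` at both S levels and the effect signs
#'   agree; a sign conflict with both p below alpha returns `FALSE` with a
#'   warning.
#' @export
dual_threshold_significance <- function(result_s25, result_s30,
                                        alpha = 0.05) {
  eff <- function(res) {
    for (nm in c("std_beta", "estimate", "r", "value")) {
      if (!is.null(res[[nm]])) return(res[[nm]][1])
    }
    abort("Result carries no signed effect field.")
  }
  p1 <- result_s25$p[1]
  p2 <- result_s30$p[1]
  both_sig <- p1 < alpha && p2 < alpha
  if (!both_sig) return(FALSE)
  if (sign(eff(result_s25)) != sign(eff(result_s30))) {
    warn("Significant at both S levels but with conflicting effect signs.")
    return(FALSE)
  }
  TRUE
}

#' Pearson correlation with a two-tailed p-value
#'
#' Thin wrapper over [stats::cor.test()] (t transform with n-2 df).
#'
#' @param x,y Numeric vectors of equal length, n >= 4, both with positive
#'   SD.
#' @return One-row tibble: `statistic` (= "r"), `r`, `df`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  keep <- complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 4) abort("At least 4 complete pairs are required.")
  if (sd(x) == 0 || sd(y) == 0) abort("Both variables need positive SD.")
  ct <- cor.test(x, y, alternative = "two.sided", method = "pearson")
  tibble(statistic = "r", r = unname(ct$estimate),
         df = unname(ct$parameter), p = ct$p.value, n = length(x))
}
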