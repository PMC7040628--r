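#' One-way ANOVA with Tukey HSD on group values
#'
#' Classical between/within decomposition of per-tree summaries (e.g. total
#' tracheids produced) across treatment groups, with Tukey honest
#' significant difference pairwise comparisons via the studentized range
#' distribution. Shapiro-Wilk (residual normality) and Levene
#' (homogeneity) checks are reported as diagnostics only; they never gate
#' the test.
#'
#' @param values numeric response, one value per experimental unit (tree).
#' @param group treatment labels, same length.
#' @param conf_level confidence level for Tukey intervals (default 0.95).
#' @return object of class `anova_result`: list with `F`, `df_between`,
#'   `df_within`, `p`, `group_means`, `tukey` (data frame `pair, diff, lwr,
#'   upr, p_adj`) and `diagnostics` (Shapiro and Levene p values).
#' @export
one_way_anova <- function(values, group, conf_level = 0.95) {
  group <- factor(group)
  if (nlevels(group) < 2)
    stop("need at least two groups", call. = FALSE)
  sizes <- table(group)
  if (any(sizes < 2))
    stop("every group needs at least two values", call. = FALSE)
  dat <- data.frame(y = values, g = group)
  fit <- stats::aov(y ~ g, data = dat)
  tab <- summary(fit)[[1]]
  Fval <- tab["g", "F value"]
  pval <- tab["g", "Pr(>F)"]
  no_between <- stats::var(tapply(values, group, mean)) < 1e-24
  if (no_between) {
    # no between-group variance: F is 0 by convention, not numerical noise
    Fval <- 0; pval <- 1
  }
  tk <- suppressWarnings(stats::TukeyHSD(fit, conf.level = conf_level)$g)
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  fix <- abs(tukey$diff) < 1e-12 & (no_between | !is.finite(tukey$p_adj))
  tukey$p_adj[fix] <- 1
  res <- stats::residuals(fit)
  shapiro_p <- if (length(res) >= 3 && stats::sd(res) > 0)
    stats::shapiro.test(res)$p.value else NA_real_
  levene_p <- tryCatch(car::leveneTest(y ~ g, data = dat)[1, "Pr(>F)"],
                       error = function(e) NA_real_)
  structure(list(
    F = Fval,
    df_between = tab["g", "Df"], df_within = tab["Residuals", "Df"],
    p = pval,
    group_means = tapply(values, group, mean),
    tukey = tukey,
    diagnostics = c(shapiro_p = shapiro_p, levene_p = levene_p)),
    class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d,%d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  cat("group means:\n")
  print(round(x$group_means, 2))
  cat("Tukey HSD:\n")
  print(transform(x$tukey, diff = round(diff, 3), lwr = round(lwr, 3),
                  upr = round(upr, 3), p_adj = signif(p_adj, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Mixed-effects slope of a tracheid trait on a differentiation duration
#'
#' Fits `trait ~ duration + (1 | tree)` by REML: a fixed linear slope with
#' a random intercept per tree to absorb between-tree level differences in
#' repeatedly measured anatomy. With a single tree the model collapses to
#' ordinary least squares. The slope CI is a Wald interval.
#'
#' @param y trait values (e.g. lumen diameter, um).
#' @param x durations (days).
#' @param tree grouping labels.
#' @param conf_level confidence level for the slope CI (default 0.95).
#' @return object of class `mixed_slope_result`: list with `slope`,
#'   `intercept`, `slope_se`, `slope_ci`, `re_var` (tree intercept
#'   variance), `resid_var`, `n_trees`.
#' @export
mixed_slope <- function(y, x, tree, conf_level = 0.95) {
  if (length(y) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(x) == 0)
    stop("degenerate design: durations are constant", call. = FALSE)
  tree <- factor(tree)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (nlevels(tree) < 2) {
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2])
    se <- summary(fit)$coefficients[2, 2]
    return(structure(list(slope = slope,
                          intercept = unname(stats::coef(fit)[1]),
                          slope_se = se,
                          slope_ci = c(slope - z * se, slope + z * se),
                          re_var = 0,
                          resid_var = summary(fit)$sigma^2,
                          n_trees = 1L),
                     class = "mixed_slope_result"))
  }
  dat <- data.frame(y = y, x = x, tree = tree)
  fit <- suppressMessages(
    lme4::lmer(y ~ x + (1 | tree), data = dat, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular =
                 lme4::.makeCC(action = "ignore", tol = 1e-4))))
  fe <- lme4::fixef(fit)
  # a noiseless response makes the covariance degenerate; se is 0 then
  se <- tryCatch(
    suppressWarnings(sqrt(diag(as.matrix(stats::vcov(fit))))[2]),
    error = function(e) 0)
  if (!is.finite(se)) se <- 0
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(slope = unname(fe[2]), intercept = unname(fe[1]),
                 slope_se = unname(se),
                 slope_ci = unname(c(fe[2] - z * se, fe[2] + z * se)),
                 re_var = vc$vcov[vc$grp == "tree"],
                 resid_var = vc$vcov[vc$grp == "Residual"],
                 n_trees = nlevels(tree)),
            class = "mixed_slope_result")
}

#' @export
print.mixed_slope_result <- function(x, ...) {
  cat(sprintf(
    "mixed slope: %.4f (95%% CI %.4f to %.4f), intercept %.3f\n",
    x$slope, x$slope_ci[1], x$slope_ci[2], x$intercept))
  cat(sprintf("  tree intercept var %.4f, residual var %.4f, %d tree(s)\n",
              x$re_var, x$resid_var, x$n_trees))
  invisible(x)
}
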