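#' Smoother configuration
#'
#' Controls the penalized-spline smoother used for seasonal phase-count
#' curves and for tracheidogram trait profiles. The smoother is a cubic
#' regression spline of the response on the predictor with a random intercept
#' per tree; the smoothing parameter is selected by generalized
#' cross-validation unless forced through `sp`.
#'
#' @param basis_dim spline basis dimension (default 10).
#' @param ci_level pointwise confidence level (default 0.95).
#' @param family `"gaussian"` (default, appropriate for fractional mean
#'   counts) or `"poisson"`.
#' @param grid_step prediction-grid spacing in predictor units (default 1,
#'   i.e. daily for seasonal curves).
#' @param sp optional fixed smoothing parameter for the spline term;
#'   `NULL` (default) selects by GCV.
#' @return list of class `smooth_config`.
#' @export
smooth_config <- function(basis_dim = 10, ci_level = 0.95,
                          family = c("gaussian", "poisson"),
                          grid_step = 1, sp = NULL) {
  family <- match.arg(family)
  if (basis_dim < 4) stop("basis_dim must be at least 4", call. = FALSE)
  if (!(ci_level > 0 && ci_level < 1))
    stop("ci_level must be strictly between 0 and 1", call. = FALSE)
  if (!(grid_step > 0)) stop("grid_step must be positive", call. = FALSE)
  structure(list(basis_dim = basis_dim, ci_level = ci_level, family = family,
                 grid_step = grid_step, sp = sp),
            class = "smooth_config")
}

# Shared smoother: y ~ s(x, bs = "cr", k = basis_dim) + s(tree, bs = "re"),
# GCV-selected penalty, population-level prediction (random effect excluded).
# Returns grid, fitted mean, se and pointwise CI.
.fit_smooth <- function(x, y, tree, config, grid = NULL) {
  n_distinct <- length(unique(x))
  need <- max(6, config$basis_dim)
  if (n_distinct < need)
    stop(sprintf(
      "insufficient data: %d distinct predictor values, need at least %d",
      n_distinct, need), call. = FALSE)
  dat <- data.frame(x = x, y = y, tree = factor(tree))
  fam <- switch(config$family,
                gaussian = stats::gaussian(),
                poisson  = stats::poisson())
  multi_tree <- nlevels(dat$tree) > 1
  k <- config$basis_dim
  if (multi_tree) {
    form <- y ~ s(x, bs = "cr", k = k) + s(tree, bs = "re")
    sp <- if (!is.null(config$sp)) c(config$sp, -1) else NULL
  } else {
    form <- y ~ s(x, bs = "cr", k = k)
    sp <- config$sp
  }
  fit <- mgcv::gam(form, data = dat, family = fam, method = "GCV.Cp", sp = sp)
  if (is.null(grid))
    grid <- seq(min(x), max(x), by = config$grid_step)
  nd <- data.frame(x = grid, tree = factor(levels(dat$tree)[1],
                                           levels = levels(dat$tree)))
  pr <- if (multi_tree) {
    mgcv::predict.gam(fit, newdata = nd, se.fit = TRUE, exclude = "s(tree)",
                      newdata.guaranteed = TRUE)
  } else {
    mgcv::predict.gam(fit, newdata = nd, se.fit = TRUE,
                      newdata.guaranteed = TRUE)
  }
  z <- stats::qnorm(1 - (1 - config$ci_level) / 2)
  mu <- as.numeric(pr$fit)
  se <- as.numeric(pr$se.fit)
  if (config$family == "poisson") {           # bands on the response scale
    lower <- exp(mu - z * se); upper <- exp(mu + z * se); mu <- exp(mu)
  } else {
    lower <- mu - z * se; upper <- mu + z * se
  }
  list(grid = grid, mean = mu, se = se, lower = lower, upper = upper,
       edf = sum(fit$edf), model = fit)
}

#' Fit a smooth seasonal curve to one group x phase
#'
#' Fits a penalized cubic regression spline of the (fractional) cell count on
#' season day, with a random intercept per tree to absorb repeated measures,
#' and returns the population-level curve with pointwise confidence bands.
#' The fit itself is unconstrained; negative fitted values are clipped to
#' zero only downstream (kinetics, reports), never inside the optimizer.
#'
#' @param data data frame with columns `tree_id`, `season_day` and `count`
#'   (per-tree per-date mean counts for a single group and phase, as produced
#'   by [average_radial_files()]).
#' @param config a [smooth_config()].
#' @param group,phase labels carried into the result.
#' @param grid optional prediction grid of season days; defaults to the
#'   observed range at `grid_step` spacing.
#' @return object of class `phase_curve`: list with `group`, `phase`, `grid`,
#'   `mean`, `se`, `lower`, `upper`, `edf`.
#' @export
fit_phase_curve <- function(data, config = smooth_config(),
                            group = NA_character_, phase = NA_character_,
                            grid = NULL) {
  .require_columns(data, c("tree_id", "season_day", "count"), "phase data")
  f <- .fit_smooth(data$season_day, data$count, data$tree_id, config, grid)
  structure(list(group = group, phase = phase, grid = f$grid, mean = f$mean,
                 se = f$se, lower = f$lower, upper = f$upper, edf = f$edf,
                 ci_level = config$ci_level),
            class = "phase_curve")
}

#' @export
print.phase_curve <- function(x, ...) {
  cat(sprintf("phase_curve: group=%s phase=%s | %d grid points [%g, %g]\n",
              x$group, x$phase, length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("  fitted range [%.3f, %.3f] cells, edf %.2f, %g%% pointwise CI\n",
              min(x$mean), max(x$mean), x$edf, 100 * x$ci_level))
  invisible(x)
}

#' Fit curves for every group and phase
#'
#' @param avg per-tree per-date mean counts ([average_radial_files()] output).
#' @param config a [smooth_config()].
#' @param grid optional shared season-day grid; defaults to the full observed
#'   range so that all groups share one grid (required by the comparison and
#'   kinetics stages).
#' @return nested list: `curves[[group]][[phase]]`, phases named `cambial`,
#'   `enlarging`, `thickening`, `mature`.
#' @export
fit_phase_curves <- function(avg, config = smooth_config(), grid = NULL) {
  phases <- c(cambial = "n_cambial", enlarging = "n_enlarging",
              thickening = "n_thickening", mature = "n_mature")
  if (is.null(grid))
    grid <- seq(min(avg$season_day), max(avg$season_day),
                by = config$grid_step)
  out <- list()
  for (g in unique(avg$group)) {
    sub <- avg[avg$group == g, ]
    out[[g]] <- lapply(names(phases), function(ph) {
      d <- data.frame(tree_id = sub$tree_id, season_day = sub$season_day,
                      count = sub[[phases[[ph]]]])
      fit_phase_curve(d, config, group = g, phase = ph, grid = grid)
    })
    names(out[[g]]) <- names(phases)
  }
  out
}

#' Flatten fitted curves to a tidy table
#'
#' Fitted values are clipped at zero for reporting (counts cannot be
#' negative); the `phase_curve` objects themselves are left unclipped.
#'
#' @param curves nested list from [fit_phase_curves()], or a list of
#'   `phase_curve` objects.
#' @return data frame with columns `group, phase, season_day, mean, lower,
#'   upper`.
#' @export
curves_to_df <- function(curves) {
  flat <- if (inherits(curves, "phase_curve")) list(curves)
          else unlist(curves, recursive = FALSE)
  rows <- lapply(flat, function(cv) {
    data.frame(group = cv$group, phase = cv$phase, season_day = cv$grid,
               mean = pmax(cv$mean, 0), lower = pmax(cv$lower, 0),
               upper = pmax(cv$upper, 0))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Compare two fitted curves by confidence-band overlap
#'
#' Two groups are taken to differ wherever their pointwise confidence bands
#' are disjoint. Windows are maximal runs of grid points with disjoint bands;
#' endpoints are refined to sub-grid precision by linearly interpolating the
#' band gap `max(a.lower - b.upper, b.lower - a.upper)` to its zero crossing.
#'
#' @param a,b `phase_curve` objects on identical grids.
#' @return object of class `significance_windows`: data frame with columns
#'   `start_day`, `end_day` (possibly zero rows), with attributes `phase` and
#'   `pair`.
#' @export
compare_groups <- function(a, b) {
  if (length(a$grid) != length(b$grid) ||
      max(abs(a$grid - b$grid)) > 1e-8)
    stop("curves must share an identical grid", call. = FALSE)
  t <- a$grid
  gap <- pmax(a$lower - b$upper, b$lower - a$upper)
  disjoint <- gap > 0
  windows <- data.frame(start_day = numeric(0), end_day = numeric(0))
  if (any(disjoint)) {
    r <- rle(disjoint)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      i0 <- starts[j]; i1 <- ends[j]
      s <- if (i0 == 1) t[1] else {
        # zero crossing of gap between i0-1 (<=0) and i0 (>0)
        t[i0 - 1] + (0 - gap[i0 - 1]) / (gap[i0] - gap[i0 - 1]) *
          (t[i0] - t[i0 - 1])
      }
      e <- if (i1 == length(t)) t[length(t)] else {
        t[i1] + (0 - gap[i1]) / (gap[i1 + 1] - gap[i1]) * (t[i1 + 1] - t[i1])
      }
      windows <- rbind(windows, data.frame(start_day = s, end_day = e))
    }
  }
  structure(windows, class = c("significance_windows", "data.frame"),
            phase = if (identical(a$phase, b$phase)) a$phase else NA_character_,
            pair = c(a$group, b$group))
}

#' @export
print.significance_windows <- function(x, ...) {
  pair <- attr(x, "pair")
  cat(sprintf("significance windows (%s vs %s, phase %s): %d window(s)\n",
              pair[1], pair[2], attr(x, "phase"), nrow(x)))
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}
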