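#' Build a tracheidogram with relative in-ring positions
#'
#' A tracheidogram is the ordered pith-to-bark profile of tracheid
#' dimensions across one ring. Each cell occupies a radial slab of width
#' `radial_diameter = LD + 2*CWT`; its center sits at the cumulative sum of
#' the preceding widths plus half its own, and its *relative position* is
#' that center divided by the total ring width, putting rings with different
#' cell numbers on a common (0,1) axis.
#'
#' @param cells data frame of ordered tracheids (ring start first) with
#'   columns `lumen_diameter` and `wall_thickness` (micrometres); optional
#'   `tree_id`, `radial_file` are carried through.
#' @return object of class `tracheidogram`: list with `cells` (input plus
#'   `radial_diameter`, `center`, `rel_pos`), `ring_width` (micrometres) and
#'   `n_cells`.
#' @export
tracheidogram <- function(cells) {
  .require_columns(cells, c("lumen_diameter", "wall_thickness"),
                   "tracheidogram cells")
  if (nrow(cells) < 1) stop("tracheidogram needs at least one cell",
                            call. = FALSE)
  bad <- which(cells$lumen_diameter <= 0 | cells$wall_thickness <= 0)
  if (length(bad))
    stop(sprintf("non-positive tracheid dimension at cell %d", bad[1]),
         call. = FALSE)
  D <- cells$lumen_diameter + 2 * cells$wall_thickness
  cs <- cumsum(D)
  ring_width <- cs[length(cs)]
  cells$radial_diameter <- D
  cells$center <- cs - D / 2
  cells$rel_pos <- cells$center / ring_width
  structure(list(cells = cells, ring_width = ring_width,
                 n_cells = nrow(cells)),
            class = "tracheidogram")
}

#' @export
print.tracheidogram <- function(x, ...) {
  cat(sprintf("tracheidogram: %d cells, ring width %.1f um\n",
              x$n_cells, x$ring_width))
  cat(sprintf("  LD %.1f-%.1f um, CWT %.2f-%.2f um\n",
              min(x$cells$lumen_diameter), max(x$cells$lumen_diameter),
              min(x$cells$wall_thickness), max(x$cells$wall_thickness)))
  invisible(x)
}

#' Resample a tracheidogram onto an even relative-position grid
#'
#' Lumen diameter and wall thickness are linearly interpolated from the
#' (rel_pos, value) pairs onto the midpoint grid `(i - 0.5) / n_points`,
#' with constant extrapolation before the first and after the last cell
#' center. With `n_points` equal to the cell count and equal cell widths the
#' grid coincides with the cell centers and the original values are returned
#' exactly.
#'
#' @param t a [tracheidogram()].
#' @param n_points number of grid points (>= 2).
#' @return object of class `standardized_profile`: data frame with columns
#'   `rel_pos`, `lumen_diameter`, `wall_thickness`.
#' @export
standardize_profile <- function(t, n_points) {
  stopifnot(inherits(t, "tracheidogram"))
  if (n_points < 2) stop("n_points must be at least 2", call. = FALSE)
  grid <- (seq_len(n_points) - 0.5) / n_points
  cells <- t$cells
  interp <- function(v) {
    if (nrow(cells) < 2) return(rep(v[1], n_points))   # degenerate: constant
    stats::approx(cells$rel_pos, v, xout = grid, rule = 2)$y
  }
  structure(data.frame(rel_pos = grid,
                       lumen_diameter = interp(cells$lumen_diameter),
                       wall_thickness = interp(cells$wall_thickness)),
            class = c("standardized_profile", "data.frame"))
}

#' Per-tree tracheidograms from a tracheid table
#'
#' @param df validated tracheid table ([read_tracheids()] schema).
#' @return data frame with one row per tracheid and added `rel_pos`,
#'   `radial_diameter`, `center` columns (positions computed within each
#'   tree x radial file ring).
#' @export
tracheid_positions <- function(df) {
  df <- validate_tracheids(df)
  key <- paste(df$tree_id, df$radial_file, sep = "\r")
  parts <- lapply(unique(key), function(k) {
    sub <- df[key == k, ]
    sub <- sub[order(sub$cell_index), ]
    tg <- tracheidogram(sub)
    tg$cells
  })
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

#' Compare tracheid trait profiles between groups
#'
#' Fits the package smoother (cubic regression spline + random intercept per
#' tree) to a trait against relative in-ring position for each group, and
#' reports windows of relative position where the pointwise confidence bands
#' of a group pair are disjoint.
#'
#' @param df tracheid table with at least two groups.
#' @param trait `"wall_thickness"` or `"lumen_diameter"`.
#' @param config a [smooth_config()]; `grid_step` is ignored (the profile is
#'   evaluated at `n_grid` midpoints on (0,1)).
#' @param n_grid number of relative-position grid points (default 200).
#' @return list with `curves` (per group, `phase_curve`-style objects whose
#'   grid is relative position) and `windows` (one `significance_windows`
#'   per group pair, named "A vs B").
#' @export
compare_trait_profiles <- function(df, trait = c("wall_thickness",
                                                 "lumen_diameter"),
                                   config = smooth_config(), n_grid = 200) {
  trait <- match.arg(trait)
  pos <- tracheid_positions(df)
  groups <- unique(pos$group)
  if (length(groups) < 2)
    stop("need at least two groups to compare", call. = FALSE)
  grid <- (seq_len(n_grid) - 0.5) / n_grid
  curves <- lapply(groups, function(g) {
    sub <- pos[pos$group == g, ]
    f <- .fit_smooth(sub$rel_pos, sub[[trait]], sub$tree_id, config, grid)
    structure(list(group = g, phase = trait, grid = f$grid, mean = f$mean,
                   se = f$se, lower = f$lower, upper = f$upper, edf = f$edf,
                   ci_level = config$ci_level),
              class = "phase_curve")
  })
  names(curves) <- groups
  windows <- list()
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (i < j) {
      nm <- paste(groups[i], "vs", groups[j])
      windows[[nm]] <- compare_groups(curves[[i]], curves[[j]])
    }
  }
  list(curves = curves, windows = windows)
}

#' Earlywood / latewood split by Mork's index
#'
#' A tracheid is classed latewood when twice the double wall width reaches
#' the lumen diameter, i.e. `4 * CWT >= LD` (Mork's criterion, the field
#' default; the multiplier is configurable).
#'
#' @param t a [tracheidogram()].
#' @param multiplier wall multiplier in the criterion (default 4).
#' @return named integer vector `c(earlywood = , latewood = )`.
#' @export
earlywood_latewood_split <- function(t, multiplier = 4) {
  stopifnot(inherits(t, "tracheidogram"))
  lw <- multiplier * t$cells$wall_thickness >= t$cells$lumen_diameter
  c(earlywood = sum(!lw), latewood = sum(lw))
}
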