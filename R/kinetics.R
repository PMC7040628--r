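#' Cumulative phase-entry curves from fitted counts
#'
#' A tracheid that has reached a later differentiation phase has necessarily
#' passed through all earlier ones, so the cumulative number of cells that
#' have *entered* each phase by time t is obtained by summing the fitted
#' standing counts of that phase and all later ones:
#' `C_E = E + L + M`, `C_L = L + M`, `C_M = M`.
#' Fitted phase counts are clipped at zero first, and each cumulative curve
#' is then monotonized by a running maximum (the increasing envelope keeps
#' crossing times of the underlying entry process).
#'
#' @param curves named list of `phase_curve` objects for one group containing
#'   at least `enlarging`, `thickening` and `mature`, all on one grid.
#' @return object of class `cum_curves`: list with `grid`, monotone `C_E`,
#'   `C_L`, `C_M`, the pre-monotonization `raw` curves, and the clipped
#'   per-phase fits used to build them.
#' @export
cumulative_entry_curves <- function(curves) {
  need <- c("enlarging", "thickening", "mature")
  if (!all(need %in% names(curves)))
    stop("curves must contain 'enlarging', 'thickening' and 'mature'",
         call. = FALSE)
  grid <- curves$enlarging$grid
  for (ph in need) {
    g <- curves[[ph]]$grid
    if (length(g) != length(grid) || max(abs(g - grid)) > 1e-8)
      stop("phase curves must share an identical grid", call. = FALSE)
  }
  E <- pmax(curves$enlarging$mean, 0)
  L <- pmax(curves$thickening$mean, 0)
  M <- pmax(curves$mature$mean, 0)
  raw <- list(C_E = E + L + M, C_L = L + M, C_M = M)
  structure(list(grid = grid,
                 C_E = cummax(raw$C_E), C_L = cummax(raw$C_L),
                 C_M = cummax(raw$C_M),
                 raw = raw,
                 phase_clipped = list(enlarging = E, thickening = L,
                                      mature = M)),
            class = "cum_curves")
}

#' Conservation diagnostic for cumulative curves
#'
#' By construction `C_E - C_L` equals the clipped fitted count of enlarging
#' cells wherever monotonization did not fire; the maximum absolute
#' discrepancy over the grid is reported as a diagnostic of how much the
#' running-maximum repair distorted the standing counts.
#'
#' @param cums a [cumulative_entry_curves()] result.
#' @return maximum absolute discrepancy (cells).
#' @export
conservation_diagnostic <- function(cums) {
  max(abs((cums$C_E - cums$C_L) - cums$phase_clipped$enlarging))
}

#' Entrance date of the i-th cell into a phase
#'
#' The entrance date of cell i is the first time the cumulative entry curve
#' crosses level i, located by linear interpolation between the bracketing
#' grid points. If the curve already starts at or above i the first grid
#' time is returned (the crossing predates the observation window). Cells
#' beyond the curve's maximum are "not formed" and get `NA`.
#'
#' @param curve list with numeric `grid` and monotone non-decreasing `value`
#'   (e.g. `list(grid = cums$grid, value = cums$C_E)`).
#' @param i vector of 1-based cell indices.
#' @return season days (NA where cell i never enters the phase).
#' @export
entrance_date <- function(curve, i) {
  grid <- curve$grid; v <- curve$value
  stopifnot(length(grid) == length(v))
  vapply(i, function(ii) {
    if (ii > max(v)) return(NA_real_)
    if (v[1] >= ii) return(grid[1])
    k <- which(v >= ii)[1]
    grid[k - 1] + (ii - v[k - 1]) / (v[k] - v[k - 1]) * (grid[k] - grid[k - 1])
  }, numeric(1))
}

#' Per-cell differentiation kinetics for one group
#'
#' For each whole cell i up to `floor(max(C_E))`, computes the entrance dates
#' into enlargement, wall thickening and maturity, the residence durations
#' `d_E = t_thick - t_enl` (enlargement) and `d_T = t_mature - t_thick`
#' (wall deposition), and — when a group-mean tracheidogram profile is
#' attached — the mean enlargement rate `r_enl = LD / d_E` and wall
#' deposition rate `r_wall = CWT / d_T` (micrometres per day). Cell i is
#' matched to the anatomy at ring quantile `(i - 0.5) / n`.
#'
#' @param cums a [cumulative_entry_curves()] result.
#' @param anatomy optional anatomy source: a `standardized_profile`, a
#'   `tracheidogram`, or a data frame with columns `rel_pos`,
#'   `lumen_diameter`, `wall_thickness`.
#' @param group label carried into the result.
#' @return data frame: `group, cell_index, t_enl, t_thick, t_mature, d_E,
#'   d_T` and, with anatomy, `lumen_diameter, wall_thickness, r_enl, r_wall`.
#' @export
cell_kinetics <- function(cums, anatomy = NULL, group = NA_character_) {
  n <- floor(max(cums$C_E))
  if (n < 1)
    return(data.frame(group = character(0), cell_index = integer(0),
                      t_enl = numeric(0), t_thick = numeric(0),
                      t_mature = numeric(0), d_E = numeric(0),
                      d_T = numeric(0)))
  i <- seq_len(n)
  t_enl <- entrance_date(list(grid = cums$grid, value = cums$C_E), i)
  t_thick <- entrance_date(list(grid = cums$grid, value = cums$C_L), i)
  t_mature <- entrance_date(list(grid = cums$grid, value = cums$C_M), i)
  out <- data.frame(group = group, cell_index = i, t_enl = t_enl,
                    t_thick = t_thick, t_mature = t_mature,
                    d_E = t_thick - t_enl, d_T = t_mature - t_thick)
  if (!is.null(anatomy)) {
    prof <- .as_anatomy_profile(anatomy)
    q <- (i - 0.5) / n
    resample <- function(v) {
      if (length(v) < 2) rep(v, n)
      else stats::approx(prof$rel_pos, v, xout = q, rule = 2)$y
    }
    out$lumen_diameter <- resample(prof$lumen_diameter)
    out$wall_thickness <- resample(prof$wall_thickness)
    out$r_enl <- ifelse(out$d_E > 0, out$lumen_diameter / out$d_E, NA_real_)
    out$r_wall <- ifelse(!is.na(out$d_T) & out$d_T > 0,
                         out$wall_thickness / out$d_T, NA_real_)
  }
  out
}

.as_anatomy_profile <- function(anatomy) {
  if (inherits(anatomy, "tracheidogram")) {
    return(data.frame(rel_pos = anatomy$cells$rel_pos,
                      lumen_diameter = anatomy$cells$lumen_diameter,
                      wall_thickness = anatomy$cells$wall_thickness))
  }
  .require_columns(anatomy, c("rel_pos", "lumen_diameter", "wall_thickness"),
                   "anatomy profile")
  anatomy
}

# centered finite difference; one-sided at the ends
.fd_derivative <- function(t, v) {
  n <- length(t)
  if (n < 3) stop("grid must have at least 3 points", call. = FALSE)
  d <- numeric(n)
  d[1] <- (v[2] - v[1]) / (t[2] - t[1])
  d[n] <- (v[n] - v[n - 1]) / (t[n] - t[n - 1])
  mid <- 2:(n - 1)
  d[mid] <- (v[mid + 1] - v[mid - 1]) / (t[mid + 1] - t[mid - 1])
  d
}

#' Seasonal production and differentiation rate curves
#'
#' Rates of cell entrance into enlargement (rE), wall deposition (rL) and
#' maturity (rM) are centered finite-difference derivatives of the monotone
#' cumulative entry curves, floored at zero. The cambial cell-division rate
#' rC is, by default, the derivative of `C_E + max(0, N_C(t) - N_C(start))`:
#' cells produced are the cells exported to enlargement plus any net growth
#' of the standing cambial pool. `rc_method = "entry"` reduces rC to rE.
#'
#' @param cums a [cumulative_entry_curves()] result.
#' @param cambial optional `phase_curve` of the cambial pool (needed for the
#'   default rC definition).
#' @param rc_method `"export_plus_pool"` (default) or `"entry"`.
#' @param group label carried into the result.
#' @return data frame: `group, kind, season_day, rate` (cells/day), with
#'   `kind` in rC, rE, rL, rM.
#' @export
production_rate_curves <- function(cums, cambial = NULL,
                                   rc_method = c("export_plus_pool", "entry"),
                                   group = NA_character_) {
  rc_method <- match.arg(rc_method)
  t <- cums$grid
  rates <- list(rE = pmax(.fd_derivative(t, cums$C_E), 0),
                rL = pmax(.fd_derivative(t, cums$C_L), 0),
                rM = pmax(.fd_derivative(t, cums$C_M), 0))
  if (rc_method == "export_plus_pool") {
    if (is.null(cambial))
      stop("cambial curve required for rc_method = 'export_plus_pool'",
           call. = FALSE)
    Nc <- pmax(cambial$mean, 0)
    pool_growth <- pmax(0, Nc - Nc[1])
    rates$rC <- pmax(.fd_derivative(t, cums$C_E + pool_growth), 0)
  } else {
    rates$rC <- rates$rE
  }
  do.call(rbind, lapply(c("rC", "rE", "rL", "rM"), function(k) {
    data.frame(group = group, kind = k, season_day = t, rate = rates[[k]])
  }))
}

#' Fit-free recovery of entrance dates from raw counts
#'
#' Bypasses the smoother entirely: for each tree, cumulative entry counts
#' are read off the observed counts (`E+L+M`, `L+M`, `M`, monotonized), and
#' cell i's entrance is estimated as the midpoint of the sampling interval
#' preceding its first detection. A count taken on day t only reveals that
#' the cell entered somewhere in `(t_prev, t]`; the interval midpoint is the
#' natural estimator for this interval censoring and bounds the error by
#' half the sampling interval. Used for recovery tests against simulator
#' ground truth and for quick fit-free looks at raw data.
#'
#' @param obs counts table (one or more trees; radial files are averaged
#'   first if the `radial_file` column is present).
#' @return data frame: `tree_id, group, phase, cell_index, t_est` with phase
#'   in `enlarging, thickening, mature`; `censored` flags cells already
#'   present at the first sampling day (their entry predates observation).
#' @export
recover_entrance_dates <- function(obs) {
  if ("radial_file" %in% names(obs)) obs <- average_radial_files(obs)
  out <- list()
  for (tr in unique(obs$tree_id)) {
    sub <- obs[obs$tree_id == tr, ]
    sub <- sub[order(sub$season_day), ]
    t <- sub$season_day
    step <- if (length(t) > 1) stats::median(diff(t)) else 1
    cum <- list(
      enlarging = cummax(sub$n_enlarging + sub$n_thickening + sub$n_mature),
      thickening = cummax(sub$n_thickening + sub$n_mature),
      mature = cummax(sub$n_mature))
    for (ph in names(cum)) {
      v <- cum[[ph]]
      n <- floor(max(v))
      if (n < 1) next
      first_idx <- vapply(seq_len(n), function(i) which(v >= i)[1],
                          integer(1))
      t_before <- c(t[1] - step, t[-length(t)])   # sampling day preceding each
      prev <- t_before[first_idx]
      out[[length(out) + 1]] <- data.frame(
        tree_id = tr, group = sub$group[1], phase = ph,
        cell_index = seq_len(n), t_est = (t[first_idx] + prev) / 2,
        censored = first_idx == 1)
    }
  }
  if (!length(out))
    return(data.frame(tree_id = character(0), group = character(0),
                      phase = character(0), cell_index = integer(0),
                      t_est = numeric(0), censored = logical(0)))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
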