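#' Per-group parameters for the wood-formation simulator
#'
#' Each simulated cell is indexed by its formation quantile
#' `q = (i - 0.5) / total_cells`. Entrance into enlargement is the inverse
#' CDF of a Gaussian production mixture at q (one component = unimodal
#' season, two = bimodal); residence durations and final dimensions are
#' simple functions of q: enlargement duration `d_E(q)` linear, wall
#' deposition duration `d_T(q)` linear, lumen diameter `LD(q)` a plateau
#' followed by a linear decline, wall thickness `CWT(q)` linear. The
#' standing cambial pool is a Gaussian bump on a base level.
#'
#' @param label group (treatment) label.
#' @param total_cells target tracheids per tree.
#' @param peaks data frame with columns `day`, `sd`, `weight` (weights sum
#'   to 1); one row per production pulse.
#' @param d_E length-2 numeric: enlargement duration (days) at q = 0 and
#'   q = 1.
#' @param d_T length-2 numeric: wall-deposition duration (days) at q = 0
#'   and q = 1.
#' @param LD list `plateau` (um), `plateau_end` (quantile), `final` (um).
#' @param CWT length-2 numeric: wall thickness (um) at q = 0 and q = 1.
#' @param pool list `base`, `peak` (cells), `peak_day`, `sd` (days).
#' @param tree_total_sd between-tree SD of total cells (cells).
#' @param tree_shift_sd between-tree SD of a whole-season timing shift
#'   (days).
#' @param anatomy_noise list `LD`, `CWT`: per-cell measurement noise SDs
#'   (um) applied to the emitted anatomy table (truth stays noiseless).
#' @return list of group parameters.
#' @export
group_params <- function(label, total_cells, peaks,
                         d_E = c(20, 8), d_T = c(20, 80),
                         LD = list(plateau = 40, plateau_end = 0.4,
                                   final = 10),
                         CWT = c(2.5, 8),
                         pool = list(base = 6, peak = 10, peak_day = 85,
                                     sd = 35),
                         tree_total_sd = 0, tree_shift_sd = 0,
                         anatomy_noise = list(LD = 0, CWT = 0)) {
  peaks <- as.data.frame(peaks)
  .require_columns(peaks, c("day", "sd", "weight"), "production peaks")
  if (abs(sum(peaks$weight) - 1) > 1e-8)
    stop("production peak weights must sum to 1", call. = FALSE)
  if (any(c(d_E, d_T) <= 0))
    stop("residence durations must be positive", call. = FALSE)
  if (total_cells < 1) stop("total_cells must be at least 1", call. = FALSE)
  list(label = label, total_cells = total_cells, peaks = peaks,
       d_E = d_E, d_T = d_T, LD = LD, CWT = CWT, pool = pool,
       tree_total_sd = tree_total_sd, tree_shift_sd = tree_shift_sd,
       anatomy_noise = anatomy_noise)
}

#' Simulator configuration
#'
#' @param groups list of [group_params()] (named by their labels).
#' @param n_trees trees per group.
#' @param sampling_days microcore sampling schedule (season days).
#' @param n_radial_files radial files counted per microcore.
#' @param noise observation noise: `list(type = "none")` (all files see the
#'   exact counts) or `list(type = "thinning", p = ...)` (each file detects
#'   each differentiated cell independently with probability p).
#' @param seed integer RNG seed; the whole experiment is reproducible from
#'   it.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(groups, n_trees = 5,
                              sampling_days = seq(60, 430, by = 10),
                              n_radial_files = 3,
                              noise = list(type = "none"), seed = 1) {
  labels <- vapply(groups, `[[`, character(1), "label")
  names(groups) <- labels
  if (!noise$type %in% c("none", "thinning"))
    stop("noise$type must be 'none' or 'thinning'", call. = FALSE)
  if (noise$type == "thinning" &&
      (is.null(noise$p) || noise$p <= 0 || noise$p > 1))
    stop("thinning noise needs a detection probability p in (0, 1]",
         call. = FALSE)
  structure(list(groups = groups, n_trees = n_trees,
                 sampling_days = sort(sampling_days),
                 n_radial_files = n_radial_files, noise = noise,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Quantile of a Gaussian mixture by root finding on the CDF.
.mixture_quantile <- function(q, peaks) {
  lo <- min(peaks$day - 10 * peaks$sd)
  hi <- max(peaks$day + 10 * peaks$sd)
  cdf <- function(t) sum(peaks$weight * stats::pnorm(t, peaks$day, peaks$sd))
  vapply(q, function(qq) {
    stats::uniroot(function(t) cdf(t) - qq, c(lo, hi), tol = 1e-9)$root
  }, numeric(1))
}

.tree_seed <- function(config, group_index, tree) {
  (config$seed + 7919L * group_index + 104729L * tree) %% .Machine$integer.max
}

#' Simulate one tree's cohort of tracheids
#'
#' Deterministic given the configuration: cell i enters enlargement at the
#' production-mixture quantile `(i - 0.5) / n`, shifted by the tree's
#' timing effect; durations and dimensions come from the q-models. The
#' tree's total cell count and timing shift are the only random tree
#' effects, drawn from a seed derived from (config seed, group, tree).
#'
#' @param config a [simulation_config()].
#' @param group group label.
#' @param tree tree number within the group (1-based).
#' @return list with `tree_id`, `group`, `cells` (data frame of true
#'   `cell_index, q, t_enl, t_thick, t_mature, d_E, d_T, LD, CWT`), `shift`,
#'   and `pool` (function of season day giving the cambial pool size).
#' @export
simulate_cohort <- function(config, group, tree) {
  stopifnot(inherits(config, "simulation_config"))
  g <- config$groups[[group]]
  if (is.null(g)) stop("unknown group: ", group, call. = FALSE)
  gi <- match(group, names(config$groups))
  set.seed(.tree_seed(config, gi, tree))
  n <- max(1L, as.integer(round(g$total_cells +
                                  stats::rnorm(1, 0, g$tree_total_sd))))
  shift <- stats::rnorm(1, 0, g$tree_shift_sd)
  q <- (seq_len(n) - 0.5) / n
  t_enl <- .mixture_quantile(q, g$peaks) + shift
  d_E <- g$d_E[1] + (g$d_E[2] - g$d_E[1]) * q
  d_T <- g$d_T[1] + (g$d_T[2] - g$d_T[1]) * q
  pe <- g$LD$plateau_end
  LD <- ifelse(q <= pe, g$LD$plateau,
               g$LD$plateau + (g$LD$final - g$LD$plateau) * (q - pe) / (1 - pe))
  CWT <- g$CWT[1] + (g$CWT[2] - g$CWT[1]) * q
  cells <- data.frame(cell_index = seq_len(n), q = q, t_enl = t_enl,
                      t_thick = t_enl + d_E, t_mature = t_enl + d_E + d_T,
                      d_E = d_E, d_T = d_T, LD = LD, CWT = CWT)
  pool <- local({
    base <- g$pool$base; peak <- g$pool$peak
    day0 <- g$pool$peak_day + shift; psd <- g$pool$sd
    function(t) base + (peak - base) * exp(-((t - day0) / psd)^2)
  })
  list(tree_id = sprintf("%s_t%d", group, tree), group = group,
       cells = cells, shift = shift, pool = pool)
}

#' Observe a simulated cohort as microcore counts
#'
#' At each sampling day t a cell is enlarging iff `t_enl <= t < t_thick`,
#' wall-thickening iff `t_thick <= t < t_mature`, and mature iff
#' `t >= t_mature`. The cambial count is the pool curve rounded to whole
#' cells. Under `"none"` noise all radial files report the exact counts;
#' under `"thinning"` each file detects each differentiated cell
#' independently with probability p (counts stay integer and non-negative).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param sampling_days observation days.
#' @param n_files radial files per microcore.
#' @param noise noise spec as in [simulation_config()].
#' @return counts table in the [read_counts()] schema.
#' @export
observe_counts <- function(cohort, sampling_days, n_files = 3,
                           noise = list(type = "none")) {
  cells <- cohort$cells
  rows <- vector("list", length(sampling_days) * n_files)
  k <- 0
  for (t in sampling_days) {
    nC <- as.integer(round(cohort$pool(t)))
    enl <- cells$t_enl <= t & t < cells$t_thick
    thk <- cells$t_thick <= t & t < cells$t_mature
    mat <- t >= cells$t_mature
    for (f in seq_len(n_files)) {
      if (noise$type == "thinning") {
        seen <- stats::runif(nrow(cells)) <= noise$p
        e <- sum(enl & seen); l <- sum(thk & seen); m <- sum(mat & seen)
      } else {
        e <- sum(enl); l <- sum(thk); m <- sum(mat)
      }
      k <- k + 1
      rows[[k]] <- data.frame(tree_id = cohort$tree_id, group = cohort$group,
                              season_day = t, radial_file = f,
                              n_cambial = nC, n_enlarging = e,
                              n_thickening = l, n_mature = m)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Simulate a full wood-formation experiment
#'
#' Runs [simulate_cohort()] and [observe_counts()] for every tree in every
#' group and assembles the three tables the analysis pipeline consumes:
#' ground-truth cell timelines, microcore counts, and the end-of-season
#' tracheid anatomy table (one radial file per tree, with optional
#' measurement noise on the dimensions).
#'
#' @param config a [simulation_config()].
#' @return list with `truth`, `counts` and `tracheids` data frames.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- list(); counts <- list(); trach <- list()
  for (group in names(config$groups)) {
    g <- config$groups[[group]]
    for (tree in seq_len(config$n_trees)) {
      cohort <- simulate_cohort(config, group, tree)
      # simulate_cohort seeded this tree's stream; observation noise and
      # anatomy noise continue the same stream, so replay is exact.
      obs <- observe_counts(cohort, config$sampling_days,
                            config$n_radial_files, config$noise)
      tr <- cbind(tree_id = cohort$tree_id, group = group, cohort$cells)
      ld <- cohort$cells$LD +
        stats::rnorm(nrow(cohort$cells), 0, g$anatomy_noise$LD)
      cwt <- cohort$cells$CWT +
        stats::rnorm(nrow(cohort$cells), 0, g$anatomy_noise$CWT)
      anat <- data.frame(tree_id = cohort$tree_id, group = group,
                         radial_file = 1L,
                         cell_index = cohort$cells$cell_index,
                         lumen_diameter = pmax(ld, 1),
                         wall_thickness = pmax(cwt, 0.3))
      truth[[length(truth) + 1]] <- tr
      counts[[length(counts) + 1]] <- obs
      trach[[length(trach) + 1]] <- anat
    }
  }
  list(truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       counts = do.call(rbind, c(counts, list(make.row.names = FALSE))),
       tracheids = do.call(rbind, c(trach, list(make.row.names = FALSE))))
}

#' Default simulation scenario: a Mediterranean drought-manipulation season
#'
#' Three treatment groups of five maritime-pine-like trees sampled every 10
#' days from season day 60 to 430. Control trees form 41 tracheids with a
#' bimodal production season (spring pulse around day 90, autumn pulse
#' around day 295); irrigated trees form 30 with the same bimodal shape;
#' rain-excluded trees form 26 in a single spring pulse, enlarge more slowly
#' (about 25 days for the first cells vs 20), deposit wall for up to 120
#' days (vs 80 control, 60 irrigation) and cap latewood wall thickness at
#' 6 um (vs 8). Lumen diameter plateaus at 40 um over the first 40% of the
#' ring and declines to 10 um; the cambial pool peaks at 10 cells (control)
#' or 8 (others) in early spring. Between-tree SDs are 5.6 cells for season
#' totals and 3 days for timing.
#'
#' @param seed RNG seed for the experiment.
#' @return a [simulation_config()].
#' @export
default_paper_scenario <- function(seed = 1) {
  bimodal <- function(w_autumn)
    data.frame(day = c(90, 295), sd = c(13, 14),
               weight = c(1 - w_autumn, w_autumn))
  groups <- list(
    group_params("control", total_cells = 41, peaks = bimodal(0.2),
                 d_E = c(20, 8), d_T = c(20, 80), CWT = c(2.5, 8),
                 pool = list(base = 6.5, peak = 10, peak_day = 85, sd = 35),
                 tree_total_sd = 5.6, tree_shift_sd = 3,
                 anatomy_noise = list(LD = 2, CWT = 0.4)),
    group_params("irrigation", total_cells = 30, peaks = bimodal(0.22),
                 d_E = c(20, 8), d_T = c(20, 60), CWT = c(2.5, 8),
                 pool = list(base = 6.5, peak = 8, peak_day = 85, sd = 35),
                 tree_total_sd = 5.6, tree_shift_sd = 3,
                 anatomy_noise = list(LD = 2, CWT = 0.4)),
    group_params("exclusion", total_cells = 26,
                 peaks = data.frame(day = 90, sd = 13, weight = 1),
                 d_E = c(25, 10), d_T = c(20, 120), CWT = c(2.5, 6),
                 pool = list(base = 5, peak = 8, peak_day = 85, sd = 35),
                 tree_total_sd = 5.6, tree_shift_sd = 3,
                 anatomy_noise = list(LD = 2, CWT = 0.4)))
  simulation_config(groups, n_trees = 5,
                    sampling_days = seq(60, 430, by = 10),
                    n_radial_files = 3, noise = list(type = "none"),
                    seed = seed)
}
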