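# In-code fixtures shared across test files.

# minimal valid counts table: one tree, given days/files
make_counts <- function(tree = "t1", group = "control", days = c(60, 70),
                        files = 1L, C = 5, E = 1, L = 0, M = 0) {
  expand.grid(season_day = days, radial_file = seq_len(files),
              KEEP.OUT.ATTRS = FALSE) |>
    (\(g) data.frame(tree_id = tree, group = group,
                     season_day = g$season_day,
                     radial_file = g$radial_file,
                     n_cambial = C, n_enlarging = E, n_thickening = L,
                     n_mature = M))()
}

# ordered tracheid ring for one tree/file
make_ring <- function(tree = "t1", group = "a", LD, CWT, file = 1L) {
  data.frame(tree_id = tree, group = group, radial_file = file,
             cell_index = seq_along(LD), lumen_diameter = LD,
             wall_thickness = CWT)
}

# multi-tree noisy observations of a known mean function f(day)
make_curve_data <- function(f, n_trees = 5, days, sd = 0.5, seed = 42) {
  set.seed(seed)
  dat <- expand.grid(tree_id = paste0("t", seq_len(n_trees)),
                     season_day = days, KEEP.OUT.ATTRS = FALSE)
  dat$count <- f(dat$season_day) + stats::rnorm(nrow(dat), 0, sd)
  dat
}

# hand-built phase_curve with given bands on a grid
make_band <- function(grid, mean, lower, upper, group = "g",
                      phase = "thickening") {
  structure(list(group = group, phase = phase, grid = grid,
                 mean = mean, se = (upper - lower) / (2 * 1.96),
                 lower = lower, upper = upper, edf = NA, ci_level = 0.95),
            class = "phase_curve")
}

# hand-built cum_curves object from monotone components
make_cums <- function(grid, E, L, M) {
  raw <- list(C_E = E + L + M, C_L = L + M, C_M = M)
  structure(list(grid = grid, C_E = cummax(raw$C_E), C_L = cummax(raw$C_L),
                 C_M = cummax(raw$C_M), raw = raw,
                 phase_clipped = list(enlarging = E, thickening = L,
                                      mature = M)),
            class = "cum_curves")
}

# small two-group simulation used by pipeline tests (fast)
small_sim <- function(seed = 5) {
  groups <- list(
    group_params("a", total_cells = 20,
                 peaks = data.frame(day = 90, sd = 12, weight = 1),
                 d_E = c(15, 8), d_T = c(15, 50), CWT = c(2.5, 7),
                 pool = list(base = 5, peak = 8, peak_day = 85, sd = 30),
                 tree_total_sd = 2, tree_shift_sd = 2,
                 anatomy_noise = list(LD = 1, CWT = 0.2)),
    group_params("b", total_cells = 12,
                 peaks = data.frame(day = 95, sd = 12, weight = 1),
                 d_E = c(18, 10), d_T = c(15, 60), CWT = c(2.5, 5),
                 pool = list(base = 4, peak = 7, peak_day = 85, sd = 30),
                 tree_total_sd = 2, tree_shift_sd = 2,
                 anatomy_noise = list(LD = 1, CWT = 0.2)))
  simulation_config(groups, n_trees = 3,
                    sampling_days = seq(60, 300, by = 10),
                    n_radial_files = 2, noise = list(type = "none"),
                    seed = seed)
}
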