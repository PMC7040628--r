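#' Pipeline configuration
#'
#' @param counts path to a counts CSV, or a counts data frame; `NULL` when
#'   simulating.
#' @param tracheids optional path to a tracheid CSV, or data frame.
#' @param sim_config optional [simulation_config()]; when given, inputs are
#'   simulated instead of read (`counts`/`tracheids` must then be `NULL`).
#' @param out_dir output directory (created if missing).
#' @param seed integer seed; overrides `sim_config$seed` when simulating.
#' @param smooth a [smooth_config()].
#' @param threshold phenology activity threshold, cells.
#' @param min_prominence,min_separation modality parameters
#'   ([classify_modality()]).
#' @param rc_method cambial rate definition ([production_rate_curves()]).
#' @param profile_points relative-position grid size for trait profiles.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, tracheids = NULL,
                            sim_config = NULL, out_dir, seed = 1,
                            smooth = smooth_config(), threshold = 0.5,
                            min_prominence = 0.2, min_separation = 60,
                            rc_method = "export_plus_pool",
                            profile_points = 100) {
  if (is.null(counts) && is.null(sim_config))
    stop("either counts or sim_config must be provided", call. = FALSE)
  structure(list(counts = counts, tracheids = tracheids,
                 sim_config = sim_config, out_dir = out_dir,
                 seed = as.integer(seed), smooth = smooth,
                 threshold = threshold, min_prominence = min_prominence,
                 min_separation = min_separation, rc_method = rc_method,
                 profile_points = profile_points),
            class = "pipeline_config")
}

.write_tidy <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# group-mean standardized anatomy profile from a tracheid table
.group_profile <- function(trach, group, n_points) {
  sub <- trach[trach$group == group, ]
  key <- paste(sub$tree_id, sub$radial_file, sep = "\r")
  profs <- lapply(unique(key), function(k) {
    ring <- sub[key == k, ]
    ring <- ring[order(ring$cell_index), ]
    standardize_profile(tracheidogram(ring), n_points)
  })
  grid <- (seq_len(n_points) - 0.5) / n_points
  data.frame(
    rel_pos = grid,
    lumen_diameter = rowMeans(sapply(profs, `[[`, "lumen_diameter")),
    wall_thickness = rowMeans(sapply(profs, `[[`, "wall_thickness")))
}

# per-tree season totals (cells produced) from averaged counts
.tree_totals <- function(avg) {
  tot <- avg$n_enlarging + avg$n_thickening + avg$n_mature
  agg <- stats::aggregate(list(total = tot),
                          by = list(tree_id = avg$tree_id, group = avg$group),
                          FUN = max)
  agg[order(agg$group, agg$tree_id), ]
}

#' Run the full xylogenesis analysis pipeline
#'
#' Reads (or simulates) the input tables, smooths phase counts per group,
#' compares groups by confidence-band overlap, inverts the curves into
#' per-cell kinetics and rate curves, standardizes tracheid trait profiles,
#' derives phenology metrics, and runs the group-level statistics. Writes
#' `fitted_curves.csv`, `significance_windows.csv`, `kinetics.csv`,
#' `rates.csv`, `profiles.csv`, `phenology.csv`, `stats.csv`, a
#' `units.csv` sidecar describing the units of every output column, and a
#' `manifest.json` echoing the configuration. Output is byte-identical for
#' a fixed configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a named list of the written file paths plus the main
#'   in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)

  trach <- NULL
  if (!is.null(config$sim_config)) {
    sim <- config$sim_config
    sim$seed <- config$seed
    sims <- simulate_experiment(sim)
    counts <- sims$counts
    trach <- sims$tracheids
    .write_tidy(sims$truth, p("simulated_truth.csv"))
  } else {
    counts <- if (is.character(config$counts)) read_counts(config$counts)
              else validate_counts(config$counts)
    if (!is.null(config$tracheids)) {
      trach <- if (is.character(config$tracheids))
                 read_tracheids(config$tracheids)
               else validate_tracheids(config$tracheids)
    }
  }

  avg <- average_radial_files(counts)
  groups <- sort(unique(avg$group))
  curves <- fit_phase_curves(avg, config$smooth)
  .write_tidy(curves_to_df(curves), p("fitted_curves.csv"))

  # --- band-overlap comparisons, per phase and group pair
  win_rows <- list()
  for (ph in c("cambial", "enlarging", "thickening", "mature")) {
    for (i in seq_along(groups)) for (j in seq_along(groups)) if (i < j) {
      w <- compare_groups(curves[[groups[i]]][[ph]], curves[[groups[j]]][[ph]])
      if (nrow(w))
        win_rows[[length(win_rows) + 1]] <- data.frame(
          comparison = ph, group_a = groups[i], group_b = groups[j],
          start = w$start_day, end = w$end_day)
    }
  }

  # --- kinetics, rates, phenology per group
  kin_rows <- list(); rate_rows <- list()
  kinetics_by_group <- list()
  for (g in groups) {
    cums <- cumulative_entry_curves(curves[[g]])
    anatomy <- if (!is.null(trach))
      .group_profile(trach, g, config$profile_points) else NULL
    if (!is.null(anatomy))
      names(anatomy) <- c("rel_pos", "lumen_diameter", "wall_thickness")
    kin <- cell_kinetics(cums, anatomy = anatomy, group = g)
    kinetics_by_group[[g]] <- kin
    kin_rows[[g]] <- kin
    rate_rows[[g]] <- production_rate_curves(
      cums, cambial = curves[[g]]$cambial, rc_method = config$rc_method,
      group = g)
  }
  kin_all <- do.call(rbind, c(unname(kin_rows), list(make.row.names = FALSE)))
  .write_tidy(kin_all, p("kinetics.csv"))
  .write_tidy(do.call(rbind, c(unname(rate_rows),
                               list(make.row.names = FALSE))),
              p("rates.csv"))

  phen <- phenology_metrics(curves, config$threshold, config$min_prominence,
                            config$min_separation)
  .write_tidy(phen, p("phenology.csv"))

  # --- tracheid trait profiles and their group comparisons
  if (!is.null(trach)) {
    prof_rows <- lapply(groups, function(g) {
      pr <- .group_profile(trach, g, config$profile_points)
      cbind(group = g, pr)
    })
    .write_tidy(do.call(rbind, c(prof_rows, list(make.row.names = FALSE))),
                p("profiles.csv"))
    if (length(groups) >= 2) {
      for (trait in c("wall_thickness", "lumen_diameter")) {
        cmp <- compare_trait_profiles(trach, trait, config$smooth)
        for (nm in names(cmp$windows)) {
          w <- cmp$windows[[nm]]
          pair <- attr(w, "pair")
          if (nrow(w))
            win_rows[[length(win_rows) + 1]] <- data.frame(
              comparison = trait, group_a = pair[1], group_b = pair[2],
              start = w$start_day, end = w$end_day)
        }
      }
    }
  } else {
    .write_tidy(data.frame(group = character(0), rel_pos = numeric(0),
                           lumen_diameter = numeric(0),
                           wall_thickness = numeric(0)),
                p("profiles.csv"))
  }
  wins <- if (length(win_rows))
    do.call(rbind, c(win_rows, list(make.row.names = FALSE)))
  else data.frame(comparison = character(0), group_a = character(0),
                  group_b = character(0), start = numeric(0),
                  end = numeric(0))
  .write_tidy(wins, p("significance_windows.csv"))

  # --- group-level statistics
  stat_rows <- list()
  add_anova <- function(test, an) {
    rows <- data.frame(test = test, component = "omnibus",
                       statistic = an$F, df1 = an$df_between,
                       df2 = an$df_within, p = an$p, estimate = NA_real_,
                       lower = NA_real_, upper = NA_real_)
    rows <- rbind(rows, data.frame(
      test = test, component = an$tukey$pair, statistic = NA_real_,
      df1 = NA_real_, df2 = NA_real_, p = an$tukey$p_adj,
      estimate = an$tukey$diff, lower = an$tukey$lwr, upper = an$tukey$upr))
    stat_rows[[length(stat_rows) + 1]] <<- rows
  }
  totals <- .tree_totals(avg)
  if (length(unique(totals$group)) >= 2 && all(table(totals$group) >= 2))
    add_anova("total_cells_anova", one_way_anova(totals$total, totals$group))
  if (!is.null(trach)) {
    key <- paste(trach$tree_id, trach$radial_file, sep = "\r")
    ew <- do.call(rbind, lapply(unique(key), function(k) {
      ring <- trach[key == k, ]
      ring <- ring[order(ring$cell_index), ]
      s <- earlywood_latewood_split(tracheidogram(ring))
      data.frame(tree_id = ring$tree_id[1], group = ring$group[1],
                 earlywood = s[["earlywood"]], latewood = s[["latewood"]])
    }))
    if (length(unique(ew$group)) >= 2 && all(table(ew$group) >= 2)) {
      add_anova("earlywood_anova", one_way_anova(ew$earlywood, ew$group))
      add_anova("latewood_anova", one_way_anova(ew$latewood, ew$group))
    }
    # trait ~ duration mixed models, per group, tracheids matched to group
    # kinetics by formation-order quantile
    pos <- tracheid_positions(trach)
    for (g in groups) {
      kin <- kinetics_by_group[[g]]
      if (nrow(kin) < 3) next
      qk <- (kin$cell_index - 0.5) / nrow(kin)
      sub <- pos[pos$group == g, ]
      nk <- stats::ave(sub$cell_index, paste(sub$tree_id, sub$radial_file),
                       FUN = length)
      qt <- (sub$cell_index - 0.5) / nk
      dE <- stats::approx(qk, kin$d_E, xout = qt, rule = 2)$y
      ok <- !is.na(kin$d_T)
      for (spec in list(
        list(name = sprintf("lmm_LD_dE_%s", g), y = sub$lumen_diameter,
             x = dE),
        list(name = sprintf("lmm_CWT_dT_%s", g),
             y = sub$wall_thickness,
             x = if (sum(ok) >= 2)
               stats::approx(qk[ok], kin$d_T[ok], xout = qt, rule = 2)$y
             else NULL))) {
        if (is.null(spec$x) || stats::var(spec$x) == 0) next
        ms <- mixed_slope(spec$y, spec$x, sub$tree_id)
        stat_rows[[length(stat_rows) + 1]] <- data.frame(
          test = spec$name, component = "slope", statistic = NA_real_,
          df1 = NA_real_, df2 = NA_real_, p = NA_real_,
          estimate = ms$slope, lower = ms$slope_ci[1],
          upper = ms$slope_ci[2])
      }
    }
  }
  stats_df <- if (length(stat_rows))
    do.call(rbind, c(stat_rows, list(make.row.names = FALSE)))
  else data.frame(test = character(0), component = character(0),
                  statistic = numeric(0), df1 = numeric(0), df2 = numeric(0),
                  p = numeric(0), estimate = numeric(0), lower = numeric(0),
                  upper = numeric(0))
  .write_tidy(stats_df, p("stats.csv"))

  # --- sidecar metadata: units for every output column
  units <- rbind(
    data.frame(file = "fitted_curves.csv",
               column = c("season_day", "mean", "lower", "upper"),
               unit = c("day", "cells", "cells", "cells")),
    data.frame(file = "significance_windows.csv",
               column = c("start", "end"),
               unit = "day (season) or relative position for trait rows"),
    data.frame(file = "kinetics.csv",
               column = c("t_enl", "t_thick", "t_mature", "d_E", "d_T",
                          "lumen_diameter", "wall_thickness", "r_enl",
                          "r_wall"),
               unit = c("day", "day", "day", "days", "days", "um", "um",
                        "um/day", "um/day")),
    data.frame(file = "rates.csv", column = c("season_day", "rate"),
               unit = c("day", "cells/day")),
    data.frame(file = "profiles.csv",
               column = c("rel_pos", "lumen_diameter", "wall_thickness"),
               unit = c("fraction of ring", "um", "um")),
    data.frame(file = "phenology.csv",
               column = c("onset", "cessation", "duration", "peak_days"),
               unit = c("day", "day", "days", "day")),
    data.frame(file = "stats.csv",
               column = c("statistic", "p", "estimate"),
               unit = c("F or t", "probability", "response units")))
  .write_tidy(units, p("units.csv"))

  manifest <- list(
    package = "xylokin",
    version = as.character(utils::packageVersion("xylokin")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    simulated = !is.null(config$sim_config),
    smooth = unclass(config$smooth),
    threshold = config$threshold,
    min_prominence = config$min_prominence,
    min_separation = config$min_separation,
    rc_method = config$rc_method,
    profile_points = config$profile_points)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(out_dir = config$out_dir, curves = curves,
                 kinetics = kinetics_by_group, phenology = phen,
                 stats = stats_df, windows = wins))
}
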