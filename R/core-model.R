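#' @keywords internal
"_PACKAGE"

# Column schemas shared by the readers/writers and the simulator.
.count_cols <- c("n_cambial", "n_enlarging", "n_thickening", "n_mature")
.counts_schema <- c("tree_id", "group", "season_day", "radial_file", .count_cols)
.tracheid_schema <- c("tree_id", "group", "radial_file", "cell_index",
                      "lumen_diameter", "wall_thickness")

#' Season bookkeeping for a wood-formation campaign
#'
#' All time in this package runs on a single monotone axis, the *season day*:
#' days since January 1 of the season's start year (January 1 = day 1),
#' continuing past 365 when a campaign crosses the calendar boundary. A
#' Mediterranean campaign running February to the following March therefore
#' spans roughly season days 60-430.
#'
#' @param start_year calendar year in which the season starts.
#' @param grid_step spacing, in days, of the prediction grid used by the
#'   smoother (default 1).
#' @param ci_level pointwise confidence level for fitted bands (default 0.95).
#' @return a list of class `season_config`.
#' @export
season_config <- function(start_year, grid_step = 1, ci_level = 0.95) {
  stopifnot(is.numeric(start_year), length(start_year) == 1)
  if (!(grid_step > 0)) stop("grid_step must be positive", call. = FALSE)
  if (!(ci_level > 0 && ci_level < 1))
    stop("ci_level must be strictly between 0 and 1", call. = FALSE)
  structure(list(start_year = as.integer(start_year),
                 grid_step = grid_step, ci_level = ci_level),
            class = "season_config")
}

#' Convert ISO dates to season days
#'
#' @param dates character or `Date` vector of ISO dates (`"2017-03-03"`).
#' @param start_year year whose January 1 anchors day 1; dates in the
#'   following year map past 365.
#' @return integer season days.
#' @examples
#' season_day("2017-03-03", 2017) # 62
#' @export
season_day <- function(dates, start_year) {
  d <- as.Date(dates)
  as.integer(d - as.Date(sprintf("%d-01-01", start_year))) + 1L
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
}

#' Validate a phase-count table
#'
#' One row per tree x sampling date x radial file, with integer counts of
#' cambial (#C), enlarging (#E), wall-thickening (#L) and mature (#M) cells.
#'
#' @param df data frame to validate.
#' @return the validated data frame (invisibly unchanged).
#' @export
validate_counts <- function(df) {
  .require_columns(df, .counts_schema, "counts table")
  for (col in c("season_day", "radial_file", .count_cols)) {
    if (!is.numeric(df[[col]]))
      stop(sprintf("column '%s' must be numeric", col), call. = FALSE)
  }
  for (col in .count_cols) {
    bad <- which(df[[col]] < 0)
    if (length(bad))
      stop(sprintf("negative count in column '%s' at row %d", col, bad[1]),
           call. = FALSE)
  }
  bad <- which(df$season_day <= 0)
  if (length(bad))
    stop(sprintf("season_day must be strictly positive (row %d)", bad[1]),
         call. = FALSE)
  key <- paste(df$tree_id, df$season_day, df$radial_file, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicate (tree_id, season_day, radial_file) key at row %d",
                 dup[1]), call. = FALSE)
  df
}

#' Read a phase-count CSV
#'
#' @param path CSV with header columns `tree_id, group, season_day,
#'   radial_file, n_cambial, n_enlarging, n_thickening, n_mature`.
#' @return validated data frame of count observations.
#' @seealso [write_counts()], [average_radial_files()]
#' @export
read_counts <- function(path) {
  if (!file.exists(path))
    stop("counts file not found: ", path, call. = FALSE)
  validate_counts(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a phase-count CSV
#'
#' @param df validated counts table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(df, path) {
  validate_counts(df)
  utils::write.csv(df[, .counts_schema], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a tracheid anatomy table
#'
#' Ordered tracheids per radial file with lumen diameter (LD) and single
#' radial cell-wall thickness (CWT), both in micrometres. The radial cell
#' diameter is `LD + 2 * CWT` and is (re)computed here.
#'
#' @param df data frame to validate.
#' @return validated data frame with a `radial_diameter` column.
#' @export
validate_tracheids <- function(df) {
  .require_columns(df, .tracheid_schema, "tracheid table")
  for (col in c("cell_index", "lumen_diameter", "wall_thickness")) {
    if (!is.numeric(df[[col]]))
      stop(sprintf("column '%s' must be numeric", col), call. = FALSE)
  }
  bad <- which(df$lumen_diameter <= 0 | df$wall_thickness <= 0)
  if (length(bad))
    stop(sprintf("non-positive tracheid dimension at row %d", bad[1]),
         call. = FALSE)
  # cell_index must run 1..n within each (tree, radial file)
  key <- paste(df$tree_id, df$radial_file, sep = "\r")
  for (k in unique(key)) {
    idx <- sort(df$cell_index[key == k])
    if (!identical(as.integer(idx), seq_along(idx)))
      stop(sprintf("cell_index not contiguous from 1 for tree '%s'",
                   strsplit(k, "\r", fixed = TRUE)[[1]][1]), call. = FALSE)
  }
  df$radial_diameter <- df$lumen_diameter + 2 * df$wall_thickness
  df
}

#' Read a tracheid anatomy CSV
#'
#' @param path CSV with header columns `tree_id, group, radial_file,
#'   cell_index, lumen_diameter, wall_thickness`.
#' @return validated data frame with derived `radial_diameter`.
#' @export
read_tracheids <- function(path) {
  if (!file.exists(path))
    stop("tracheid file not found: ", path, call. = FALSE)
  validate_tracheids(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a tracheid anatomy CSV
#'
#' @param df validated tracheid table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tracheids <- function(df, path) {
  df <- validate_tracheids(df)
  utils::write.csv(df[, .tracheid_schema], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Average phase counts over radial files
#'
#' Microcore counts are taken along (typically three) radial files; all
#' downstream modelling uses the per-tree per-date arithmetic mean over the
#' available files, so fractional cell counts are allowed from here on.
#'
#' @param df counts table (one row per tree x date x file).
#' @return data frame with one row per (tree, date): columns `tree_id`,
#'   `group`, `season_day` and fractional mean counts.
#' @export
average_radial_files <- function(df) {
  if (nrow(df) == 0) {
    out <- df[, c("tree_id", "group", "season_day", .count_cols)]
    return(out)
  }
  validate_counts(df)
  agg <- stats::aggregate(
    df[.count_cols],
    by = list(tree_id = df$tree_id, group = df$group,
              season_day = df$season_day),
    FUN = mean)
  agg <- agg[order(agg$group, agg$tree_id, agg$season_day), ]
  rownames(agg) <- NULL
  agg
}
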