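#' Onset and cessation of a differentiation phase
#'
#' A phase is considered active while its fitted curve exceeds a small count
#' threshold (default half a cell). Onset is the first up-crossing and
#' cessation the last down-crossing of the threshold, both located by linear
#' interpolation; a curve already above threshold at the grid boundary
#' returns the boundary itself. A curve that never exceeds the threshold has
#' no window (both values `NA`).
#'
#' @param curve a `phase_curve` (or any list with `grid` and `mean`).
#' @param threshold activity threshold in cells (default 0.5).
#' @return named numeric vector `c(onset = , cessation = )`.
#' @export
phase_window <- function(curve, threshold = 0.5) {
  t <- curve$grid; v <- curve$mean
  above <- v >= threshold
  if (!any(above)) return(c(onset = NA_real_, cessation = NA_real_))
  i0 <- which(above)[1]
  i1 <- which(above)[length(which(above))]
  onset <- if (i0 == 1) t[1] else
    t[i0 - 1] + (threshold - v[i0 - 1]) / (v[i0] - v[i0 - 1]) *
      (t[i0] - t[i0 - 1])
  cessation <- if (i1 == length(t)) t[length(t)] else
    t[i1] + (threshold - v[i1]) / (v[i1 + 1] - v[i1]) * (t[i1 + 1] - t[i1])
  c(onset = onset, cessation = cessation)
}

# Topographic prominence of a local maximum at index p: height above the
# higher of the two key saddles (minimum between the peak and the nearest
# strictly higher point on each side, or the series end).
.peak_prominence <- function(v, p) {
  h <- v[p]
  left_min <- if (p == 1) h else {
    higher <- which(v[seq_len(p - 1)] > h)
    from <- if (length(higher)) max(higher) + 1 else 1
    min(v[from:(p - 1)])
  }
  right_min <- if (p == length(v)) h else {
    right <- v[(p + 1):length(v)]
    higher <- which(right > h)
    to <- if (length(higher)) min(higher) - 1 else length(right)
    min(right[seq_len(to)])
  }
  h - max(left_min, right_min)
}

#' Classify a seasonal curve as unimodal or bimodal
#'
#' Mediterranean conifers can show a facultative bimodal pattern: a spring
#' pulse of activity and a second, post-summer pulse. This operationalizes
#' the visual call: local maxima qualify as peaks when their topographic
#' prominence reaches a fraction of the curve's global maximum and they are
#' separated by a minimum number of days; the curve is bimodal when two or
#' more qualify. The classification is invariant under positive rescaling
#' of the curve.
#'
#' @param curve a `phase_curve` / rate curve (list with `grid` and `mean`),
#'   or supply `grid` and `values` directly via a list.
#' @param min_prominence minimum peak prominence as a fraction of the global
#'   maximum (default 0.2).
#' @param min_separation minimum distance between reported peaks, in grid
#'   units (default 60 days).
#' @return list with `modality` (`"unimodal"` or `"bimodal"`) and
#'   `peak_days` (up to the two highest qualifying peaks, ascending; empty
#'   for a flat zero curve).
#' @export
classify_modality <- function(curve, min_prominence = 0.2,
                              min_separation = 60) {
  t <- curve$grid
  v <- if (!is.null(curve$mean)) curve$mean else curve$values
  v <- pmax(v, 0)
  vmax <- max(v)
  if (vmax <= 0)
    return(list(modality = "unimodal", peak_days = numeric(0)))
  n <- length(v)
  # interior local maxima (left-closed on plateaus), plus boundary maxima
  cand <- which(diff(sign(diff(v))) < 0) + 1
  if (v[1] > v[2]) cand <- c(1L, cand)
  if (v[n] > v[n - 1]) cand <- c(cand, n)
  cand <- unique(cand)
  prom <- vapply(cand, function(p) .peak_prominence(v, p), numeric(1))
  keep <- cand[prom >= min_prominence * vmax]
  # greedy separation filter, highest peaks first
  keep <- keep[order(v[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (p in keep) {
    if (!length(sel) || all(abs(t[p] - t[sel]) >= min_separation))
      sel <- c(sel, p)
  }
  sel <- sel[order(v[sel], decreasing = TRUE)]
  top <- sort(t[utils::head(sel, 2)])
  list(modality = if (length(sel) >= 2) "bimodal" else "unimodal",
       peak_days = top)
}

#' Phenology metrics for fitted curves
#'
#' @param curves nested list from [fit_phase_curves()]
#'   (`curves[[group]][[phase]]`).
#' @param threshold activity threshold in cells for onset/cessation.
#' @param min_prominence,min_separation passed to [classify_modality()].
#' @return data frame: `group, phase, onset, cessation, duration, modality,
#'   peak_days` (peak days joined with ";").
#' @export
phenology_metrics <- function(curves, threshold = 0.5, min_prominence = 0.2,
                              min_separation = 60) {
  rows <- list()
  for (g in names(curves)) for (ph in names(curves[[g]])) {
    cv <- curves[[g]][[ph]]
    w <- phase_window(cv, threshold)
    m <- classify_modality(cv, min_prominence, min_separation)
    rows[[length(rows) + 1]] <- data.frame(
      group = g, phase = ph, onset = w[["onset"]],
      cessation = w[["cessation"]], duration = w[["cessation"]] - w[["onset"]],
      modality = m$modality,
      peak_days = paste(round(m$peak_days, 1), collapse = ";"))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
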