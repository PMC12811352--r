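#' Dense along-track interpolation at 1-minute spacing
#'
#' Piecewise-linear positions along the original fix series (not the
#' regularised track), at 1-min spacing from the first to the last fix of
#' each individual; each timestamp appears once. With `d` the track duration
#' in minutes, each individual contributes `floor(d) + 1` points.
#'
#' @param fixes fix table (`id`, `time`, `x`, `y`).
#' @return data frame `id`, `time`, `x`, `y`; individuals with fewer than
#'   two fixes contribute no points (with a warning).
#' @export
interpolate_1min <- function(fixes) {
  out <- list()
  for (ind in unique(fixes$id)) {
    fx <- fixes[fixes$id == ind, , drop = FALSE]
    fx <- fx[order(fx$time), , drop = FALSE]
    if (nrow(fx) < 2) {
      warning("individual ", ind, " has fewer than 2 fixes; skipped")
      next
    }
    grid <- seq(min(fx$time), max(fx$time), by = 60)
    out[[length(out) + 1]] <- data.frame(
      id = ind, time = grid,
      x = approx(as.numeric(fx$time), fx$x, as.numeric(grid))$y,
      y = approx(as.numeric(fx$time), fx$y, as.numeric(grid))$y,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(id = character(0), time = as.POSIXct(character(0)),
                      x = numeric(0), y = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# mode with ties broken by earliest occurrence (values in time order)
mode_earliest <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_character_)
  counts <- table(factor(v, levels = unique(v)))  # unique() preserves order
  names(counts)[which.max(counts)]  # which.max takes the first maximum
}

#' Summarise dense habitat values to 2-h intervals
#'
#' Dense points (with extracted cell values) are assigned to intervals by
#' timestamp on the half-open window `[midpoint - 1 h, midpoint + 1 h)`;
#' PEA is summarised to the median and the categorical layers to the mode,
#' with ties broken by the category occupied earliest in the interval.
#' Missing cell values are excluded; an interval whose points all lack data
#' is flagged `missing_covariates`.
#'
#' @param points output of [interpolate_1min()] with columns
#'   `geomorphology`, `substrate`, `pea` added (see [seascape_extract()]).
#' @param intervals interval table (`id`, `time` midpoints).
#' @return `intervals` with `geomorphology`, `substrate`, `pea` (median) and
#'   logical `missing_covariates` columns added.
#' @export
summarize_intervals <- function(points, intervals) {
  intervals$geomorphology <- NA_character_
  intervals$substrate <- NA_character_
  intervals$pea <- NA_real_
  for (ind in unique(intervals$id)) {
    pt <- points[points$id == ind, , drop = FALSE]
    pt <- pt[order(pt$time), , drop = FALSE]
    sel <- which(intervals$id == ind)
    for (k in sel) {
      lo <- intervals$time[k] - 3600
      hi <- intervals$time[k] + 3600
      inw <- pt$time >= lo & pt$time < hi
      if (!any(inw)) next
      intervals$geomorphology[k] <- mode_earliest(pt$geomorphology[inw])
      intervals$substrate[k] <- mode_earliest(pt$substrate[inw])
      pv <- pt$pea[inw]
      if (any(!is.na(pv))) intervals$pea[k] <- median(pv, na.rm = TRUE)
    }
  }
  intervals$missing_covariates <- is.na(intervals$geomorphology) &
    is.na(intervals$substrate) & is.na(intervals$pea)
  intervals
}

#' Attach habitat covariates to regularised intervals
#'
#' Convenience wrapper: interpolates the original fixes at 1-min spacing,
#' extracts seascape values at every dense point, and summarises them per
#' 2-h interval.
#'
#' @param intervals regularised interval table.
#' @param fixes the original (cleaned) fix table.
#' @param seascape a [build_seascape()] object.
#' @return `intervals` with habitat columns added (see
#'   [summarize_intervals()]).
#' @export
attach_habitat <- function(intervals, fixes, seascape) {
  pts <- interpolate_1min(fixes)
  pts <- cbind(pts, seascape_extract(seascape, pts$x, pts$y))
  summarize_intervals(pts, intervals)
}
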