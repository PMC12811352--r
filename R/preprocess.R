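#' Non-diving known-state threshold
#'
#' Seals must surface to breathe and can spend at most 88.8% of a 2-h
#' interval underwater; an interval is coded a-priori as non-diving when the
#' proportion of time diving is below 50% of that physiological maximum.
#'
#' @param max_diving maximum possible diving proportion per interval.
#' @param fraction fraction of the maximum defining the cutoff.
#' @return the threshold (0.444 at the defaults).
#' @export
diving_threshold <- function(max_diving = 0.888, fraction = 0.5) {
  max_diving * fraction
}

#' Clean location fixes on quality thresholds
#'
#' Retains fixes with at least `min_satellites` satellite links and residual
#' error at most `max_residual` (both boundaries inclusive), preserving row
#' order.
#'
#' @param fixes data frame with columns `n_satellites` and `residual`.
#' @param min_satellites,max_residual quality thresholds.
#' @return the retained rows.
#' @export
clean_fixes <- function(fixes, min_satellites = 5, max_residual = 25) {
  for (col in c("n_satellites", "residual")) {
    if (is.null(fixes[[col]]))
      stop("fixes is missing required quality column '", col, "'")
  }
  keep <- fixes$n_satellites >= min_satellites &
    fixes$residual <= max_residual
  keep[is.na(keep)] <- FALSE
  fixes[keep, , drop = FALSE]
}

#' Segment at-sea fixes into trips between haulout events
#'
#' A trip is any at-sea location data between consecutive recorded haulout
#' events (per individual). Events shorter than `min_haulout_min` minutes
#' are treated as erroneous surface-dry records and ignored. Fixes
#' timestamped inside a haulout event trigger a warning and are assigned to
#' the haulout (excluded from trips).
#'
#' @param fixes cleaned fix table (`id`, `time`, ...).
#' @param haulout_events data frame `event_id`, `id`, `start`, `end`;
#'   non-overlapping per individual.
#' @param min_haulout_min minimum credible haulout duration (minutes).
#' @return data frame of trips: `trip_id`, `id`, `start`, `end`,
#'   `duration_h`, `start_haulout`, `end_haulout`, `n_fixes`.
#' @export
segment_trips <- function(fixes, haulout_events = NULL,
                          min_haulout_min = 10) {
  out <- list()
  for (ind in unique(fixes$id)) {
    fx <- fixes[fixes$id == ind, , drop = FALSE]
    fx <- fx[order(fx$time), , drop = FALSE]
    ev <- haulout_events[haulout_events$id == ind, , drop = FALSE]
    if (!is.null(ev) && nrow(ev)) {
      ev <- ev[as.numeric(difftime(ev$end, ev$start, units = "mins")) >=
                 min_haulout_min, , drop = FALSE]
      ev <- ev[order(ev$start), , drop = FALSE]
    }
    ne <- if (is.null(ev)) 0 else nrow(ev)
    if (ne) {
      inside <- vapply(fx$time, function(tm)
        any(tm >= ev$start & tm <= ev$end), TRUE)
      if (any(inside)) {
        warning(sum(inside), " fix(es) for ", ind,
                " fall inside haulout events; assigned to haulout")
        fx <- fx[!inside, , drop = FALSE]
      }
    }
    if (!nrow(fx)) next
    bounds_start <- c(min(fx$time), if (ne) ev$end)
    bounds_end <- c(if (ne) ev$start, max(fx$time))
    ev_ids <- if (ne) ev$event_id else character(0)
    start_ho <- c(NA_character_, ev_ids)
    end_ho <- c(ev_ids, NA_character_)
    k <- 0
    for (g in seq_along(bounds_start)) {
      if (bounds_end[g] <= bounds_start[g] && g > 1 && g <= ne) next
      n_in <- sum(fx$time >= bounds_start[g] & fx$time <= bounds_end[g])
      if (n_in == 0) next
      k <- k + 1
      out[[length(out) + 1]] <- data.frame(
        trip_id = sprintf("%s_trip%03d", ind, k), id = ind,
        start = bounds_start[g], end = bounds_end[g],
        duration_h = as.numeric(difftime(bounds_end[g], bounds_start[g],
                                         units = "hours")),
        start_haulout = start_ho[g], end_haulout = end_ho[g],
        n_fixes = n_in, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(trip_id = character(0), id = character(0),
                      start = as.POSIXct(character(0)),
                      end = as.POSIXct(character(0)),
                      duration_h = numeric(0),
                      start_haulout = character(0),
                      end_haulout = character(0), n_fixes = integer(0)))
  }
  do.call(rbind, out)
}

#' Regularise fixes to 2-h interval midpoints
#'
#' Positions are linearly interpolated (in x and y separately) at the
#' midpoint of each 2-h summary interval lying between an individual's first
#' and last fix. The midpoint grid is completed to a contiguous 2-h sequence
#' spanning the summary records, so that gaps in the summaries appear as
#' intervals with missing summary data. Step length is the Euclidean
#' distance to the next midpoint position; the turn angle is the signed
#' angle between consecutive displacement vectors, and is missing wherever
#' an adjoining step is missing or zero.
#'
#' @param fixes cleaned fix table (`id`, `time`, `x`, `y`).
#' @param summaries 2-h summary table (`id`, `interval_start`,
#'   `interval_end`, `prop_diving`, optionally `prop_hauled`).
#' @return data frame of regularised intervals: `id`, `time` (midpoint),
#'   `x`, `y`, `step`, `angle`, `prop_diving`, `prop_hauled`.
#' @export
regularize_track <- function(fixes, summaries) {
  out <- list()
  for (ind in unique(summaries$id)) {
    sm <- summaries[summaries$id == ind, , drop = FALSE]
    sm <- sm[order(sm$interval_start), , drop = FALSE]
    width <- as.numeric(difftime(sm$interval_end, sm$interval_start,
                                 units = "hours"))
    if (any(abs(width - 2) > 1e-6))
      stop("summaries for ", ind, " are not on a 2-h grid")
    mids_obs <- sm$interval_start + 3600
    grid <- seq(min(mids_obs), max(mids_obs), by = 7200)
    m <- match(as.numeric(grid), as.numeric(mids_obs))
    prop <- sm$prop_diving[m]
    ph <- if (is.null(sm$prop_hauled)) rep(NA_real_, length(m)) else
      sm$prop_hauled[m]
    fx <- fixes[fixes$id == ind, , drop = FALSE]
    fx <- fx[order(fx$time), , drop = FALSE]
    x <- y <- rep(NA_real_, length(grid))
    if (nrow(fx) >= 2) {
      inside <- grid >= min(fx$time) & grid <= max(fx$time)
      if (any(inside)) {
        x[inside] <- approx(as.numeric(fx$time), fx$x,
                            xout = as.numeric(grid[inside]))$y
        y[inside] <- approx(as.numeric(fx$time), fx$y,
                            xout = as.numeric(grid[inside]))$y
      }
    }
    step <- c(sqrt(diff(x)^2 + diff(y)^2), NA)
    heading <- atan2(c(diff(y), NA), c(diff(x), NA))
    heading[is.na(step) | step == 0] <- NA
    angle <- wrap_angle(c(NA, diff(heading)))
    angle[is.na(step)] <- NA
    out[[length(out) + 1]] <- data.frame(
      id = ind, time = grid, x = x, y = y, step = step, angle = angle,
      prop_diving = prop, prop_hauled = ph, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag unreliable intervals
#'
#' An interval is unreliable iff its summary record is missing, or the
#' observed fixes bracketing its midpoint are more than `max_gap_h` hours
#' apart (strict inequality), or no fixes bracket the midpoint at all.
#'
#' @param intervals output of [regularize_track()].
#' @param fixes the cleaned fix table used for regularisation.
#' @param max_gap_h maximum tolerated fix gap around a midpoint (hours).
#' @return `intervals` with a logical `unreliable` column added.
#' @export
flag_unreliable <- function(intervals, fixes, max_gap_h = 6) {
  intervals$unreliable <- NA
  for (ind in unique(intervals$id)) {
    sel <- intervals$id == ind
    mids <- as.numeric(intervals$time[sel])
    fx <- sort(as.numeric(fixes$time[fixes$id == ind]))
    if (!length(fx)) {
      intervals$unreliable[sel] <- TRUE
      next
    }
    i_prev <- findInterval(mids, fx)
    prev <- ifelse(i_prev >= 1, fx[pmax(i_prev, 1)], NA)
    # a midpoint equal to a fix time brackets itself (gap 0)
    i_next <- length(fx) - findInterval(-mids, rev(-fx)) + 1
    nxt <- ifelse(i_next <= length(fx), fx[pmin(i_next, length(fx))], NA)
    gap_h <- (nxt - prev) / 3600
    intervals$unreliable[sel] <- is.na(gap_h) | gap_h > max_gap_h
  }
  intervals$unreliable <- intervals$unreliable | is.na(intervals$prop_diving)
  intervals
}

#' Code a-priori known states
#'
#' Unreliable intervals are coded `"Unk"`; otherwise an interval is
#' non-diving (`"N"`) when its diving proportion is strictly below the
#' threshold, and `"free"` (state to be inferred among the movement states)
#' when at or above it. Diving proportions above the physiological maximum
#' (0.888) are clamped with a warning.
#'
#' @param intervals output of [flag_unreliable()].
#' @param threshold the non-diving cutoff, from [diving_threshold()].
#' @param max_diving the physiological maximum diving proportion.
#' @return `intervals` with a `known` column in `{"N", "Unk", "free"}`.
#' @export
code_known_states <- function(intervals, threshold = diving_threshold(),
                              max_diving = 0.888) {
  over <- !is.na(intervals$prop_diving) & intervals$prop_diving > max_diving
  if (any(over)) {
    warning(sum(over), " diving proportion(s) above the physiological ",
            "maximum ", max_diving, "; clamped")
    intervals$prop_diving[over] <- max_diving
  }
  intervals$known <- ifelse(intervals$unreliable, "Unk",
                            ifelse(intervals$prop_diving < threshold,
                                   "N", "free"))
  intervals
}

#' Attach trip identifiers to intervals
#'
#' @param intervals regularised interval table.
#' @param trips output of [segment_trips()].
#' @return `intervals` with a `trip_id` column (`NA` outside all trips).
#' @export
attach_trips <- function(intervals, trips) {
  intervals$trip_id <- NA_character_
  for (k in seq_len(nrow(trips))) {
    sel <- intervals$id == trips$id[k] &
      intervals$time >= trips$start[k] & intervals$time <= trips$end[k]
    intervals$trip_id[sel] <- trips$trip_id[k]
  }
  intervals
}

season_months <- function(species) {
  switch(species,
         grey = 5:9,          # summer, May-September inclusive
         harbour = c(9:12, 1:5),  # September-May inclusive
         stop("unknown species label '", species, "'"))
}

#' Trip- and interval-level filters for habitat analysis
#'
#' Applies the data-cleaning rules ahead of the habitat association models:
#' trips starting within 168 h of the individual's capture are removed;
#' trips shorter than 8 h are removed; intervals outside the species'
#' season window (grey: May-September; harbour: September-May, boundary
#' months inclusive) are removed; intervals inside any supplied exclusion
#' polygon are removed. Intervals belonging to a removed trip are dropped.
#'
#' @param trips output of [segment_trips()].
#' @param intervals interval table carrying `trip_id` (see
#'   [attach_trips()]).
#' @param capture_dates data frame `id`, `capture` (POSIXct).
#' @param species `"grey"` or `"harbour"`.
#' @param exclusion_polygons optional list of data frames with columns
#'   `x`, `y` giving polygon vertices.
#' @param post_capture_h exclusion window after capture (hours).
#' @param min_trip_h minimum trip duration (hours).
#' @return list with `trips`, `intervals` (both filtered) and `report`
#'   (rows removed per rule).
#' @export
filter_trips <- function(trips, intervals, capture_dates, species,
                         exclusion_polygons = NULL, post_capture_h = 168,
                         min_trip_h = 8) {
  months_ok <- season_months(species)
  cap <- capture_dates$capture[match(trips$id, capture_dates$id)]
  if (any(is.na(cap))) stop("capture date missing for some individuals")
  early <- as.numeric(difftime(trips$start, cap, units = "hours")) <
    post_capture_h
  short <- trips$duration_h < min_trip_h
  report <- list(trips_post_capture = sum(early),
                 trips_short = sum(short & !early))
  keep_trips <- trips[!early & !short, , drop = FALSE]
  in_trip <- !is.na(intervals$trip_id)
  in_kept <- intervals$trip_id %in% keep_trips$trip_id
  report$intervals_removed_with_trips <- sum(in_trip & !in_kept)
  iv <- intervals[!in_trip | in_kept, , drop = FALSE]
  mon <- as.integer(format(iv$time, "%m"))
  out_season <- !mon %in% months_ok
  report$intervals_out_of_season <- sum(out_season)
  iv <- iv[!out_season, , drop = FALSE]
  if (!is.null(exclusion_polygons)) {
    excl <- rep(FALSE, nrow(iv))
    has_pos <- !is.na(iv$x) & !is.na(iv$y)
    for (poly in exclusion_polygons) {
      bnd <- as.matrix(poly[, c("x", "y")])
      excl[has_pos] <- excl[has_pos] |
        mgcv::in.out(bnd, cbind(iv$x[has_pos], iv$y[has_pos]))
    }
    report$intervals_in_exclusion_polygons <- sum(excl)
    iv <- iv[!excl, , drop = FALSE]
  }
  list(trips = keep_trips, intervals = iv, report = report)
}

#' Assign intervals to regions via trip haulouts
#'
#' Each trip takes the region of its associated haulout sites. Trips whose
#' start and end haulouts lie in different regions are divided at the
#' midpoint: the first `floor(n/2)` intervals take the departure region and
#' the remainder the destination region.
#'
#' @param trips trip table with `start_haulout` / `end_haulout` event ids.
#' @param intervals interval table carrying `trip_id`.
#' @param haulout_events haulout-event table with `event_id`.
#' @param region_map data frame `event_id`, `region` mapping every haulout
#'   event to a region; events without a region raise an error.
#' @return `intervals` with a `region` column (`NA` outside trips).
#' @export
assign_regions <- function(trips, intervals, haulout_events, region_map) {
  lookup <- function(ev) {
    if (is.na(ev)) return(NA_character_)
    r <- region_map$region[match(ev, region_map$event_id)]
    if (is.na(r)) stop("haulout event '", ev, "' is outside all regions")
    r
  }
  intervals$region <- NA_character_
  for (k in seq_len(nrow(trips))) {
    dep <- lookup(trips$start_haulout[k])
    dst <- lookup(trips$end_haulout[k])
    if (is.na(dep)) dep <- dst
    if (is.na(dst)) dst <- dep
    sel <- which(intervals$trip_id %in% trips$trip_id[k])
    sel <- sel[order(intervals$time[sel])]
    n <- length(sel)
    if (!n) next
    if (identical(dep, dst) || is.na(dep)) {
      intervals$region[sel] <- dep
    } else {
      h <- floor(n / 2)
      intervals$region[sel[seq_len(h)]] <- dep
      if (h < n) intervals$region[sel[(h + 1):n]] <- dst
    }
  }
  intervals
}

#' Write / read a regularised interval table
#'
#' Plain CSV round-trip with ISO-8601 timestamps; reading back reproduces
#' the table (column classes included).
#'
#' @param intervals interval table.
#' @param path CSV path.
#' @return `read_intervals_csv()` returns the interval data frame.
#' @export
write_intervals_csv <- function(intervals, path) {
  out <- intervals
  out$time <- format(out$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intervals_csv
#' @export
read_intervals_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  out$time <- as.POSIXct(out$time, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out
}
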