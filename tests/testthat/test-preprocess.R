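ts <- function(h) as.POSIXct("2015-06-01 00:00:00", tz = "UTC") + h * 3600

test_that("fix cleaning applies inclusive quality thresholds", {
  fx <- data.frame(id = "a", time = ts(0:3),
                   n_satellites = c(5, 4, 12, 5),
                   residual = c(25, 10, 26, 0))
  out <- clean_fixes(fx)
  expect_equal(out$time, fx$time[c(1, 4)])  # boundary row retained, order kept
  expect_error(clean_fixes(fx[, c("id", "time", "residual")]),
               "n_satellites")
})

test_that("fix cleaning equals a brute-force predicate scan", {
  set.seed(10)
  fx <- data.frame(id = "a", time = ts(seq_len(100)),
                   n_satellites = sample(3:12, 100, replace = TRUE),
                   residual = runif(100, 0, 40))
  keep <- logical(100)
  for (i in 1:100) keep[i] <- fx$n_satellites[i] >= 5 && fx$residual[i] <= 25
  expect_equal(clean_fixes(fx), fx[keep, ])
})

test_that("trips are segmented between haulout events", {
  ev <- data.frame(event_id = c("h1", "h2", "h3"), id = "a",
                   start = ts(c(10, 30, 60)), end = ts(c(12, 33, 62)))
  fx <- data.frame(id = "a", time = ts(c(15, 20, 25, 40, 50)),
                   x = 0, y = 0)
  tr <- segment_trips(fx, ev)
  expect_equal(nrow(tr), 2)
  expect_equal(tr$start_haulout, c("h1", "h2"))
  expect_equal(tr$end_haulout, c("h2", "h3"))
  # no events: one trip spanning all fixes
  tr0 <- segment_trips(fx, ev[0, ])
  expect_equal(nrow(tr0), 1)
  expect_equal(tr0$duration_h, 35)
  # sub-10-min events are ignored as erroneous dry records
  ev2 <- rbind(ev, data.frame(event_id = "h4", id = "a",
                              start = ts(22), end = ts(22) + 5 * 60))
  expect_equal(nrow(segment_trips(fx, ev2)), 2)
  # fixes inside a haulout event are reassigned with a warning
  fx2 <- rbind(fx, data.frame(id = "a", time = ts(11), x = 0, y = 0))
  expect_warning(segment_trips(fx2, ev), "inside haulout")
})

test_that("trip boundaries equal a brute-force partition on random layouts", {
  set.seed(77)
  for (rep in 1:20) {
    n_ev <- sample(0:4, 1)
    starts <- sort(runif(n_ev, 0, 90))
    ev <- data.frame(event_id = sprintf("h%d", seq_len(n_ev)),
                     id = rep("a", n_ev), start = ts(starts),
                     end = ts(starts + runif(n_ev, 0.5, 3)))
    ok <- c(TRUE, ev$start[-1] > ev$end[-n_ev])[seq_len(n_ev)]
    ev <- ev[ok, , drop = FALSE]   # keep events non-overlapping
    fx <- data.frame(id = "a", time = ts(sort(runif(30, 0, 100))), x = 0, y = 0)
    inside <- vapply(fx$time, function(tm)
      any(tm >= ev$start & tm <= ev$end), TRUE)
    fx_out <- fx[!inside, , drop = FALSE]
    tr <- suppressWarnings(segment_trips(fx, ev))
    # oracle: cut fix times at event boundaries and count non-empty gaps
    bnds <- c(min(fx_out$time), rbind(ev$start, ev$end), max(fx_out$time))
    gap_lo <- c(min(fx_out$time), ev$end)
    gap_hi <- c(ev$start, max(fx_out$time))
    n_oracle <- 0
    for (g in seq_along(gap_lo)) {
      if (any(fx_out$time >= gap_lo[g] & fx_out$time <= gap_hi[g]))
        n_oracle <- n_oracle + 1
    }
    expect_equal(nrow(tr), n_oracle)
    # every remaining fix lies in exactly one trip
    hits <- vapply(fx_out$time, function(tm)
      sum(tm >= tr$start & tm <= tr$end), 0)
    expect_true(all(hits == 1))
  }
})

make_summaries <- function(id, first_mid_h, n) {
  data.frame(id = id, interval_start = ts(first_mid_h - 1 + 2 * (0:(n - 1))),
             interval_end = ts(first_mid_h + 1 + 2 * (0:(n - 1))),
             prop_diving = 0.6, prop_hauled = 0)
}

test_that("regularisation interpolates positions at summary midpoints", {
  fx <- data.frame(id = "a", time = ts(c(0, 2)), x = c(0, 4), y = c(0, 0))
  sm <- make_summaries("a", 1, 1)
  iv <- regularize_track(fx, sm)
  expect_equal(iv$x, 2)
  expect_equal(iv$y, 0)
  # collinear equal-spaced fixes give zero turn angles throughout
  fx <- data.frame(id = "a", time = ts(seq(0, 20, 2)),
                   x = seq(0, 20, 2), y = seq(0, 10, 1))
  sm <- make_summaries("a", 1, 9)
  iv <- regularize_track(fx, sm)
  # first angle needs two displacements; the last interval has no next
  # midpoint, so its step (and hence angle) is missing
  expect_equal(iv$angle[2:8], rep(0, 7), tolerance = 1e-12)
  expect_true(all(is.na(iv$angle[c(1, 9)])))
  expect_equal(iv$step[1:8], rep(sqrt(4 + 1), 8), tolerance = 1e-12)
})

test_that("interpolated positions match an independent evaluator", {
  set.seed(5)
  fx <- data.frame(id = "a", time = ts(sort(runif(25, 0, 50))),
                   x = cumsum(rnorm(25)), y = cumsum(rnorm(25)))
  sm <- make_summaries("a", 1, 24)
  iv <- regularize_track(fx, sm)
  for (k in seq_len(nrow(iv))) {
    if (iv$time[k] < min(fx$time) || iv$time[k] > max(fx$time)) {
      expect_true(is.na(iv$x[k]))
    } else {
      o <- lerp_at(as.numeric(fx$time), fx$x, fx$y, as.numeric(iv$time[k]))
      expect_equal(c(iv$x[k], iv$y[k]), o, tolerance = 1e-9)
    }
  }
})

test_that("steps and angles are translation/rotation invariant", {
  set.seed(6)
  fx <- data.frame(id = "a", time = ts(seq(0, 30, 1.5)),
                   x = cumsum(rnorm(21)), y = cumsum(rnorm(21)))
  sm <- make_summaries("a", 1, 14)
  base <- regularize_track(fx, sm)
  th <- 0.83
  fx2 <- fx
  fx2$x <- 5 + cos(th) * fx$x - sin(th) * fx$y
  fx2$y <- -3 + sin(th) * fx$x + cos(th) * fx$y
  rot <- regularize_track(fx2, sm)
  expect_equal(rot$step, base$step, tolerance = 1e-9)
  expect_equal(rot$angle, base$angle, tolerance = 1e-9)
})

test_that("unreliable flagging uses a strict 6-h bracketing-gap rule", {
  sm <- make_summaries("a", 1, 3)   # midpoints at 1, 3, 5 h
  # fixes 7 h apart around the middle midpoint -> flagged
  fx <- data.frame(id = "a", time = ts(c(-0.5, 6.5)), x = 0:1, y = 0:1)
  iv <- flag_unreliable(regularize_track(fx, sm), fx)
  expect_true(iv$unreliable[2])
  # exactly 6 h apart -> not flagged
  fx <- data.frame(id = "a", time = ts(c(0, 6)), x = 0:1, y = 0:1)
  iv <- flag_unreliable(regularize_track(fx, sm), fx)
  expect_false(iv$unreliable[2])
  # missing summary record -> flagged regardless of fixes
  sm2 <- make_summaries("a", 1, 3)[-2, ]
  iv <- flag_unreliable(regularize_track(fx, sm2), fx)
  expect_true(iv$unreliable[2])
})

test_that("unreliable flags equal a brute-force re-scan on random gaps", {
  set.seed(9)
  fx <- data.frame(id = "a", time = ts(sort(runif(12, 0, 60))),
                   x = rnorm(12), y = rnorm(12))
  sm <- make_summaries("a", 1, 30)
  sm$prop_diving[sample(30, 4)] <- NA
  iv <- flag_unreliable(regularize_track(fx, sm), fx)
  for (k in seq_len(nrow(iv))) {
    tm <- iv$time[k]
    prevs <- fx$time[fx$time <= tm]; nexts <- fx$time[fx$time >= tm]
    gap_bad <- if (!length(prevs) || !length(nexts)) TRUE else
      as.numeric(difftime(min(nexts), max(prevs), units = "hours")) > 6
    expect_equal(iv$unreliable[k], gap_bad | is.na(iv$prop_diving[k]))
  }
})

test_that("known-state coding follows the diving threshold strictly", {
  expect_identical(diving_threshold(), 0.444)
  iv <- data.frame(id = "a", time = ts(c(1, 3, 5, 7)),
                   prop_diving = c(0.40, 0.444, 0.80, 0.95),
                   unreliable = c(FALSE, FALSE, TRUE, FALSE))
  expect_warning(out <- code_known_states(iv), "clamped")
  expect_equal(out$known, c("N", "free", "Unk", "free"))
  expect_equal(out$prop_diving[4], 0.888)
})

test_that("trip filters reproduce the stated rules and a predicate oracle", {
  set.seed(14)
  n <- 40
  trips <- data.frame(trip_id = sprintf("t%02d", 1:n), id = "a",
                      start = ts(runif(n, 0, 400)))
  trips$duration_h <- runif(n, 2, 40)
  trips$end <- trips$start + trips$duration_h * 3600
  iv <- data.frame(id = "a", time = ts(runif(300, 0, 5000)),
                   x = runif(300, 0, 10), y = runif(300, 0, 10))
  iv$trip_id <- trips$trip_id[sample(n, 300, replace = TRUE)]
  cap <- data.frame(id = "a", capture = ts(0))
  res <- filter_trips(trips, iv, cap, species = "grey")
  # oracle: survives iff started >= 168 h post capture and >= 8 h long
  keep_oracle <- trips$trip_id[
    as.numeric(difftime(trips$start, ts(0), units = "hours")) >= 168 &
      trips$duration_h >= 8]
  expect_setequal(res$trips$trip_id, keep_oracle)
  # boundary: a 7.9-h trip is removed
  tr2 <- data.frame(trip_id = c("x1", "x2"), id = "a",
                    start = ts(c(200, 200)), duration_h = c(7.9, 8.0))
  tr2$end <- tr2$start + tr2$duration_h * 3600
  res2 <- filter_trips(tr2, iv[0, ], cap, species = "grey")
  expect_equal(res2$trips$trip_id, "x2")
  # season windows are inclusive of the named boundary months
  iv3 <- data.frame(id = "a",
                    time = as.POSIXct(c("2015-07-01", "2015-11-01",
                                        "2015-05-15", "2015-09-30"),
                                      tz = "UTC"),
                    x = 0, y = 0, trip_id = NA_character_)
  res3 <- filter_trips(trips[0, ], iv3, cap, species = "grey")
  expect_equal(format(res3$intervals$time, "%m"), c("07", "05", "09"))
  res4 <- filter_trips(trips[0, ], iv3, cap, species = "harbour")
  expect_equal(format(res4$intervals$time, "%m"), c("11", "05", "09"))
  expect_error(filter_trips(trips, iv, cap, species = "leopard"),
               "unknown species")
})

test_that("exclusion polygons remove enclosed intervals", {
  iv <- data.frame(id = "a", time = ts(seq(1, 19, 2)),
                   x = seq(0.5, 9.5, 1), y = 5, trip_id = NA_character_)
  cap <- data.frame(id = "a", capture = ts(-10000))
  poly <- data.frame(x = c(2, 6, 6, 2), y = c(0, 0, 10, 10))
  res <- filter_trips(data.frame(trip_id = character(0), id = character(0),
                                 start = ts(0)[0], end = ts(0)[0],
                                 duration_h = numeric(0)),
                      iv, cap, species = "grey",
                      exclusion_polygons = list(poly))
  expect_true(all(res$intervals$x < 2 | res$intervals$x > 6))
  expect_equal(res$report$intervals_in_exclusion_polygons, 4)
})

test_that("region assignment splits cross-region trips at floor(n/2)", {
  ev <- data.frame(event_id = c("h1", "h2"), id = "a",
                   start = ts(c(-5, 100)), end = ts(c(-4, 101)))
  rm <- data.frame(event_id = c("h1", "h2"),
                   region = c("region_1", "region_3"))
  for (n in c(10, 7, 1)) {
    trips <- data.frame(trip_id = "t1", id = "a", start = ts(0),
                        end = ts(99), start_haulout = "h1",
                        end_haulout = "h2")
    iv <- data.frame(id = "a", time = ts(seq(1, by = 2, length.out = n)),
                     trip_id = "t1")
    out <- assign_regions(trips, iv, ev, rm)
    h <- floor(n / 2)
    expect_equal(out$region,
                 c(rep("region_1", h), rep("region_3", n - h)))
  }
  # same start/end region: whole trip labelled with it
  rm2 <- data.frame(event_id = c("h1", "h2"), region = "region_2")
  trips <- data.frame(trip_id = "t1", id = "a", start = ts(0), end = ts(99),
                      start_haulout = "h1", end_haulout = "h2")
  iv <- data.frame(id = "a", time = ts(seq(1, 19, 2)), trip_id = "t1")
  expect_equal(unique(assign_regions(trips, iv, ev, rm2)$region), "region_2")
  # haulout missing from the region map is an error naming the site
  expect_error(assign_regions(trips, iv, ev,
                              data.frame(event_id = "h1",
                                         region = "region_1")), "h2")
})

test_that("interval tables survive a CSV round-trip", {
  cfg <- simulation_config(2, 50, species = "grey",
                           movement_states_only = FALSE, seed = 2)
  tel <- tracks_to_telemetry(simulate_hmm_tracks(cfg))
  iv <- regularize_track(tel$fixes, tel$summaries)
  iv <- code_known_states(flag_unreliable(iv, tel$fixes))
  path <- tempfile(fileext = ".csv")
  write_intervals_csv(iv, path)
  back <- read_intervals_csv(path)
  expect_equal(back$time, iv$time)
  expect_equal(back$step, iv$step, tolerance = 1e-12)
  expect_equal(back$known, iv$known)
  unlink(path)
})

test_that("every coded interval carries exactly one known-state code", {
  cfg <- simulation_config(3, 200, species = "harbour",
                           movement_states_only = FALSE, gap_rate = 0.05,
                           seed = 8)
  tel <- tracks_to_telemetry(simulate_hmm_tracks(cfg))
  iv <- code_known_states(
    flag_unreliable(regularize_track(tel$fixes, tel$summaries), tel$fixes))
  expect_true(all(iv$known %in% c("N", "Unk", "free")))
  expect_false(any(is.na(iv$known)))
})
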