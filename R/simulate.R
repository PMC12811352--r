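#' Simulation configuration
#'
#' Bundles the study conditions for track simulation. Step lengths are in km
#' per 2-h interval throughout.
#'
#' @param n_individuals number of simulated animals (> 0).
#' @param n_intervals number of 2-h intervals per animal (> 0).
#' @param species `"grey"` or `"harbour"`: selects the generating parameter
#'   profile when none is supplied to [simulate_hmm_tracks()].
#' @param movement_states_only if `TRUE`, simulate the 3-state movement model
#'   (focussed ARS, broad ARS, transit); otherwise the 5-state model with
#'   non-diving and unknown states.
#' @param gap_rate probability, per interval, of an additional unreliable gap
#'   (missing position and summary data), in [0, 1).
#' @param seed integer seed; fixed seeds reproduce output exactly.
#' @param step_units label recording the step-length units.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_individuals, n_intervals,
                              species = c("grey", "harbour"),
                              movement_states_only = TRUE, gap_rate = 0,
                              seed = 1L,
                              step_units = "km per 2-h interval") {
  species <- match.arg(species)
  stopifnot(n_individuals >= 1, n_intervals >= 1,
            gap_rate >= 0, gap_rate < 1)
  structure(list(n_individuals = as.integer(n_individuals),
                 n_intervals = as.integer(n_intervals), species = species,
                 movement_states_only = isTRUE(movement_states_only),
                 gap_rate = gap_rate, seed = as.integer(seed),
                 step_units = step_units),
            class = "simulation_config")
}

sim_markov_chain <- function(n, Gamma, delta) {
  K <- nrow(Gamma)
  s <- integer(n)
  s[1] <- sample.int(K, 1, prob = delta)
  if (n > 1) for (t in 2:n) s[t] <- sample.int(K, 1, prob = Gamma[s[t - 1], ])
  s
}

# proportion of interval spent diving: movement states in (0.444, 0.888),
# non-diving in (0, 0.444); scaled Beta(2, 2) within each band
sim_dive_prop <- function(state_lab) {
  n <- length(state_lab)
  lo <- ifelse(state_lab %in% c("N", "Unk"), 0, 0.444)
  lo + 0.444 * rbeta(n, 2, 2)
}

#' Simulate tracks from a movement HMM
#'
#' Draws state sequences from the Markov chain, state-dependent steps
#' (gamma) and turn angles (wrapped Cauchy), and builds positions by dead
#' reckoning on a planar km grid. Observed steps and angles are then
#' recomputed from the positions, so they are deterministic functions of the
#' track; the turn angle is missing at the first interval and wherever an
#' adjoining step is missing or zero. Dive proportions fall below the
#' non-diving threshold (0.444) exactly for the non-diving state. Intervals
#' in the unknown state, and additional random gaps at `config$gap_rate`,
#' have missing position and summary fields.
#'
#' @param config a [simulation_config()].
#' @param params an [hmm_params()] object; defaults to
#'   [species_profile()] for the configured species and model order.
#' @return a list of per-individual data frames (class `ars_tracks`) with
#'   columns `id`, `time`, `x`, `y`, `step`, `angle`, `prop_diving`,
#'   `hauled`, `gap`, and the true `state`; the generating parameters are
#'   attached as attributes. Haulout events (runs of zero-step non-diving
#'   intervals) are in `attr(, "haulout_events")`.
#' @export
simulate_hmm_tracks <- function(config, params = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(params)) {
    params <- species_profile(config$species,
                              if (config$movement_states_only) 3 else 5)
  }
  stopifnot(inherits(params, "hmm_params"))
  if (any(abs(rowSums(params$Gamma) - 1) > 1e-8) || any(params$Gamma < 0))
    stop("transition matrix rows must be stochastic")
  set.seed(config$seed)
  K <- length(params$states)
  labs <- params$states
  # latent dynamics for the emission-free unknown state borrow the middle
  # movement state (unobserved either way)
  latent_idx <- function(s) ifelse(labs[s] == "Unk",
                                   min(2, params$n_move), s)
  t0 <- as.POSIXct("2015-01-01 01:00:00", tz = "UTC")
  tracks <- vector("list", config$n_individuals)
  events <- list()
  for (i in seq_len(config$n_individuals)) {
    Tn <- config$n_intervals
    s <- sim_markov_chain(Tn + 1, params$Gamma, params$delta)
    li <- latent_idx(s)
    mu <- full_par(params$mu, params); sg <- full_par(params$sigma, params)
    kp <- full_par(params$kappa, params); zm <- full_par(params$zeromass, params)
    steps <- vapply(li, function(z) rstep(1, mu[z], sg[z], zm[z]), 0)
    turns <- vapply(li, function(z) rwcauchy(1, kp[z]), 0)
    head0 <- runif(1, -pi, pi)
    headings <- head0 + cumsum(c(0, turns[-1]))
    x <- runif(1, 0, 50) + c(0, cumsum(steps * cos(headings)))
    y <- runif(1, 0, 50) + c(0, cumsum(steps * sin(headings)))
    state_lab <- labs[s[seq_len(Tn)]]
    gap <- state_lab == "Unk" | runif(Tn) < config$gap_rate
    xo <- x[seq_len(Tn)]; yo <- y[seq_len(Tn)]
    xo[gap] <- NA; yo[gap] <- NA
    xn <- x[seq_len(Tn) + 1]; yn <- y[seq_len(Tn) + 1]
    xn[c(gap[-1], FALSE)] <- NA; yn[c(gap[-1], FALSE)] <- NA
    step_obs <- sqrt((xn - xo)^2 + (yn - yo)^2)
    head_obs <- atan2(yn - yo, xn - xo)
    head_obs[is.na(step_obs) | step_obs == 0] <- NA
    angle_obs <- wrap_angle(c(NA, diff(head_obs)))
    angle_obs[is.na(step_obs)] <- NA
    prop <- sim_dive_prop(state_lab)
    prop[gap] <- NA
    hauled <- state_lab == "N" & !gap & steps[seq_len(Tn)] == 0
    id <- sprintf("ind_%02d", i)
    tr <- data.frame(id = id,
                     time = t0 + (seq_len(Tn) - 1) * 7200,
                     x = xo, y = yo, step = step_obs, angle = angle_obs,
                     prop_diving = prop, hauled = hauled, gap = gap,
                     state = state_lab, stringsAsFactors = FALSE)
    tracks[[i]] <- tr
    r <- rle(hauled)
    if (any(r$values)) {
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      keep <- r$values
      events[[i]] <- data.frame(
        event_id = sprintf("%s_ho%02d", id, seq_len(sum(keep))),
        id = id,
        start = tr$time[starts[keep]] - 3600,
        end = tr$time[ends[keep]] + 3600,
        x = tr$x[starts[keep]], y = tr$y[starts[keep]],
        stringsAsFactors = FALSE)
    }
  }
  structure(tracks, class = "ars_tracks", params = params, config = config,
            haulout_events = do.call(rbind, events))
}

#' Flatten simulated tracks into a fitting-ready interval table
#'
#' Derives the known-state code from the observables (dive proportion and
#' gap flag), exactly as [code_known_states()] would from real data.
#'
#' @param tracks output of [simulate_hmm_tracks()].
#' @return one data frame with columns `id`, `time`, `step`, `angle`,
#'   `prop_diving`, `unreliable`, `known` and the true `state`.
#' @export
tracks_to_intervals <- function(tracks) {
  stopifnot(inherits(tracks, "ars_tracks"))
  params <- attr(tracks, "params")
  out <- do.call(rbind, tracks)
  out$unreliable <- out$gap
  if ("Unk" %in% params$states) {
    out$known <- ifelse(out$gap, "Unk",
                        ifelse(out$prop_diving < diving_threshold(),
                               "N", "free"))
  } else {
    out$known <- "free"
  }
  rownames(out) <- NULL
  out
}

#' Convert simulated tracks to raw telemetry tables
#'
#' Produces the fix, 2-h summary and haulout-event tables consumed by the
#' preprocessing module, with per-fix satellite counts and residual quality
#' scores drawn within the accepted ranges.
#'
#' @param tracks output of [simulate_hmm_tracks()].
#' @return list with data frames `fixes` (`id`, `time`, `x`, `y`,
#'   `n_satellites`, `residual`), `summaries` (`id`, `interval_start`,
#'   `interval_end`, `prop_diving`, `prop_hauled`), `haulout_events` and
#'   `true_states`.
#' @export
tracks_to_telemetry <- function(tracks) {
  stopifnot(inherits(tracks, "ars_tracks"))
  all <- do.call(rbind, tracks)
  rownames(all) <- NULL
  ok <- !all$gap & !is.na(all$x)
  fixes <- data.frame(id = all$id[ok], time = all$time[ok],
                      x = all$x[ok], y = all$y[ok],
                      n_satellites = sample(5:12, sum(ok), replace = TRUE),
                      residual = runif(sum(ok), 0, 25),
                      stringsAsFactors = FALSE)
  summaries <- data.frame(id = all$id,
                          interval_start = all$time - 3600,
                          interval_end = all$time + 3600,
                          prop_diving = all$prop_diving,
                          prop_hauled = ifelse(all$hauled,
                                               runif(nrow(all), 0.6, 1), 0),
                          stringsAsFactors = FALSE)
  summaries <- summaries[!all$gap, ]
  rownames(summaries) <- NULL
  list(fixes = fixes, summaries = summaries,
       haulout_events = attr(tracks, "haulout_events"),
       true_states = all[, c("id", "time", "state")])
}

# ---- seascape ------------------------------------------------------------

GEOMORPH_LEVELS <- c("trough", "gradual_slope", "steep_slope", "peak")
SUBSTRATE_LEVELS <- c("mud", "sand", "gravel", "rock_reef")

# smooth random surface as a sum of Gaussian bumps over the grid
smooth_field <- function(xc, yc, extent, n_bumps = 40) {
  span <- max(extent[2] - extent[1], extent[4] - extent[3])
  cx <- runif(n_bumps, extent[1], extent[2])
  cy <- runif(n_bumps, extent[3], extent[4])
  w <- runif(n_bumps, 0.08, 0.25) * span
  a <- rnorm(n_bumps)
  f <- numeric(length(xc))
  for (b in seq_len(n_bumps)) {
    f <- f + a[b] * exp(-((xc - cx[b])^2 + (yc - cy[b])^2) / (2 * w[b]^2))
  }
  f
}

#' Build a synthetic gridded seascape
#'
#' Smooth random fields are thresholded at quartiles into categorical
#' geomorphology and substrate patches; potential energy anomaly (PEA,
#' J/m3) is a smooth non-negative surface; regions are contiguous
#' longitudinal blocks each containing one haulout site.
#'
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in km, non-degenerate.
#' @param n_regions number of regions (>= 1); default 6.
#' @param seed integer seed.
#' @param cell_km grid cell size in km.
#' @return an object of class `seascape`: grid geometry, a per-cell
#'   data frame (`x`, `y`, `geomorphology`, `substrate`, `region`, `pea`),
#'   the haulout-site table, and the categorical level sets.
#' @export
build_seascape <- function(extent = c(0, 240, 0, 120), n_regions = 6,
                           seed = 1L, cell_km = 2) {
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3])
  if (n_regions < 1) stop("n_regions must be >= 1")
  set.seed(seed)
  nx <- max(1L, floor((extent[2] - extent[1]) / cell_km))
  ny <- max(1L, floor((extent[4] - extent[3]) / cell_km))
  xc <- extent[1] + (rep(seq_len(nx), times = ny) - 0.5) * cell_km
  yc <- extent[3] + (rep(seq_len(ny), each = nx) - 0.5) * cell_km
  f1 <- smooth_field(xc, yc, extent)
  f2 <- smooth_field(xc, yc, extent)
  f3 <- smooth_field(xc, yc, extent)
  cut4 <- function(f, levels) {
    q <- quantile(f, c(0.25, 0.5, 0.75))
    levels[findInterval(f, q) + 1]
  }
  geom <- cut4(f1, GEOMORPH_LEVELS)
  subs <- cut4(f2, SUBSTRATE_LEVELS)
  pea <- 60 * plogis(1.5 * (f3 - mean(f3)) / max(sd(f3), 1e-12))
  region_names <- sprintf("region_%d", seq_len(n_regions))
  breaks <- extent[1] + (extent[2] - extent[1]) * seq_len(n_regions - 1) /
    n_regions
  region <- region_names[findInterval(xc, breaks) + 1]
  grid <- data.frame(x = xc, y = yc, geomorphology = geom, substrate = subs,
                     region = region, pea = pea, stringsAsFactors = FALSE)
  haulouts <- do.call(rbind, lapply(region_names, function(r) {
    i <- sample(which(region == r), 1)
    data.frame(site = paste0("site_", r), region = r,
               x = xc[i], y = yc[i], stringsAsFactors = FALSE)
  }))
  structure(list(cell_km = cell_km, x0 = extent[1], y0 = extent[3],
                 nx = nx, ny = ny, extent = extent, grid = grid,
                 haulouts = haulouts,
                 levels = list(geomorphology = GEOMORPH_LEVELS,
                               substrate = SUBSTRATE_LEVELS,
                               region = region_names)),
            class = "seascape")
}

#' Extract seascape covariates at point locations
#'
#' Nearest-cell lookup (no interpolation) for all covariate layers; points
#' outside the grid extent return `NA` in every layer.
#'
#' @param seascape a [build_seascape()] object.
#' @param x,y point coordinates (km).
#' @return data frame with one row per point: `geomorphology`, `substrate`,
#'   `region`, `pea`.
#' @export
seascape_extract <- function(seascape, x, y) {
  stopifnot(inherits(seascape, "seascape"))
  ix <- ceiling((x - seascape$x0) / seascape$cell_km)
  iy <- ceiling((y - seascape$y0) / seascape$cell_km)
  ix[ix == 0] <- 1L; iy[iy == 0] <- 1L  # points exactly on the lower edge
  bad <- is.na(ix) | is.na(iy) | ix < 1 | ix > seascape$nx |
    iy < 1 | iy > seascape$ny
  idx <- (iy - 1) * seascape$nx + ix
  idx[bad] <- NA_integer_
  out <- seascape$grid[idx, c("geomorphology", "substrate", "region", "pea")]
  rownames(out) <- NULL
  out
}

#' Write / read a seascape as plain-text files
#'
#' The grid is stored as one CSV row per cell with integer-coded categorical
#' layers and a sidecar JSON legend holding the grid geometry and level
#' codes; haulout sites go in their own CSV.
#'
#' @param seascape a `seascape` object.
#' @param dir directory to write into (created if needed).
#' @return `write_seascape()` returns `dir` invisibly; `read_seascape()`
#'   returns the reconstructed `seascape` object.
#' @export
write_seascape <- function(seascape, dir) {
  stopifnot(inherits(seascape, "seascape"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- seascape$grid
  enc <- data.frame(x = g$x, y = g$y,
                    geomorphology = match(g$geomorphology,
                                          seascape$levels$geomorphology),
                    substrate = match(g$substrate, seascape$levels$substrate),
                    region = match(g$region, seascape$levels$region),
                    pea = g$pea)
  write.csv(enc, file.path(dir, "seascape_grid.csv"), row.names = FALSE)
  write.csv(seascape$haulouts, file.path(dir, "seascape_haulouts.csv"),
            row.names = FALSE)
  legend <- list(cell_km = seascape$cell_km, x0 = seascape$x0,
                 y0 = seascape$y0, nx = seascape$nx, ny = seascape$ny,
                 extent = seascape$extent, levels = seascape$levels)
  jsonlite::write_json(legend, file.path(dir, "seascape_legend.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_seascape
#' @export
read_seascape <- function(dir) {
  legend <- jsonlite::read_json(file.path(dir, "seascape_legend.json"),
                                simplifyVector = TRUE)
  enc <- read.csv(file.path(dir, "seascape_grid.csv"))
  grid <- data.frame(x = enc$x, y = enc$y,
                     geomorphology = legend$levels$geomorphology[enc$geomorphology],
                     substrate = legend$levels$substrate[enc$substrate],
                     region = legend$levels$region[enc$region],
                     pea = enc$pea, stringsAsFactors = FALSE)
  structure(list(cell_km = legend$cell_km, x0 = legend$x0, y0 = legend$y0,
                 nx = legend$nx, ny = legend$ny, extent = legend$extent,
                 grid = grid,
                 haulouts = read.csv(file.path(dir, "seascape_haulouts.csv"),
                                     stringsAsFactors = FALSE),
                 levels = legend$levels),
            class = "seascape")
}

# ---- habitat-driven state simulation ------------------------------------

#' Logit coefficient sets for habitat-driven state simulation
#'
#' Each component (`ars` for P(ARS | encounter), `fars` for
#' P(focussed | ARS)) holds an intercept, optional named effect vectors for
#' `region`, `geomorphology` and `substrate` (treatment-style: unnamed levels
#' contribute 0), and an optional smooth `pea` effect given as a function of
#' PEA.
#'
#' @param ars,fars lists with elements `intercept`, `region`,
#'   `geomorphology`, `substrate` (named numeric vectors) and `pea`
#'   (function or `NULL`).
#' @return a validated `habitat_coefs` object.
#' @export
habitat_coefs <- function(ars = list(intercept = 0),
                          fars = list(intercept = 0)) {
  check <- function(cf, nm) {
    cf$intercept <- if (is.null(cf$intercept)) 0 else cf$intercept
    for (term in c("intercept", "region", "geomorphology", "substrate")) {
      v <- cf[[term]]
      if (!is.null(v) && (any(!is.finite(v))))
        stop("non-finite coefficient in ", nm, "$", term)
    }
    if (!is.null(cf$pea) && !is.function(cf$pea))
      stop("pea effect must be a function or NULL")
    cf
  }
  structure(list(ars = check(ars, "ars"), fars = check(fars, "fars")),
            class = "habitat_coefs")
}

lin_pred <- function(cf, cov) {
  eta <- rep(cf$intercept, nrow(cov))
  for (term in c("region", "geomorphology", "substrate")) {
    v <- cf[[term]]
    if (!is.null(v)) {
      e <- v[cov[[term]]]
      e[is.na(e)] <- 0
      eta <- eta + e
    }
  }
  if (!is.null(cf$pea)) eta <- eta + cf$pea(cov$pea)
  as.numeric(eta)
}

#' Simulate habitat-driven behavioural states
#'
#' The generative counterpart of the nested binomial use-encounter model:
#' each 2-h interval is dropped on a random seascape cell and its state is
#' drawn by two nested Bernoulli draws — ARS vs transit from
#' `plogis(eta_ars + u_i)`, then focussed vs broad ARS from
#' `plogis(eta_fars + v_i)` — with per-individual random intercepts
#' `u_i, v_i ~ N(0, random_intercept_sd^2)`. The generating probabilities
#' (both conditional on the individual and at the population level, random
#' intercepts zero) are stored alongside for recovery tests.
#'
#' @param seascape a [build_seascape()] object.
#' @param coefficients a [habitat_coefs()] object.
#' @param random_intercept_sd SD of the individual random intercepts.
#' @param n_individuals,n_intervals numbers of animals and intervals each.
#' @param seed integer seed.
#' @return data frame with habitat covariates, `id`, drawn `state`
#'   (`"Tr"`, `"bARS"`, `"fARS"`) and generating probabilities
#'   (`p_ars`, `p_fars`, `p_ars_pop`, `p_fars_pop`).
#' @export
simulate_habitat_driven_states <- function(seascape, coefficients,
                                           random_intercept_sd = 0.5,
                                           n_individuals, n_intervals,
                                           seed = 1L) {
  stopifnot(inherits(seascape, "seascape"),
            inherits(coefficients, "habitat_coefs"),
            random_intercept_sd >= 0, n_individuals >= 1, n_intervals >= 1)
  set.seed(seed)
  n <- n_individuals * n_intervals
  cells <- sample.int(nrow(seascape$grid), n, replace = TRUE)
  cov <- seascape$grid[cells, c("region", "geomorphology", "substrate", "pea")]
  rownames(cov) <- NULL
  id <- rep(sprintf("ind_%03d", seq_len(n_individuals)), each = n_intervals)
  u <- rnorm(n_individuals, 0, random_intercept_sd)
  v <- rnorm(n_individuals, 0, random_intercept_sd)
  iid <- rep(seq_len(n_individuals), each = n_intervals)
  eta1 <- lin_pred(coefficients$ars, cov)
  eta2 <- lin_pred(coefficients$fars, cov)
  p1 <- plogis(eta1 + u[iid]); p2 <- plogis(eta2 + v[iid])
  y1 <- rbinom(n, 1, p1)
  y2 <- rbinom(n, 1, p2)
  state <- ifelse(y1 == 0, "Tr", ifelse(y2 == 1, "fARS", "bARS"))
  out <- data.frame(id = id, cov, state = state,
                    p_ars = p1, p_fars = p2,
                    p_ars_pop = plogis(eta1), p_fars_pop = plogis(eta2),
                    stringsAsFactors = FALSE)
  attr(out, "coefficients") <- coefficients
  attr(out, "random_intercepts") <- list(ars = u, fars = v)
  out
}
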