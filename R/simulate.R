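#' Configuration for the paired-track simulator
#'
#' Defines the study conditions the generator emulates: two central-place
#' foragers per pair alternating foraging trips and nest bouts over the
#' 30-day chick-rearing window, GPS fixes every 180 s, gamma trip durations
#' with mean 4.4 h, gamma nest-bout durations with a log-linear decline in
#' offspring age, and a tunable probability `coordination_w` that a departure
#' is deferred until the partner is back in the colony (departure-gating:
#' coordination of timing, not of trip durations). Within trips, movement is
#' behaviour-dependent (commute out, area-restricted foraging, optional rest,
#' commute back), each individual holds 1-3 persistent foraging sites, and an
#' accelerometer-style behaviour class is emitted through a row-stochastic
#' confusion matrix.
#'
#' @param n_pairs Number of pairs (default 25, as in a two-colony field
#'   deployment of this design).
#' @param days Length of the chick-rearing window in days (default 30).
#' @param fix_interval GPS fix interval in seconds (default 180).
#' @param colony A `colony_geometry` (default 500 m circle on the southern
#'   North Sea coast).
#' @param trip_shape,trip_mean_h Gamma shape and mean (hours) of trip
#'   durations.
#' @param bout_shape,bout_mean_h Gamma shape and mean (hours) of nest-bout
#'   durations at offspring age 0.
#' @param beta_age Log-scale slope of bout duration on offspring age
#'   (days); negative values shorten bouts as chicks grow.
#' @param coordination_w Probability in `[0, 1]` that a departure waits for
#'   the partner's return.
#' @param wait_lag_mean_h Mean of the exponential lag added after the
#'   partner's return when waiting.
#' @param speeds_mps Named speeds (m/s) for `rest`, `commute`, `forage`.
#' @param n_sites_range Range of persistent foraging sites per individual.
#' @param site_dist_km_range Distance range of foraging sites from the
#'   colony.
#' @param shared_sites If `TRUE` both pair members use the same site set
#'   (shared environment); if `FALSE` sites are drawn independently.
#' @param site_habitats Habitat labels assigned to foraging sites.
#' @param acc_confusion 3x3 row-stochastic matrix (rows/cols
#'   rest, commute, forage) mapping true behaviour to the emitted
#'   accelerometer class.
#' @param start_date POSIXct origin of the simulated window (hatch date).
#' @param colony_ids Labels used to split pairs across colonies.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 25, days = 30, fix_interval = 180,
                       colony = colony_circle(51.45, 3.69, 500),
                       trip_shape = 4, trip_mean_h = 4.4,
                       bout_shape = 2.5, bout_mean_h = 3.6,
                       beta_age = -0.0142,
                       coordination_w = 0.65, wait_lag_mean_h = 0.25,
                       speeds_mps = c(rest = 0.05, commute = 10, forage = 1.5),
                       n_sites_range = c(1, 3),
                       site_dist_km_range = c(15, 60),
                       shared_sites = FALSE,
                       site_habitats = c("agriculture", "urban", "coast"),
                       acc_confusion = NULL,
                       start_date = as.POSIXct("2016-06-01", tz = "UTC"),
                       colony_ids = c("VL", "ZB")) {
  if (is.null(acc_confusion)) {
    acc_confusion <- matrix(c(0.90, 0.05, 0.05,
                              0.05, 0.90, 0.05,
                              0.05, 0.05, 0.90), 3, 3, byrow = TRUE,
                            dimnames = list(c("rest", "commute", "forage"),
                                            c("rest", "commute", "forage")))
  }
  if (coordination_w < 0 || coordination_w > 1)
    stop("coordination_w must be in [0, 1]")
  stopifnot(trip_shape > 0, trip_mean_h > 0, bout_shape > 0, bout_mean_h > 0,
            fix_interval > 0, days > 0, n_pairs >= 1,
            all(abs(rowSums(acc_confusion) - 1) < 1e-12))
  structure(as.list(environment()), class = "sim_config")
}

# deterministic child seed below 2^31 from a master seed and an index
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed %% 100003L) * 20011 +
                as.numeric(index) * 7919 + 12345) %% 2147483629)
}

#' Simulate the joint trip/bout schedules of one pair
#'
#' Event-driven generation of two alternating trip/bout timelines. Both birds
#' start the window in the colony. At each imminent departure a coordination
#' coin (probability `coordination_w`) decides whether the bird waits: if the
#' partner is away, the bout is extended until the partner's return plus an
#' exponential lag, and the decision is re-checked at the deferred instant,
#' so a waiting bird never departs while its partner is away. Bout means
#' decline log-linearly with offspring age. The window-final interval of each
#' bird is clipped at the window end and flagged censored.
#'
#' @param config A [sim_config()].
#' @param pair_id Pair identifier.
#' @param colony_id Colony label for the pair.
#' @return A list with `intervals` (truth trips and bouts, one
#'   `data.frame`), and `sites` (per-individual foraging sites).
#' @export
simulate_pair_schedules <- function(config, pair_id = "P01",
                                    colony_id = config$colony_ids[1]) {
  W <- config$days * 24
  ids <- paste0(pair_id, c("-M", "-F"))
  sexes <- c("male", "female")
  rtrip <- function() stats::rgamma(1, config$trip_shape,
                                    scale = config$trip_mean_h / config$trip_shape)
  rbout <- function(age) stats::rgamma(1, config$bout_shape,
                                       scale = config$bout_mean_h *
                                         exp(config$beta_age * age) / config$bout_shape)

  sites <- .draw_sites(config, ids)

  cur_type <- c("bout", "bout")
  cur_start <- c(0, 0)
  cur_end <- c(rbout(0), rbout(0))
  cur_site <- c(NA_integer_, NA_integer_)
  waiting <- c(FALSE, FALSE)
  coin_drawn <- c(FALSE, FALSE)
  rows <- list()
  push <- function(i, type, s, e, site) {
    rows[[length(rows) + 1]] <<- data.frame(
      individual_id = ids[i], pair_id = pair_id, sex = sexes[i],
      colony_id = colony_id, type = type, start_h = s, end_h = e,
      site = site, stringsAsFactors = FALSE)
  }

  while (min(cur_end) < W) {
    i <- which.min(cur_end)
    t <- cur_end[i]
    j <- 3L - i
    if (cur_type[i] == "bout") {
      if (!coin_drawn[i]) {
        waiting[i] <- stats::runif(1) < config$coordination_w
        coin_drawn[i] <- TRUE
      }
      partner_away <- cur_type[j] == "trip" && cur_end[j] > t
      if (waiting[i] && partner_away) {
        cur_end[i] <- cur_end[j] + stats::rexp(1, 1 / config$wait_lag_mean_h)
      } else {
        push(i, "bout", cur_start[i], t, NA_integer_)
        cur_type[i] <- "trip"
        cur_start[i] <- t
        cur_end[i] <- t + rtrip()
        cur_site[i] <- sample.int(nrow(sites[[ids[i]]]), 1)
        coin_drawn[i] <- FALSE
        waiting[i] <- FALSE
      }
    } else {
      push(i, "trip", cur_start[i], t, cur_site[i])
      cur_type[i] <- "bout"
      cur_start[i] <- t
      cur_end[i] <- t + rbout(floor(t / 24))
      cur_site[i] <- NA_integer_
    }
  }
  for (i in 1:2) {
    if (cur_start[i] < W)
      push(i, cur_type[i], cur_start[i], W,
           if (cur_type[i] == "trip") cur_site[i] else NA_integer_)
  }
  iv <- do.call(rbind, rows)
  iv <- iv[order(iv$individual_id, iv$start_h), , drop = FALSE]
  iv$duration_h <- iv$end_h - iv$start_h
  iv$censored_start <- iv$start_h == 0
  iv$censored_end <- iv$end_h == W
  iv$age_start <- floor(iv$start_h / 24)
  iv$start <- config$start_date + iv$start_h * 3600
  iv$end <- config$start_date + iv$end_h * 3600
  rownames(iv) <- NULL
  list(intervals = iv, sites = sites)
}

.draw_sites <- function(config, ids) {
  draw_one <- function() {
    ns <- seq(config$n_sites_range[1], config$n_sites_range[2])
    n <- ns[sample.int(length(ns), 1)]
    d <- stats::runif(n, config$site_dist_km_range[1], config$site_dist_km_range[2])
    b <- stats::runif(n, 0, 360)
    p <- dest_point(config$colony$lat, config$colony$lon, b, d * 1000)
    data.frame(lat = p[, "lat"], lon = p[, "lon"], dist_km = d, bearing = b,
               habitat = sample(config$site_habitats, n, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  s1 <- draw_one()
  s2 <- if (config$shared_sites) s1 else draw_one()
  stats::setNames(list(s1, s2), ids)
}

#' Simulate one pair, optionally with per-fix tracks
#'
#' Generates the pair's joint schedules ([simulate_pair_schedules()]) and, if
#' `fixes = TRUE`, samples GPS fixes every `fix_interval` seconds along a
#' behaviour-dependent trajectory: commuting straight towards the trip's
#' foraging site, area-restricted search around it (short tortuous steps),
#' an optional rest phase, and a straight commute back, with the bird at its
#' nest during bouts. Each fix records the true behaviour, a noisy ground
#' speed, an accelerometer class drawn through the configured confusion
#' matrix, and a habitat label from the site map.
#'
#' @param config A [sim_config()].
#' @param pair_id,colony_id Identifiers.
#' @param seed Optional integer seed (set before any draws).
#' @param fixes Generate per-fix tracks (slower) or schedules only.
#' @return List with `truth` (interval `data.frame`), `fixes` (or `NULL`),
#'   `sites`, `pair_id`, `seed`.
#' @export
simulate_pair <- function(config, pair_id = "P01",
                          colony_id = config$colony_ids[1],
                          seed = NULL, fixes = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  sch <- simulate_pair_schedules(config, pair_id, colony_id)
  fx <- NULL
  if (fixes) {
    fx <- do.call(rbind, lapply(unique(sch$intervals$individual_id), function(id)
      .simulate_fixes_individual(config, sch$intervals[sch$intervals$individual_id == id, ],
                                 sch$sites[[id]])))
    rownames(fx) <- NULL
  }
  list(truth = sch$intervals, fixes = fx, sites = sch$sites,
       pair_id = pair_id, seed = seed)
}

.simulate_fixes_individual <- function(config, iv, sites) {
  W <- config$days * 24
  dt_h <- config$fix_interval / 3600
  th <- seq(0, W, by = dt_h)
  nest <- dest_point(config$colony$lat, config$colony$lon,
                     stats::runif(1, 0, 360),
                     stats::runif(1, 0, 0.2 * config$colony$radius_m))
  lat <- rep(nest[1, "lat"], length(th))
  lon <- rep(nest[1, "lon"], length(th))
  behav <- rep("rest", length(th))

  trips <- iv[iv$type == "trip", , drop = FALSE]
  for (k in seq_len(nrow(trips))) {
    s <- trips$start_h[k]; e <- trips$end_h[k]
    idx <- which(th >= s & th < e)
    if (!length(idx)) next
    site <- sites[if (is.na(trips$site[k])) 1 else trips$site[k], ]
    tr <- .trip_trajectory(config, th[idx] - s, e - s, site)
    lat[idx] <- tr$lat; lon[idx] <- tr$lon; behav[idx] <- tr$behav
  }
  # nest jitter for resting fixes at the colony
  at_nest <- behav == "rest" & great_circle_km(lat, lon, nest[1, "lat"],
                                               nest[1, "lon"]) < 0.001
  jit <- dest_point(lat[at_nest], lon[at_nest],
                    stats::runif(sum(at_nest), 0, 360),
                    abs(stats::rnorm(sum(at_nest), 0, 3)))
  lat[at_nest] <- jit[, "lat"]; lon[at_nest] <- jit[, "lon"]

  sp_mean <- config$speeds_mps[behav]
  speed <- pmax(0, stats::rnorm(length(th), sp_mean,
                                pmax(0.02, 0.1 * sp_mean)))
  acc <- vapply(behav, function(b)
    sample(colnames(config$acc_confusion), 1,
           prob = config$acc_confusion[b, ]), character(1))
  habitat <- .habitat_at(config, sites, lat, lon)
  data.frame(individual_id = iv$individual_id[1], pair_id = iv$pair_id[1],
             sex = iv$sex[1], colony_id = iv$colony_id[1],
             timestamp = config$start_date + th * 3600,
             lat = lat, lon = lon, ground_speed = unname(speed),
             acc_class = unname(acc), habitat = habitat,
             true_behaviour = behav, stringsAsFactors = FALSE)
}

# positions within one trip at elapsed hours `u` (0 <= u < total duration T)
.trip_trajectory <- function(config, u, T, site) {
  v_c_kmh <- config$speeds_mps[["commute"]] * 3.6
  v_f_kmh <- config$speeds_mps[["forage"]] * 3.6
  D <- site$dist_km
  Tc <- D / v_c_kmh
  if (2 * Tc > 0.6 * T) {          # short trip: scale the site inward
    D <- 0.3 * T * v_c_kmh
    Tc <- D / v_c_kmh
  }
  site_pos <- dest_point(config$colony$lat, config$colony$lon,
                         site$bearing, D * 1000)
  T_site <- T - 2 * Tc
  rest_frac <- stats::runif(1, 0.1, 0.35)
  T_forage <- (1 - rest_frac) * T_site
  t_ret <- Tc + T_site               # start of return commute

  n <- length(u)
  lat <- numeric(n); lon <- numeric(n); behav <- character(n)
  # forage random walk precomputed sequentially over the forage fixes
  forage_idx <- which(u >= Tc & u < Tc + T_forage)
  pos <- c(site_pos[1, "lat"], site_pos[1, "lon"])
  heading <- stats::runif(1, 0, 360)
  last_forage_pos <- pos
  for (i in forage_idx) {
    step_m <- config$speeds_mps[["forage"]] * config$fix_interval
    heading <- (heading + stats::rnorm(1, 0, 70)) %% 360
    if (great_circle_km(pos[1], pos[2], site_pos[1, "lat"], site_pos[1, "lon"]) > 2)
      heading <- bearing_deg(pos[1], pos[2], site_pos[1, "lat"], site_pos[1, "lon"])
    np <- dest_point(pos[1], pos[2], heading, step_m)
    pos <- c(np[1, "lat"], np[1, "lon"])
    lat[i] <- pos[1]; lon[i] <- pos[2]; behav[i] <- "forage"
    last_forage_pos <- pos
  }
  for (i in seq_len(n)) {
    if (u[i] < Tc) {                              # commute out
      d_m <- config$speeds_mps[["commute"]] * u[i] * 3600
      p <- dest_point(config$colony$lat, config$colony$lon,
                      site$bearing + stats::rnorm(1, 0, 2), d_m)
      lat[i] <- p[1, "lat"]; lon[i] <- p[1, "lon"]; behav[i] <- "commute"
    } else if (u[i] < Tc + T_forage) {
      # filled above
    } else if (u[i] < t_ret) {                    # rest at the last site
      p <- dest_point(last_forage_pos[1], last_forage_pos[2],
                      stats::runif(1, 0, 360), abs(stats::rnorm(1, 0, 3)))
      lat[i] <- p[1, "lat"]; lon[i] <- p[1, "lon"]; behav[i] <- "rest"
    } else {                                      # commute back
      frac <- min(1, (T - u[i]) / Tc)
      d_m <- frac * great_circle_km(config$colony$lat, config$colony$lon,
                                    last_forage_pos[1], last_forage_pos[2]) * 1000
      brg <- bearing_deg(config$colony$lat, config$colony$lon,
                         last_forage_pos[1], last_forage_pos[2])
      p <- dest_point(config$colony$lat, config$colony$lon, brg, d_m)
      lat[i] <- p[1, "lat"]; lon[i] <- p[1, "lon"]; behav[i] <- "commute"
    }
  }
  list(lat = lat, lon = lon, behav = behav)
}

.habitat_at <- function(config, sites, lat, lon) {
  hab <- rep("marine", length(lat))
  for (k in seq_len(nrow(sites))) {
    near <- great_circle_km(lat, lon, sites$lat[k], sites$lon[k]) <= 3
    hab[near] <- sites$habitat[k]
  }
  in_col <- in_colony(config$colony, lat, lon)
  hab[in_col] <- "urban"
  hab
}

#' Simulate a whole colony of pairs
#'
#' Runs [simulate_pair()] for `n_pairs` pairs with per-pair child seeds
#' derived deterministically from the master seed, so the same master seed
#' reproduces the whole dataset bit-identically and each pair is independent.
#' Pairs are split across the configured colony labels.
#'
#' @param config A [sim_config()].
#' @param seed Master seed (integer).
#' @param fixes Generate per-fix tracks.
#' @return List with combined `fixes`, `truth`, `manifest` (pair, colony,
#'   child seed) and the `config`.
#' @export
simulate_colony <- function(config, seed = 1, fixes = TRUE) {
  n <- config$n_pairs
  half <- ceiling(n / 2)
  manifest <- data.frame(
    pair_id = sprintf("P%02d", seq_len(n)),
    colony_id = rep(config$colony_ids, c(half, n - half))[seq_len(n)],
    seed = vapply(seq_len(n), function(k) derive_seed(seed, k), integer(1)),
    stringsAsFactors = FALSE)
  sims <- lapply(seq_len(n), function(k)
    simulate_pair(config, manifest$pair_id[k], manifest$colony_id[k],
                  seed = manifest$seed[k], fixes = fixes))
  list(fixes = if (fixes) do.call(rbind, lapply(sims, `[[`, "fixes")) else NULL,
       truth = do.call(rbind, lapply(sims, `[[`, "truth")),
       manifest = manifest, config = config, seed = seed,
       sites = lapply(sims, `[[`, "sites"))
}

#' Pair schedules from simulator truth tables
#'
#' Convenience: builds one [pair_schedule()] per pair directly from the
#' simulator's truth intervals.
#'
#' @param truth Truth interval `data.frame` from [simulate_colony()].
#' @return Named list of `pair_schedule`s.
#' @export
truth_schedules <- function(truth) {
  lapply(split(truth, truth$pair_id), pair_schedule)
}
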