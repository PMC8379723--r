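#' Segment one individual's fixes into foraging trips and nest bouts
#'
#' Splices a time-sorted fix series into alternating out-of-colony foraging
#' trips and in-colony nest bouts. A trip starts at the last fix inside the
#' colony boundary before an out-of-colony run and ends at the first fix
#' inside the boundary after it; bouts are the complementary in-colony
#' intervals. Everything is clipped to the chick-rearing window given by
#' `brood`. Trips spanning darkness are retained; there is no diel gating.
#'
#' Tracks that begin (end) with an out-of-colony run yield a trip whose start
#' (end) is the first (last) fix, flagged `censored_start` (`censored_end`).
#' The first and last interval of the window are always flagged as censored at
#' the window edge, since their true start/end was not observed. When a single
#' in-colony fix separates two trips, a zero-duration bout is emitted so that
#' trips and bouts keep alternating and tile the window; duration-based models
#' drop such degenerate bouts.
#'
#' @param fixes Fix `data.frame` for one individual (see [read_fixes()]).
#' @param colony A `colony_geometry`.
#' @param brood A [brood_info()] row for the individual's pair.
#' @return A list with `data.frame`s `trips` and `bouts`. Columns:
#'   `individual_id, pair_id, sex, colony_id, type, start, end, duration_h,
#'   distance_km (trips), n_fixes, censored_start, censored_end, age_start`.
#' @export
segment_track <- function(fixes, colony, brood) {
  stopifnot(nrow(fixes) >= 1, length(unique(fixes$individual_id)) == 1)
  keep <- fixes$timestamp >= brood$hatch_date & fixes$timestamp <= brood$end_date
  f <- fixes[keep, , drop = FALSE]
  if (nrow(f) == 0) {
    warning("no fixes inside the chick-rearing window for ",
            fixes$individual_id[1])
    empty <- .empty_intervals()
    return(list(trips = empty, bouts = empty))
  }
  if (is.unsorted(as.numeric(f$timestamp), strictly = TRUE))
    stop("fixes must be strictly time-sorted")
  inside <- in_colony(colony, f$lat, f$lon)
  n <- nrow(f)
  ts <- f$timestamp

  r <- rle(inside)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  out_runs <- which(!r$values)

  meta <- list(individual_id = f$individual_id[1], pair_id = f$pair_id[1],
               sex = f$sex[1], colony_id = f$colony_id[1])

  trips <- lapply(out_runs, function(k) {
    i <- run_start[k]; j <- run_end[k]
    s_idx <- if (i > 1) i - 1L else i
    e_idx <- if (j < n) j + 1L else j
    idx <- s_idx:e_idx
    data.frame(meta, type = "trip",
               start = ts[s_idx], end = ts[e_idx],
               duration_h = as.numeric(difftime(ts[e_idx], ts[s_idx], units = "hours")),
               distance_km = track_distance_km(f$lat[idx], f$lon[idx]),
               n_fixes = length(idx),
               censored_start = i == 1L,
               censored_end = j == n,
               age_start = offspring_age(ts[s_idx], brood$hatch_date),
               stringsAsFactors = FALSE)
  })
  trips <- if (length(trips)) do.call(rbind, trips) else .empty_intervals()

  # bouts: in-colony complements between consecutive trips plus window edges;
  # when the track starts (ends) mid-trip the zero-length edge complement is
  # dropped -- the censored trip already reaches the window edge
  edges_start <- c(ts[1], trips$end)
  edges_end <- c(trips$start, ts[n])
  keep_b <- rep(TRUE, length(edges_start))
  if (nrow(trips) > 0 && trips$censored_start[1]) keep_b[1] <- FALSE
  if (nrow(trips) > 0 && trips$censored_end[nrow(trips)])
    keep_b[length(keep_b)] <- FALSE
  bouts <- data.frame(meta, type = "bout",
                      start = edges_start, end = edges_end,
                      duration_h = as.numeric(difftime(edges_end, edges_start,
                                                       units = "hours")),
                      distance_km = NA_real_, n_fixes = NA_integer_,
                      censored_start = FALSE, censored_end = FALSE,
                      age_start = offspring_age(edges_start, brood$hatch_date),
                      stringsAsFactors = FALSE)[keep_b, , drop = FALSE]
  # window-edge censoring: first/last interval of the observed window
  if (nrow(bouts)) {
    if (as.numeric(bouts$start[1]) == as.numeric(ts[1]))
      bouts$censored_start[1] <- TRUE
    if (as.numeric(bouts$end[nrow(bouts)]) == as.numeric(ts[n]))
      bouts$censored_end[nrow(bouts)] <- TRUE
  }
  rownames(trips) <- rownames(bouts) <- NULL
  list(trips = trips, bouts = bouts)
}

.empty_intervals <- function() {
  data.frame(individual_id = character(), pair_id = character(),
             sex = character(), colony_id = character(), type = character(),
             start = as.POSIXct(character(), tz = "UTC"),
             end = as.POSIXct(character(), tz = "UTC"),
             duration_h = numeric(), distance_km = numeric(),
             n_fixes = integer(), censored_start = logical(),
             censored_end = logical(), age_start = numeric(),
             stringsAsFactors = FALSE)
}

#' Segment all individuals in a fix table
#'
#' @param fixes Fix `data.frame` (possibly many individuals).
#' @param colony A `colony_geometry`.
#' @param broods `data.frame` with columns `pair_id, hatch_date, end_date`
#'   (one row per pair), e.g. built by rbinding [brood_info()] rows.
#' @return List with combined `trips` and `bouts` data.frames.
#' @export
segment_all <- function(fixes, colony, broods) {
  ids <- unique(fixes$individual_id)
  out <- lapply(ids, function(id) {
    f <- fixes[fixes$individual_id == id, , drop = FALSE]
    b <- broods[broods$pair_id == f$pair_id[1], , drop = FALSE]
    if (nrow(b) != 1)
      stop("no brood metadata for pair ", f$pair_id[1])
    segment_track(f, colony, b)
  })
  list(trips = do.call(rbind, c(lapply(out, `[[`, "trips"),
                                list(make.row.names = FALSE))),
       bouts = do.call(rbind, c(lapply(out, `[[`, "bouts"),
                                list(make.row.names = FALSE))))
}

#' Exclude short / near-colony trips
#'
#' Removes trips below a duration or distance threshold. The defaults (30 min,
#' 1 km) discard returns and loitering near the colony that are unlikely to be
#' foraging trips. With `combine = "either"` (default, the stricter reading) a
#' trip is excluded when it fails either criterion; with `"both"` only when it
#' fails both.
#'
#' @param trips Trip `data.frame` from [segment_track()].
#' @param min_duration_h,min_distance_km Exclusion thresholds.
#' @param combine `"either"` or `"both"`.
#' @return Filtered trips.
#' @export
filter_trips <- function(trips, min_duration_h = 0.5, min_distance_km = 1,
                         combine = c("either", "both")) {
  combine <- match.arg(combine)
  if (!nrow(trips)) return(trips)
  short <- trips$duration_h < min_duration_h
  near <- trips$distance_km < min_distance_km
  drop <- if (combine == "either") short | near else short & near
  out <- trips[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recompute trip metrics from its fixes
#'
#' Duration in hours from the interval endpoints and cumulative point-to-point
#' great-circle distance. Single-fix trips get distance 0 and are flagged
#' degenerate.
#'
#' @param trip_fixes Fix `data.frame` of one trip, time-sorted.
#' @return A list with `duration_h`, `distance_km`, `degenerate`.
#' @export
trip_metrics <- function(trip_fixes) {
  n <- nrow(trip_fixes)
  list(duration_h = if (n >= 2)
         as.numeric(difftime(trip_fixes$timestamp[n], trip_fixes$timestamp[1],
                             units = "hours")) else 0,
       distance_km = track_distance_km(trip_fixes$lat, trip_fixes$lon),
       degenerate = n < 2)
}

#' Write / read interval tables
#'
#' Trips and bouts are serialised as delimited text with ISO-8601 timestamps
#' and full-precision numerics, and re-read bit-exactly for text fields.
#'
#' @param intervals Trip or bout `data.frame`.
#' @param path File path.
#' @export
write_intervals <- function(intervals, path) {
  d <- intervals
  d$start <- format(d$start, "%Y-%m-%dT%H:%M:%OS6", tz = "UTC")
  d$end <- format(d$end, "%Y-%m-%dT%H:%M:%OS6", tz = "UTC")
  for (col in c("duration_h", "distance_km", "age_start"))
    if (is.numeric(d[[col]])) d[[col]] <- formatC(d[[col]], format = "g", digits = 17)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$start <- as.POSIXct(d$start, tz = "UTC",
                        tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  d$end <- as.POSIXct(d$end, tz = "UTC",
                      tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  d
}
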