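#' Build the merged two-individual timeline of a pair
#'
#' Combines the segmented trips and bouts of the two members of a pair into a
#' `pair_schedule`: per-individual alternating interval lists on a common
#' observation window (the overlap of the two individuals' observed windows),
#' expressed in hours from the window start. All coordination statistics and
#' the randomisation null operate on this object.
#'
#' @param trips,bouts Interval `data.frame`s from [segment_all()] (or the
#'   simulator's truth tables), restricted to one pair. May also be passed as
#'   a single combined `data.frame` via `trips` with `bouts = NULL`.
#' @return An object of class `pair_schedule`: a list with `pair_id`,
#'   `colony_id`, `W` (window length, hours) and `ind`, a list of two
#'   per-individual schedules (`individual_id`, `sex`, `dur`, `is_trip`,
#'   `censored`).
#' @export
pair_schedule <- function(trips, bouts = NULL) {
  iv <- if (is.null(bouts)) trips else rbind(trips, bouts)
  stopifnot(nrow(iv) > 0)
  ids <- unique(iv$individual_id)
  if (length(ids) != 2)
    stop("pair_schedule needs intervals for exactly 2 individuals, got ",
         length(ids))
  if (length(unique(iv$pair_id)) != 1)
    stop("intervals span more than one pair")
  iv <- iv[order(iv$individual_id, iv$start), , drop = FALSE]
  t0 <- as.numeric(iv$start); t1 <- as.numeric(iv$end)
  win_a <- max(tapply(t0, iv$individual_id, min))
  win_b <- min(tapply(t1, iv$individual_id, max))
  if (win_b <= win_a) stop("the two individuals' observed windows do not overlap")
  W <- (win_b - win_a) / 3600

  ind <- lapply(ids, function(id) {
    k <- iv$individual_id == id
    s <- (t0[k] - win_a) / 3600
    e <- (t1[k] - win_a) / 3600
    cs <- if (!is.null(iv$censored_start)) iv$censored_start[k] else rep(FALSE, sum(k))
    ce <- if (!is.null(iv$censored_end)) iv$censored_end[k] else rep(FALSE, sum(k))
    keep <- e > 0 & s < W | (s == e & s >= 0 & s <= W)
    s <- s[keep]; e <- e[keep]; cs <- cs[keep]; ce <- ce[keep]
    clip_s <- s < 0; clip_e <- e > W
    s[clip_s] <- 0; e[clip_e] <- W
    ord <- order(s, e)
    s <- s[ord]; e <- e[ord]
    list(individual_id = id, sex = iv$sex[k][1],
         dur = e - s, is_trip = iv$type[k][ord] == "trip",
         censored = (cs | ce | clip_s | clip_e)[ord])
  })
  names(ind) <- ids
  structure(list(pair_id = iv$pair_id[1], colony_id = iv$colony_id[1],
                 W = W, ind = ind),
            class = "pair_schedule")
}

#' @export
print.pair_schedule <- function(x, ...) {
  cat(sprintf("<pair_schedule %s: window %.1f h>\n", x$pair_id, x$W))
  for (s in x$ind)
    cat(sprintf("  %s (%s): %d trips, %d bouts\n", s$individual_id, s$sex,
                sum(s$is_trip), sum(!s$is_trip)))
  invisible(x)
}

# interval starts implied by the alternating duration vector
.sched_starts <- function(s) cumsum(c(0, s$dur[-length(s$dur)]))

# Is the individual inside the colony at instant(s) t? In-colony intervals
# (bouts) are closed on the left and open on the right: an individual that
# returns at exactly t counts as present, one that departs at exactly t does
# not.
.in_colony_at <- function(s, t) {
  starts <- .sched_starts(s)
  ends <- starts + s$dur
  idx <- findInterval(t, starts)
  ok <- idx >= 1
  res <- logical(length(t))
  i <- idx[ok]
  res[ok] <- !s$is_trip[i] & t[ok] < ends[i]
  # a zero-length bout can shadow the interval that actually contains t;
  # findInterval returns the last start <= t, which is then the next interval,
  # so no correction is needed
  res
}

# Departure instants eligible for the presence-at-departure statistic:
# trip starts strictly inside the window, excluding segment-censored trips
# when `use_flags` (the observed schedule); randomised rebuilds use position
# only.
.departures <- function(s, use_flags = TRUE) {
  starts <- .sched_starts(s)
  k <- s$is_trip & starts > 0 & starts < sum(s$dur)
  if (use_flags) k <- k & !s$censored
  starts[k]
}

#' Proportion of departures with the partner present
#'
#' For each eligible departure of the focal individual (a non-censored trip
#' start strictly inside the window) checks whether the partner's schedule
#' places it inside the colony at that instant. The partner's in-colony
#' intervals are closed on the left: a partner returning at exactly the
#' departure instant counts as present, simultaneous departures do not.
#'
#' @param focal,partner Per-individual schedules (elements of
#'   `pair_schedule$ind`).
#' @param use_flags Honour segment-censoring flags when selecting departures.
#' @return List with `prop` (NA if no eligible trips, flagged via `n = 0`)
#'   and `n`, the number of eligible departures.
#' @export
partner_present_at_departure <- function(focal, partner, use_flags = TRUE) {
  t <- .departures(focal, use_flags)
  if (!length(t)) return(list(prop = NA_real_, n = 0L))
  list(prop = mean(.in_colony_at(partner, t)), n = length(t))
}

#' Nest attendance of a pair
#'
#' Fraction of the common observation window during which at least one pair
#' member is inside the colony: the measure of the union of both individuals'
#' in-colony intervals divided by the window length.
#'
#' @param ps A `pair_schedule`.
#' @return A proportion in `[0, 1]`.
#' @export
nest_attendance <- function(ps) {
  if (ps$W <= 0) stop("empty observation window")
  segs <- lapply(ps$ind, function(s) {
    starts <- .sched_starts(s)
    k <- !s$is_trip & s$dur > 0
    cbind(starts[k], starts[k] + s$dur[k])
  })
  m <- do.call(rbind, segs)
  if (is.null(m) || nrow(m) == 0) return(0)
  .interval_union_length(m) / ps$W
}

# total length of the union of intervals given as a 2-column matrix
.interval_union_length <- function(m) {
  m <- m[order(m[, 1]), , drop = FALSE]
  tot <- 0; cur_s <- m[1, 1]; cur_e <- m[1, 2]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] > cur_e) {
      tot <- tot + (cur_e - cur_s)
      cur_s <- m[i, 1]; cur_e <- m[i, 2]
    } else cur_e <- max(cur_e, m[i, 2])
  }
  tot + (cur_e - cur_s)
}

#' All four coordination statistics of a pair
#'
#' `male`: proportion of the male's departures with the female in the colony;
#' `female`: the reverse; `partner`: both sexes pooled (total departures with
#' the partner present over total departures); `attendance`: fraction of the
#' window with at least one parent in the colony.
#'
#' @param ps A `pair_schedule`.
#' @param use_flags Honour censoring flags (observed schedules) or use
#'   position-only eligibility (randomised rebuilds).
#' @return Named numeric vector `c(male, female, partner, attendance)` with an
#'   attribute `n` giving the per-statistic departure counts.
#' @export
coordination_stats <- function(ps, use_flags = TRUE) {
  sx <- vapply(ps$ind, function(s) tolower(as.character(s$sex)), character(1))
  i_m <- match("male", sx); i_f <- match("female", sx)
  if (is.na(i_m) || is.na(i_f)) { i_m <- 1L; i_f <- 2L }
  a <- ps$ind[[i_m]]; b <- ps$ind[[i_f]]
  pm <- partner_present_at_departure(a, b, use_flags)
  pf <- partner_present_at_departure(b, a, use_flags)
  pooled_n <- pm$n + pf$n
  pooled <- if (pooled_n > 0)
    (ifelse(pm$n > 0, pm$prop * pm$n, 0) + ifelse(pf$n > 0, pf$prop * pf$n, 0)) / pooled_n
  else NA_real_
  out <- c(male = pm$prop, female = pf$prop, partner = pooled,
           attendance = nest_attendance(ps))
  attr(out, "n") <- c(male = pm$n, female = pf$n, partner = pooled_n)
  out
}

#' Randomise one individual's schedule
#'
#' The randomisation null for uncoordinated care: trip durations and bout
#' durations are independently permuted as two multisets, the alternation
#' order and the starting state are preserved, and the timeline is rebuilt
#' from the window start. Because trips and bouts tile the window, the rebuilt
#' timeline spans exactly the same window, so clipping never truncates
#' anything; per-individual total trip time and total bout time are preserved
#' exactly. Between-mate timing dependence is destroyed while each
#' individual's marginal behaviour is retained.
#'
#' @param s A per-individual schedule (element of `pair_schedule$ind`).
#' @return A schedule of the same shape with permuted durations.
#' @export
randomise_schedule <- function(s) {
  ti <- which(s$is_trip); bi <- which(!s$is_trip)
  dur <- s$dur
  cen <- s$censored
  pt <- sample.int(length(ti)); pb <- sample.int(length(bi))
  dur[ti] <- s$dur[ti][pt]; dur[bi] <- s$dur[bi][pb]
  cen[ti] <- s$censored[ti][pt]; cen[bi] <- s$censored[bi][pb]
  list(individual_id = s$individual_id, sex = s$sex,
       dur = dur, is_trip = s$is_trip, censored = cen)
}
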