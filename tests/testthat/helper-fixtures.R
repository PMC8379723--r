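# Builders for hand-specified schedules and fix tables, plus deliberately
# naive oracle implementations of the coordination statistics and their
# exhaustive nulls. The oracles share no code with the package's fast paths.

t_origin <- as.POSIXct("2016-06-01", tz = "UTC")

# interval data.frame for one individual from alternating durations (hours)
mk_intervals <- function(individual_id, sex, types, durs,
                         pair_id = "P1", colony_id = "C1",
                         origin = t_origin) {
  stopifnot(length(types) == length(durs))
  s <- cumsum(c(0, durs[-length(durs)]))
  e <- s + durs
  data.frame(individual_id = individual_id, pair_id = pair_id, sex = sex,
             colony_id = colony_id, type = types,
             start = origin + s * 3600, end = origin + e * 3600,
             duration_h = durs, distance_km = ifelse(types == "trip", 10, NA),
             n_fixes = NA_integer_, censored_start = FALSE,
             censored_end = FALSE, age_start = floor(s / 24),
             stringsAsFactors = FALSE)
}

mk_pair <- function(types_a, durs_a, types_b, durs_b,
                    sex_a = "male", sex_b = "female") {
  pair_schedule(rbind(mk_intervals("A", sex_a, types_a, durs_a),
                      mk_intervals("B", sex_b, types_b, durs_b)))
}

# fix table at given minutes/distances north of a colony centre
mk_fixes <- function(minutes, dist_m, individual_id = "X1", pair_id = "XP1",
                     sex = "male", colony_id = "C1",
                     clat = 51.45, clon = 3.69) {
  ll <- t(vapply(dist_m, function(d) {
    if (d == 0) return(c(clat, clon))
    p <- geosphere::destPoint(cbind(clon, clat), 0, d, a = 6371008.8, f = 0)
    c(p[1, 2], p[1, 1])
  }, numeric(2)))
  data.frame(individual_id = individual_id, pair_id = pair_id, sex = sex,
             colony_id = colony_id,
             timestamp = t_origin + minutes * 60,
             lat = ll[, 1], lon = ll[, 2],
             ground_speed = NA, acc_class = NA, habitat = NA,
             true_behaviour = NA, stringsAsFactors = FALSE)
}

# ---- independent oracles ---------------------------------------------------

# naive presence check: loop over the partner's bout rows
oracle_presence <- function(focal_iv, partner_iv, window) {
  dep <- focal_iv$s[focal_iv$type == "trip"]
  dep <- dep[dep > 0 & dep < window]
  if (!length(dep)) return(NA_real_)
  present <- vapply(dep, function(t) {
    any(partner_iv$type == "bout" & partner_iv$s <= t & t < partner_iv$e)
  }, logical(1))
  mean(present)
}

# naive attendance: 1-second grid union
oracle_attendance <- function(iv_a, iv_b, window, grid = 1 / 3600) {
  t <- seq(0, window - grid, by = grid) + grid / 2
  in_a <- vapply(t, function(x)
    any(iv_a$type == "bout" & iv_a$s <= x & x < iv_a$e), logical(1))
  in_b <- vapply(t, function(x)
    any(iv_b$type == "bout" & iv_b$s <= x & x < iv_b$e), logical(1))
  mean(in_a | in_b)
}

# alternating interval list (s, e, type) from durations
oracle_iv <- function(types, durs) {
  s <- cumsum(c(0, durs[-length(durs)]))
  data.frame(s = s, e = s + durs, type = types, stringsAsFactors = FALSE)
}

perms_of <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- perms_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# exhaustive null of the pooled partner statistic and the per-sex statistics:
# enumerates every joint rearrangement of trip and bout duration multisets,
# computing statistics with the naive oracles above
oracle_exhaustive <- function(types_a, durs_a, types_b, durs_b) {
  window <- sum(durs_a)
  rearr <- function(types, durs) {
    ti <- which(types == "trip"); bi <- which(types == "bout")
    pt <- perms_of(length(ti)); pb <- perms_of(length(bi))
    out <- list()
    for (i in seq_len(nrow(pt))) for (j in seq_len(nrow(pb))) {
      d <- durs
      d[ti] <- durs[ti][pt[i, ]]
      d[bi] <- durs[bi][pb[j, ]]
      out[[length(out) + 1]] <- d
    }
    out
  }
  ra <- rearr(types_a, durs_a); rb <- rearr(types_b, durs_b)
  stats <- matrix(NA_real_, length(ra) * length(rb), 3)
  k <- 0
  for (da in ra) for (db in rb) {
    iva <- oracle_iv(types_a, da); ivb <- oracle_iv(types_b, db)
    pa <- oracle_presence(iva, ivb, window)
    pb_ <- oracle_presence(ivb, iva, window)
    na_ <- sum(iva$type == "trip" & iva$s > 0 & iva$s < window)
    nb_ <- sum(ivb$type == "trip" & ivb$s > 0 & ivb$s < window)
    pooled <- (ifelse(is.na(pa), 0, pa * na_) + ifelse(is.na(pb_), 0, pb_ * nb_)) /
      (na_ + nb_)
    k <- k + 1
    stats[k, ] <- c(pa, pb_, pooled)
  }
  colnames(stats) <- c("male", "female", "partner")
  stats
}

toy_fixes_path <- function() {
  system.file("extdata", "toy_fixes.csv", package = "pairforage",
              mustWork = TRUE)
}

toy_colony <- function() colony_circle(51.45, 3.69, 500)
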