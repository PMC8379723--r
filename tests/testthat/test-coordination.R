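test_that("partner presence at departure follows the hand trace and the boundary convention", {
  # partner never leaves: all departures with partner present
  ps <- mk_pair(c("bout", "trip", "bout", "trip", "bout"), c(2, 3, 2, 2, 1),
                c("bout"), c(10))
  s <- coordination_stats(ps)
  expect_equal(unname(s["male"]), 1)

  # focal departs at t=5 and t=7; partner in colony over [4,6) and [8,10)
  ps2 <- mk_pair(c("bout", "trip", "bout", "trip", "bout"),
                 c(5, 1.5, 0.5, 2, 1),
                 c("trip", "bout", "trip", "bout"), c(4, 2, 2, 2))
  s2 <- coordination_stats(ps2)
  expect_equal(unname(s2["male"]), 0.5)

  # partner returns exactly at the focal departure instant: counted present
  ps3 <- mk_pair(c("bout", "trip", "bout"), c(4, 3, 3),
                 c("trip", "bout"), c(4, 6))
  expect_equal(unname(coordination_stats(ps3)["male"]), 1)

  # simultaneous departures: not counted present
  ps4 <- mk_pair(c("bout", "trip", "bout"), c(4, 3, 3),
                 c("bout", "trip", "bout"), c(4, 3, 3))
  expect_equal(unname(coordination_stats(ps4)["male"]), 0)
})

test_that("nest attendance is the union of in-colony intervals over the window", {
  # A in colony [0,6), B in [4,10): full coverage
  ps <- mk_pair(c("bout", "trip"), c(6, 4), c("trip", "bout"), c(4, 6))
  expect_equal(nest_attendance(ps), 1.0)
  # A in [0,4), B in [6,10): 0.8
  ps2 <- mk_pair(c("bout", "trip"), c(4, 6), c("trip", "bout"), c(6, 4))
  expect_equal(nest_attendance(ps2), 0.8)
  # union monotonicity: attendance >= each individual's own in-colony fraction
  set.seed(21)
  for (k in 1:20) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    da <- rgamma(2 * na, 2, 1); db <- rgamma(2 * nb, 2, 1)
    da <- da / sum(da) * 20; db <- db / sum(db) * 20
    ps3 <- mk_pair(rep(c("bout", "trip"), na), da,
                   rep(c("trip", "bout"), nb), db)
    att <- nest_attendance(ps3)
    f_a <- sum(da[seq(1, 2 * na, 2)]) / 20
    f_b <- sum(db[seq(2, 2 * nb, 2)]) / 20
    expect_gte(att + 1e-12, max(f_a, f_b))
  }
})

test_that("attendance and presence agree with the naive grid/loop oracles on random schedules", {
  set.seed(31)
  for (k in 1:10) {
    na <- sample(2:4, 1); nb <- sample(2:4, 1)
    da <- round(rgamma(2 * na + 1, 2, 1), 2) + 0.05
    db <- round(rgamma(2 * nb + 1, 2, 1), 2) + 0.05
    da <- da / sum(da) * 12; db <- db / sum(db) * 12
    ta <- rep(c("bout", "trip"), length.out = 2 * na + 1)
    tb <- rep(c("trip", "bout"), length.out = 2 * nb + 1)
    ps <- mk_pair(ta, da, tb, db)
    s <- coordination_stats(ps)
    iva <- oracle_iv(ta, da); ivb <- oracle_iv(tb, db)
    expect_equal(unname(s["male"]), oracle_presence(iva, ivb, 12))
    expect_equal(unname(s["female"]), oracle_presence(ivb, iva, 12))
    expect_equal(unname(s["attendance"]),
                 oracle_attendance(iva, ivb, 12), tolerance = 2e-3)
  }
})

test_that("schedule randomisation preserves duration multisets, alternation and totals", {
  ps <- mk_pair(c("bout", "trip", "bout", "trip", "bout", "trip"),
                c(1, 4, 2, 5, 3, 6),
                c("bout", "trip"), c(10, 11))
  s <- ps$ind[[1]]
  set.seed(5)
  for (k in 1:25) {
    r <- randomise_schedule(s)
    expect_identical(r$is_trip, s$is_trip)
    expect_equal(sort(r$dur[r$is_trip]), sort(s$dur[s$is_trip]))
    expect_equal(sort(r$dur[!r$is_trip]), sort(s$dur[!s$is_trip]))
    expect_equal(sum(r$dur[r$is_trip]), sum(s$dur[s$is_trip]))
    expect_equal(sum(r$dur), sum(s$dur))
  }
  # single trip + single bout: only one arrangement
  s1 <- mk_pair(c("bout", "trip"), c(2, 3), c("bout"), c(5))$ind[[1]]
  set.seed(6)
  r1 <- randomise_schedule(s1)
  expect_equal(r1$dur, s1$dur)
})

test_that("randomisation samples the 36 arrangements of a 3-trip/3-bout schedule uniformly", {
  s <- mk_pair(c("bout", "trip", "bout", "trip", "bout", "trip"),
               c(1, 4, 2, 5, 3, 6),
               c("bout", "trip"), c(10, 11))$ind[[1]]
  set.seed(99)
  n_draw <- 7200
  key <- character(n_draw)
  for (k in seq_len(n_draw))
    key[k] <- paste(randomise_schedule(s)$dur, collapse = ",")
  tab <- table(key)
  expect_equal(length(tab), 36)
  chi <- sum((tab - n_draw / 36)^2 / (n_draw / 36))
  expect_lt(chi, qchisq(0.999, df = 35))
})

test_that("the exact enumeration path reproduces the brute-force exhaustive null", {
  types_a <- c("bout", "trip", "bout", "trip", "bout")
  durs_a <- c(2, 3, 1, 4, 2)
  types_b <- c("bout", "trip", "bout", "trip", "bout")
  durs_b <- c(1, 5, 2, 3, 1)
  ps <- mk_pair(types_a, durs_a, types_b, durs_b)
  rt <- randomisation_test(ps)
  expect_equal(rt$method, "exact")
  # each bird: 2 trips, 3 bouts -> 2! * 3! = 12 arrangements; joint 144
  expect_equal(rt$n_replicates, 144)

  oracle <- oracle_exhaustive(types_a, durs_a, types_b, durs_b)
  obs <- coordination_stats(ps)
  for (stat in c("male", "female", "partner")) {
    p_oracle <- mean(oracle[, stat] >= obs[stat] - 1e-12)
    expect_equal(unname(rt$p[stat]), p_oracle, tolerance = 1e-12,
                 label = paste("exact p for", stat))
    expect_equal(unname(rt$expected[stat]), mean(oracle[, stat]),
                 tolerance = 1e-9)
  }
  expect_equal(unname(rt$difference), unname(rt$observed - rt$expected),
               tolerance = 1e-12)
})

test_that("sampled and exact p-values agree on small schedules", {
  types <- c("bout", "trip", "bout", "trip", "bout")
  set.seed(13)
  for (k in 1:3) {
    da <- round(rgamma(5, 2, 0.5), 2) + 0.1
    db <- round(rgamma(5, 2, 0.5), 2) + 0.1
    # common window so neither bird loses intervals to clipping
    da <- da / sum(da) * 15
    db <- db / sum(db) * 15
    ps <- mk_pair(types, da, types, db)
    rt_ex <- randomisation_test(ps, exact = "always")
    rt_mc <- randomisation_test(ps, n_rep = 1999, exact = "never")
    for (stat in c("male", "female", "partner", "attendance"))
      expect_lt(abs(rt_mc$p[stat] - rt_ex$p[stat]), 0.05,
                label = paste("MC vs exact p,", stat, "rep", k))
  }
})

test_that("degenerate schedules are flagged untestable, not errored", {
  ps <- mk_pair(c("bout", "trip", "bout"), c(2, 3, 5),
                c("bout", "trip", "bout"), c(4, 2, 4))
  r <- randomisation_test(ps)
  expect_true(r$untestable)
  expect_true(all(is.na(r$p)))
})

test_that("population summary reproduces the bundled reference table's averages and counts", {
  d <- example_pair_table()
  expect_equal(nrow(d), 25)
  s <- summarise_population(d)
  expect_lt(abs(s$mean_observed[s$statistic == "male"] - 0.815), 5e-4)
  expect_lt(abs(s$mean_observed[s$statistic == "female"] - 0.835), 5e-4)
  expect_lt(abs(s$mean_observed[s$statistic == "attendance"] - 0.9304), 5e-5)
  expect_equal(s$n_significant[s$statistic == "male"], 22)
  expect_equal(s$n_significant[s$statistic == "female"], 23)
  # all pairs identical: mean equals the common value
  same <- d[rep(3, 10), ]
  s2 <- summarise_population(same)
  expect_equal(s2$mean_observed[s2$statistic == "male"], d$obs_male[3])
})

test_that("daily attendance and the beta age model behave on a null (no-trend) pair set", {
  set.seed(17)
  cfg <- sim_config(days = 12, n_pairs = 8, beta_age = 0, coordination_w = 0)
  sim <- simulate_colony(cfg, seed = 23, fixes = FALSE)
  scheds <- truth_schedules(sim$truth)
  da <- daily_attendance(scheds[[1]])
  expect_equal(nrow(da), 12)
  expect_true(all(da$attendance >= 0 & da$attendance <= 1))
  fit <- suppressMessages(attendance_vs_age(scheds))
  slope <- fit$coefficients[fit$coefficients$term == "day", ]
  expect_true(abs(slope$estimate) < 2.5 * slope$std_error + 0.02)
})
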