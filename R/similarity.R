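#' Multiple Response Permutation Procedure (MRPP)
#'
#' Tests whether observations are more similar within groups (here: within
#' breeding pairs) than between them. The statistic is
#' `delta = sum_g w_g * mean pairwise dissimilarity within group g`, with the
#' common weights `w_g = n_g / N` (weights `(n_g - 1) / (N - G)` style
#' alternatives via `weight`). The null distribution is obtained by randomly
#' reassigning observations to groups of the original sizes; the test is
#' one-tailed low (a smaller delta than expected means within-group
#' similarity), with the add-one p-value `(1 + #{permuted <= observed}) /
#' (n_perm + 1)`. This is a from-scratch implementation; it is cross-checked
#' against an independent one in the package tests.
#'
#' @param x Numeric vector or matrix of observations (rows).
#' @param group Group labels, one per observation.
#' @param n_perm Number of permutations (default 999).
#' @param weight `"size"` (`n_g/N`) or `"size_minus_1"` (`n_g - 1`
#'   normalised).
#' @param min_group_size Groups with fewer observations are excluded with a
#'   warning.
#' @param exact `"auto"` (default), `"never"` or `"always"`: with few
#'   observations (`factorial(N) <= exact_cap`) the null is enumerated over
#'   all label permutations and the p-value is the exact fraction
#'   `#{delta <= observed} / N!`, instead of Monte-Carlo sampling.
#' @param exact_cap Enumeration threshold on `factorial(N)`.
#' @return An object of class `mrpp_result`: `observed_delta`,
#'   `expected_delta` (mean of permuted deltas), `within_mean` and
#'   `between_mean` dissimilarities, `p`, `n_perm`, group sizes.
#' @export
mrpp <- function(x, group, n_perm = 999,
                 weight = c("size", "size_minus_1"),
                 min_group_size = 2,
                 exact = c("auto", "never", "always"), exact_cap = 5040) {
  weight <- match.arg(weight)
  exact <- match.arg(exact)
  x <- as.matrix(x)
  group <- as.character(group)
  stopifnot(nrow(x) == length(group))
  sizes <- table(group)
  small <- names(sizes)[sizes < min_group_size]
  if (length(small)) {
    warning("excluding group(s) with < ", min_group_size, " observations: ",
            paste(small, collapse = ", "))
    keep <- !(group %in% small)
    x <- x[keep, , drop = FALSE]; group <- group[keep]
    sizes <- table(group)
  }
  if (length(sizes) < 2) stop("MRPP needs at least 2 groups")
  dm <- as.matrix(stats::dist(x))
  g <- factor(group)

  delta_of <- function(gf) {
    idx <- split(seq_along(gf), gf)
    ns <- lengths(idx)
    w <- switch(weight,
                size = ns / sum(ns),
                size_minus_1 = (ns - 1) / sum(ns - 1))
    d_g <- vapply(idx, function(ii) {
      sub <- dm[ii, ii]
      sum(sub[upper.tri(sub)]) / (length(ii) * (length(ii) - 1) / 2)
    }, numeric(1))
    sum(w * d_g)
  }

  observed <- delta_of(g)
  n <- length(g)
  do_exact <- exact == "always" ||
    (exact == "auto" && factorial(n) <= exact_cap)
  if (do_exact) {
    pm <- .permutations(n)
    perm <- vapply(seq_len(nrow(pm)), function(r) delta_of(g[pm[r, ]]),
                   numeric(1))
    p <- mean(perm <= observed + 1e-12)
    method <- "exact"
    n_eff <- nrow(pm)
  } else {
    perm <- vapply(seq_len(n_perm), function(r) delta_of(sample(g)), numeric(1))
    p <- (1 + sum(perm <= observed + 1e-12)) / (n_perm + 1)
    method <- "sampled"
    n_eff <- n_perm
  }
  same <- outer(group, group, `==`)
  ut <- upper.tri(dm)
  within_mean <- mean(dm[ut & same])
  between_mean <- mean(dm[ut & !same])
  structure(list(observed_delta = observed,
                 expected_delta = mean(perm),
                 within_mean = within_mean, between_mean = between_mean,
                 p = p, method = method,
                 n_perm = n_eff, group_sizes = as.integer(sizes),
                 groups = names(sizes), permuted = perm),
            class = "mrpp_result")
}

#' @export
print.mrpp_result <- function(x, ...) {
  cat(sprintf(paste0("<mrpp: observed delta %.4f, expected %.4f, ",
                     "within %.4f, between %.4f, p = %.4g (%d perms)>\n"),
              x$observed_delta, x$expected_delta, x$within_mean,
              x$between_mean, x$p, x$n_perm))
  invisible(x)
}

#' Per-trip investment parameters for similarity analysis
#'
#' Builds the five investment parameters per trip: total distance (km), trip
#' duration (h), and the hours spent resting, flying (commuting) and foraging
#' outside the colony, obtained by counting fixes of each (predicted or true)
#' behaviour class within the trip and multiplying by the fix interval. Trips
#' without behaviour annotations keep distance/duration with `NA` behaviour
#' hours.
#'
#' @param trips Trip `data.frame` (filtered).
#' @param fixes Fix `data.frame` with a `pred_behaviour` (or
#'   `true_behaviour`) column.
#' @param fix_interval Fix interval in seconds.
#' @param behaviour_col Column holding the class labels.
#' @return `data.frame` with ids and columns `distance_km, duration_h,
#'   resting_h, flying_h, foraging_h`.
#' @export
build_investment_table <- function(trips, fixes = NULL, fix_interval = 180,
                                   behaviour_col = c("pred_behaviour",
                                                     "true_behaviour")) {
  if (!nrow(trips))
    return(data.frame(pair_id = character(), individual_id = character(),
                      colony_id = character(), sex = character(),
                      distance_km = numeric(), duration_h = numeric(),
                      resting_h = numeric(), flying_h = numeric(),
                      foraging_h = numeric(), stringsAsFactors = FALSE))
  out <- trips[, c("pair_id", "individual_id", "colony_id", "sex",
                   "distance_km", "duration_h")]
  out$resting_h <- out$flying_h <- out$foraging_h <- NA_real_
  if (!is.null(fixes)) {
    behaviour_col <- intersect(behaviour_col, names(fixes))[1]
    if (is.na(behaviour_col)) stop("fixes carry no behaviour column")
    per_h <- fix_interval / 3600
    for (i in seq_len(nrow(trips))) {
      f <- fixes[fixes$individual_id == trips$individual_id[i] &
                   fixes$timestamp >= trips$start[i] &
                   fixes$timestamp < trips$end[i], , drop = FALSE]
      cls <- as.character(f[[behaviour_col]])
      out$resting_h[i] <- sum(cls == "rest", na.rm = TRUE) * per_h
      out$flying_h[i] <- sum(cls == "commute", na.rm = TRUE) * per_h
      out$foraging_h[i] <- sum(cls == "forage", na.rm = TRUE) * per_h
    }
  }
  rownames(out) <- NULL
  out
}

#' Within-pair similarity of investment parameters, per colony
#'
#' Runs a univariate [mrpp()] for each investment parameter within each
#' colony, with breeding pairs as groups, and returns a tidy table
#' (parameter x colony: within- and between-pair mean dissimilarity,
#' observed and expected delta, p).
#'
#' @param investment Output of [build_investment_table()].
#' @param params Parameter columns to test.
#' @param n_perm Permutations per test.
#' @return `data.frame`, one row per parameter x colony.
#' @export
similarity_by_colony <- function(investment,
                                 params = c("distance_km", "duration_h",
                                            "resting_h", "flying_h",
                                            "foraging_h"),
                                 n_perm = 999) {
  out <- list()
  for (col in unique(investment$colony_id)) {
    d <- investment[investment$colony_id == col, , drop = FALSE]
    for (p in params) {
      v <- d[[p]]
      ok <- !is.na(v)
      if (sum(ok) < 4 || length(unique(d$pair_id[ok])) < 2) next
      r <- mrpp(v[ok], d$pair_id[ok], n_perm = n_perm)
      out[[length(out) + 1]] <- data.frame(
        colony_id = col, parameter = p,
        within = r$within_mean, between = r$between_mean,
        observed_delta = r$observed_delta, expected_delta = r$expected_delta,
        p = r$p, n_obs = sum(ok), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
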