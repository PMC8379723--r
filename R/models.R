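#' Mixed-model fits with a recorded fallback
#'
#' All regression stages go through this helper: it fits a generalized mixed
#' model (glmmTMB) with the requested random intercepts, dropping random
#' terms whose grouping factor has fewer than two levels, and falls back to a
#' fixed-effects GLM with cluster-robust standard errors (by `cluster`) when
#' the mixed fit fails to converge. The fallback is recorded in the returned
#' object, never silent.
#'
#' @param formula Fixed-effects formula.
#' @param data Model frame.
#' @param family A `family` or glmmTMB family object.
#' @param random Character vector of grouping variables for random
#'   intercepts.
#' @param cluster Grouping variable for the robust-error fallback.
#' @return A `model_fit` object: coefficient table (estimate, SE, statistic,
#'   p), formula, family, random terms used, convergence status and fallback
#'   flag.
#' @export
fit_mixed <- function(formula, data, family, random = character(),
                      cluster = NULL) {
  used <- random[vapply(random, function(v)
    length(unique(data[[v]])) > 1, logical(1))]
  dropped <- setdiff(random, used)
  if (length(dropped))
    message("dropping single-level random term(s): ",
            paste(dropped, collapse = ", "))
  fstr <- paste(deparse(formula), collapse = " ")

  # try the full random structure, then progressively simpler ones; a fit
  # only counts if the Hessian is positive definite and every SE is finite
  re_sets <- lapply(rev(seq_len(length(used) + 1)) - 1,
                    function(k) used[seq_len(k)])
  for (re in re_sets) {
    if (!length(re) && length(used)) break  # no-RE case goes to the fallback
    full <- if (length(re))
      stats::as.formula(paste(fstr, "+",
                              paste(sprintf("(1 | %s)", re), collapse = " + ")))
    else formula
    fit <- tryCatch(glmmTMB::glmmTMB(full, data = data, family = family),
                    error = function(e) e, warning = function(w) w)
    ok <- inherits(fit, "glmmTMB") &&
      isTRUE(fit$sdr$pdHess) && fit$fit$convergence == 0
    if (!ok) next
    sm <- summary(fit)$coefficients$cond
    if (!all(is.finite(sm[, 2]))) next
    if (length(re) < length(used))
      message("random structure simplified to: ",
              if (length(re)) paste(re, collapse = " + ") else "(none)")
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                        std_error = sm[, 2], statistic = sm[, 3],
                        p_value = sm[, 4], row.names = NULL,
                        stringsAsFactors = FALSE)
    return(structure(list(coefficients = coefs,
                          formula = paste(deparse(full), collapse = " "),
                          family = .family_label(family),
                          random = re, converged = TRUE, fallback = FALSE,
                          n = nrow(data), model = fit),
                     class = "model_fit"))
  }
  # fallback: fixed-effects GLM + cluster-robust (sandwich) errors
  glm_family <- if (inherits(family, "family")) family else {
    # beta responses have no base-R family; quasibinomial(logit) gives the
    # same mean structure for the fallback point estimates
    if (grepl("beta", family$family)) stats::quasibinomial("logit")
    else stats::Gamma("log")
  }
  g <- stats::glm(formula, data = data, family = glm_family)
  vc <- if (!is.null(cluster) &&
            requireNamespace("sandwich", quietly = TRUE)) {
    sandwich::vcovCL(g, cluster = data[[cluster]])
  } else stats::vcov(g)
  est <- stats::coef(g)
  se <- sqrt(diag(vc))
  z <- est / se
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      std_error = unname(se), statistic = unname(z),
                      p_value = unname(2 * stats::pnorm(-abs(z))),
                      stringsAsFactors = FALSE)
  reason <- "no mixed fit converged with finite standard errors"
  structure(list(coefficients = coefs, formula = fstr,
                 family = .family_label(glm_family), random = character(),
                 converged = TRUE, fallback = TRUE,
                 fallback_reason = reason, n = nrow(data), model = g),
            class = "model_fit")
}

.family_label <- function(family) {
  if (inherits(family, "family")) paste0(family$family, "(", family$link, ")")
  else paste0(family$family, "(", family$link, ")")
}

#' @export
print.model_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<model_fit: %s, family %s%s%s>\n", x$formula, x$family,
              if (length(x$random))
                paste0(", random: ", paste(x$random, collapse = " + "))
              else "",
              if (x$fallback) " [FALLBACK: cluster-robust GLM]" else ""))
  cf <- x$coefficients
  cf[, -1] <- round(cf[, -1], digits)
  print(cf, row.names = FALSE)
  invisible(x)
}

#' Pair focal trips with the partner's preceding trip
#'
#' For every filtered focal trip, finds the partner's most recent trip that
#' ended at or before the focal departure; focal trips with no preceding
#' partner trip are dropped. (A partner trip still in progress at the focal
#' departure is not "preceding"; set `rule = "started"` to accept any partner
#' trip that started before the focal departure instead.)
#'
#' @param trips Trip `data.frame` (both members of each pair).
#' @param rule `"ended"` (default) or `"started"`.
#' @return `data.frame` with one row per matched focal trip: `duration_h`,
#'   `partner_prev_h`, `sex`, ids and `age_start`.
#' @export
build_response_table <- function(trips, rule = c("ended", "started")) {
  rule <- match.arg(rule)
  trips <- trips[order(trips$pair_id, trips$individual_id, trips$start), ,
                 drop = FALSE]
  out <- lapply(split(trips, trips$pair_id), function(tp) {
    ids <- unique(tp$individual_id)
    if (length(ids) != 2) return(NULL)
    do.call(rbind, lapply(ids, function(id) {
      focal <- tp[tp$individual_id == id, , drop = FALSE]
      partner <- tp[tp$individual_id != id, , drop = FALSE]
      key <- if (rule == "ended") as.numeric(partner$end)
             else as.numeric(partner$start)
      ord <- order(key)
      partner <- partner[ord, , drop = FALSE]
      key <- key[ord]
      idx <- findInterval(as.numeric(focal$start), key)
      keep <- idx >= 1
      data.frame(pair_id = focal$pair_id[keep],
                 individual_id = focal$individual_id[keep],
                 colony_id = focal$colony_id[keep],
                 sex = focal$sex[keep],
                 age_start = focal$age_start[keep],
                 duration_h = focal$duration_h[keep],
                 partner_prev_h = partner$duration_h[idx[keep]],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Gamma mixed model of trip duration on the partner's preceding trip
#'
#' Fits `duration ~ partner_prev * sex` with a gamma distribution and log
#' link (durations are strictly positive) and random intercepts for bird and
#' colony. The full model is reported; no term selection.
#'
#' @param table Output of [build_response_table()].
#' @return A [model_fit].
#' @export
fit_trip_response <- function(table) {
  stopifnot(all(table$duration_h > 0), all(table$partner_prev_h > 0))
  fit_mixed(duration_h ~ partner_prev_h * sex, table,
            family = stats::Gamma(link = "log"),
            random = c("individual_id", "colony_id"),
            cluster = "pair_id")
}

#' Gamma mixed model of nest-bout duration on offspring age
#'
#' Fits `duration ~ age * sex` with gamma errors and log link on non-censored
#' bouts, with couple, bird and colony random intercepts. The offspring-age
#' slope (log scale, per day) is the quantity of interest.
#'
#' @param bouts Bout `data.frame` from [segment_all()] (censored and
#'   zero-length bouts are excluded here).
#' @return A [model_fit].
#' @export
fit_bout_age <- function(bouts) {
  d <- bouts[!bouts$censored_start & !bouts$censored_end &
               bouts$duration_h > 0, , drop = FALSE]
  if (!nrow(d)) stop("no uncensored positive-duration bouts")
  if (stats::var(d$age_start) == 0)
    stop("offspring age is constant; the age slope is not identifiable")
  fit_mixed(duration_h ~ age_start * sex, d,
            family = stats::Gamma(link = "log"),
            random = c("pair_id", "individual_id", "colony_id"),
            cluster = "pair_id")
}
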