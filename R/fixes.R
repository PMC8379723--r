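#' Read a GPS fix table
#'
#' Reads a delimited-text fix table with one row per GPS fix. Required columns
#' are `individual_id, pair_id, sex, colony_id, timestamp, lat, lon`;
#' `ground_speed`, `acc_class`, `habitat` and `true_behaviour` are optional
#' and are filled with `NA` when absent. Timestamps must be ISO-8601 and are
#' interpreted as UTC. Rows are returned sorted by individual and timestamp,
#' so shuffled input yields the same table as sorted input.
#'
#' @param path Path to the delimited file (header row required).
#' @param sep Field separator, comma by default.
#' @return A `data.frame` of fixes with `timestamp` as POSIXct (UTC).
#' @seealso [write_fixes()]
#' @export
read_fixes <- function(path, sep = ",") {
  stopifnot(file.exists(path))
  d <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  required <- c("individual_id", "pair_id", "sex", "colony_id",
                "timestamp", "lat", "lon")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop("fix table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  ts <- .parse_timestamp(d$timestamp)
  bad <- which(is.na(ts) & !is.na(d$timestamp) & nzchar(d$timestamp))
  if (length(bad))
    stop("unparsable timestamp at data line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  d$timestamp <- ts
  for (opt in c("ground_speed", "acc_class", "habitat", "true_behaviour"))
    if (is.null(d[[opt]])) d[[opt]] <- NA
  validate_fixes(d)
  d <- d[order(d$individual_id, d$timestamp), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' @rdname read_fixes
#' @param fixes A fix `data.frame` as returned by [read_fixes()] or
#'   [simulate_colony()].
#' @details `write_fixes()` writes coordinates with enough digits that
#'   `read_fixes(write_fixes(...))` reproduces them to better than 1e-9
#'   degrees; text fields round-trip exactly.
#' @export
write_fixes <- function(fixes, path, sep = ",") {
  d <- fixes
  d$timestamp <- format(d$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  for (col in c("lat", "lon"))
    d[[col]] <- formatC(d[[col]], format = "f", digits = 10)
  if (is.numeric(d$ground_speed))
    d$ground_speed <- formatC(d$ground_speed, format = "f", digits = 6)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# element-wise ISO-8601 parsing that yields NA (never an error) on bad input
.parse_timestamp <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d")) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = "UTC"))
  }
  out
}

#' Validate fix-table invariants
#'
#' Checks coordinate ranges, non-negative ground speed, and strictly
#' increasing timestamps within each individual. Called by [read_fixes()];
#' exported so assembled tables can be checked too.
#'
#' @param fixes A fix `data.frame`.
#' @return Invisibly, `fixes` (errors on violation).
#' @export
validate_fixes <- function(fixes) {
  stopifnot(is.data.frame(fixes))
  if (any(abs(fixes$lat) > 90, na.rm = TRUE) ||
      any(abs(fixes$lon) > 180, na.rm = TRUE))
    stop("coordinates out of range (|lat| <= 90, |lon| <= 180)")
  if (is.numeric(fixes$ground_speed) &&
      any(fixes$ground_speed < 0, na.rm = TRUE))
    stop("negative ground_speed")
  ord <- order(fixes$individual_id, fixes$timestamp)
  f <- fixes[ord, ]
  same <- f$individual_id[-1] == f$individual_id[-nrow(f)]
  if (nrow(f) > 1 &&
      any(same & diff(as.numeric(f$timestamp)) <= 0))
    stop("timestamps must be strictly increasing within an individual")
  invisible(fixes)
}

#' Brood metadata
#'
#' One record per pair: hatch date (offspring day 0) and the end of the
#' chick-rearing window (fledging at day 30, or the failure date). All
#' segmentation and modelling is clipped to this window, and offspring age is
#' `floor()` of the days elapsed since hatching.
#'
#' @param pair_id Pair identifier.
#' @param hatch_date,end_date POSIXct (UTC) or anything `as.POSIXct`
#'   understands; `end_date` defaults to 30 days after hatching.
#' @return A one-row `data.frame` of class `brood_info`.
#' @export
brood_info <- function(pair_id, hatch_date, end_date = NULL) {
  hatch_date <- as.POSIXct(hatch_date, tz = "UTC")
  end_date <- if (is.null(end_date)) hatch_date + 30 * 86400
              else as.POSIXct(end_date, tz = "UTC")
  stopifnot(end_date > hatch_date)
  structure(data.frame(pair_id = pair_id, hatch_date = hatch_date,
                       end_date = end_date, stringsAsFactors = FALSE),
            class = c("brood_info", "data.frame"))
}

#' Offspring age in days at given times
#'
#' Day 0 is the hatch day: `floor((time - hatch)/1 day)`.
#'
#' @param time POSIXct vector.
#' @param hatch_date POSIXct scalar.
#' @return Integer ages (days).
#' @export
offspring_age <- function(time, hatch_date) {
  floor(as.numeric(difftime(time, hatch_date, units = "days")))
}
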