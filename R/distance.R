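#' Great-circle distance between coordinates
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the IUGG mean Earth
#' radius). All track distances in the package (step lengths, cumulative trip
#' distance, colony membership for circular boundaries) use this function, so
#' a single Earth model applies throughout.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84).
#'   Vectors are recycled in the usual way.
#' @return Distance(s) in kilometres.
#' @examples
#' great_circle_km(51, 3, 51.009, 3)
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(lat1) <= 90, na.rm = TRUE), all(abs(lat2) <= 90, na.rm = TRUE),
            all(abs(lon1) <= 180, na.rm = TRUE), all(abs(lon2) <= 180, na.rm = TRUE))
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371.0088)
}

# Earth radius used everywhere, in metres (for geosphere calls that want one).
.earth_radius_m <- 6371008.8

# Spherical destination point: from (lat, lon) along initial bearing `brg`
# (degrees clockwise from north) for `dist_m` metres. Returns cbind(lat, lon).
dest_point <- function(lat, lon, brg, dist_m) {
  p <- geosphere::destPoint(cbind(lon, lat), brg, dist_m, a = .earth_radius_m, f = 0)
  cbind(lat = p[, 2], lon = p[, 1])
}

# Initial bearing from point 1 to point 2, degrees in [0, 360).
bearing_deg <- function(lat1, lon1, lat2, lon2) {
  b <- geosphere::bearing(cbind(lon1, lat1), cbind(lon2, lat2))
  (b + 360) %% 360
}

#' Cumulative point-to-point track distance
#'
#' Sum of great-circle distances over consecutive fixes.
#'
#' @param lat,lon Coordinate vectors, in track order.
#' @return Total distance in km; 0 for fewer than two fixes.
#' @export
track_distance_km <- function(lat, lon) {
  n <- length(lat)
  if (n < 2) return(0)
  sum(great_circle_km(lat[-n], lon[-n], lat[-1], lon[-1]))
}
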