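#' Colony boundary geometries
#'
#' A colony boundary is either a circle (centre plus radius in metres) or a
#' simple polygon of lat/lon vertices. Membership of a fix is decided by
#' great-circle distance to the centre (circle) or by point-in-polygon with
#' points on the boundary counted as inside. Field studies rarely publish an
#' explicit boundary; a 500 m radius around the colony centre is the default.
#'
#' @param lat,lon Centre coordinates (circle) or vertex coordinate vectors
#'   (polygon), decimal degrees.
#' @param radius_m Circle radius in metres; must be positive.
#' @return An object of class `colony_geometry`.
#' @examples
#' colony_circle(51.45, 3.69)
#' @export
colony_circle <- function(lat, lon, radius_m = 500) {
  stopifnot(length(lat) == 1, length(lon) == 1, is.finite(radius_m), radius_m > 0,
            abs(lat) <= 90, abs(lon) <= 180)
  structure(list(type = "circle", lat = lat, lon = lon, radius_m = radius_m),
            class = "colony_geometry")
}

#' @rdname colony_circle
#' @export
colony_polygon <- function(lat, lon) {
  stopifnot(length(lat) == length(lon), length(lat) >= 3,
            all(abs(lat) <= 90), all(abs(lon) <= 180))
  # drop an explicitly closed last vertex
  n <- length(lat)
  if (lat[1] == lat[n] && lon[1] == lon[n]) {
    lat <- lat[-n]; lon <- lon[-n]
  }
  if (.polygon_self_intersects(lat, lon))
    stop("colony polygon is self-intersecting")
  structure(list(type = "polygon", lat = lat, lon = lon),
            class = "colony_geometry")
}

#' @export
print.colony_geometry <- function(x, ...) {
  if (x$type == "circle")
    cat(sprintf("<colony: circle centre (%.4f, %.4f), radius %g m>\n",
                x$lat, x$lon, x$radius_m))
  else
    cat(sprintf("<colony: polygon, %d vertices>\n", length(x$lat)))
  invisible(x)
}

#' Test whether positions fall inside the colony boundary
#'
#' @param colony A [colony_circle()] or [colony_polygon()].
#' @param lat,lon Position vectors (decimal degrees).
#' @return Logical vector; boundary points count as inside.
#' @export
in_colony <- function(colony, lat, lon) {
  stopifnot(inherits(colony, "colony_geometry"))
  if (colony$type == "circle") {
    great_circle_km(lat, lon, colony$lat, colony$lon) <= colony$radius_m / 1000
  } else {
    vapply(seq_along(lat), function(i)
      .point_in_polygon(lat[i], lon[i], colony$lat, colony$lon), logical(1))
  }
}

#' Read a colony geometry from JSON / GeoJSON
#'
#' Circles are plain JSON objects `{"lat": ..., "lon": ..., "radius_m": ...}`;
#' polygons are GeoJSON `Polygon` geometries (outer ring only) or GeoJSON
#' Features wrapping one.
#'
#' @param path File path.
#' @return A `colony_geometry`.
#' @export
read_colony <- function(path) {
  stopifnot(file.exists(path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(j$radius_m)) {
    return(colony_circle(j$lat, j$lon, j$radius_m))
  }
  geom <- if (!is.null(j$geometry)) j$geometry else j
  if (is.null(geom$type) || !identical(geom$type, "Polygon"))
    stop("colony file is neither a circle object nor a GeoJSON Polygon")
  ring <- geom$coordinates
  if (is.list(ring)) ring <- ring[[1]]
  if (length(dim(ring)) == 3) ring <- ring[1, , ]
  colony_polygon(lat = ring[, 2], lon = ring[, 1])
}

#' @rdname read_colony
#' @param colony A `colony_geometry` to serialise.
#' @export
write_colony <- function(colony, path) {
  stopifnot(inherits(colony, "colony_geometry"))
  if (colony$type == "circle") {
    jsonlite::write_json(list(lat = colony$lat, lon = colony$lon,
                              radius_m = colony$radius_m),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    ring <- cbind(c(colony$lon, colony$lon[1]), c(colony$lat, colony$lat[1]))
    jsonlite::write_json(list(type = "Polygon", coordinates = list(ring)),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# Ray-casting point-in-polygon on lon/lat treated as planar (colony-scale
# polygons are far below the scale where sphericity matters). Boundary points
# (vertices and edges) count as inside.
.point_in_polygon <- function(plat, plon, vlat, vlon) {
  n <- length(vlat)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- vlon[i]; yi <- vlat[i]; xj <- vlon[j]; yj <- vlat[j]
    # on-vertex / on-edge check
    if ((plon == xi && plat == yi) ||
        (.on_segment(plon, plat, xi, yi, xj, yj))) return(TRUE)
    if ((yi > plat) != (yj > plat)) {
      xint <- xi + (plat - yi) * (xj - xi) / (yj - yi)
      if (plon < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

.on_segment <- function(px, py, x1, y1, x2, y2, eps = 1e-12) {
  cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
  if (abs(cross) > eps) return(FALSE)
  px >= min(x1, x2) - eps && px <= max(x1, x2) + eps &&
    py >= min(y1, y2) - eps && py <= max(y1, y2) + eps
}

.polygon_self_intersects <- function(vlat, vlon) {
  n <- length(vlat)
  seg <- cbind(vlon, vlat, vlon[c(2:n, 1)], vlat[c(2:n, 1)])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next  # adjacent edges share a vertex
      if (.segments_cross(seg[i, ], seg[j, ])) return(TRUE)
    }
  }
  FALSE
}

.segments_cross <- function(a, b) {
  d <- function(p1x, p1y, p2x, p2y, p3x, p3y)
    (p2x - p1x) * (p3y - p1y) - (p2y - p1y) * (p3x - p1x)
  d1 <- d(a[1], a[2], a[3], a[4], b[1], b[2])
  d2 <- d(a[1], a[2], a[3], a[4], b[3], b[4])
  d3 <- d(b[1], b[2], b[3], b[4], a[1], a[2])
  d4 <- d(b[1], b[2], b[3], b[4], a[3], a[4])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}
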