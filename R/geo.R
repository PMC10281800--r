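# Great-circle geometry on WGS84 lon/lat, treated spherically with
# R = 6371.0088 km (IUGG mean radius). All angles in decimal degrees.

EARTH_RADIUS_KM <- 6371.0088

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Haversine great-circle distance
#'
#' Distance in kilometres between two points (or two equal-length vectors of
#' points) given as WGS84 decimal degrees, on a sphere of radius 6371.0088 km.
#'
#' @param lat1,lon1 Coordinates of the first point(s), degrees.
#' @param lat2,lon2 Coordinates of the second point(s), degrees.
#' @return Numeric vector of distances in km. Symmetric, non-negative, and
#'   exactly zero for identical points.
#' @examples
#' haversine_km(0, 0, 0, 1) # one degree of longitude at the equator
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  stopifnot(is.numeric(lat1), is.numeric(lon1), is.numeric(lat2), is.numeric(lon2))
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dphi <- deg2rad(lat2 - lat1)
  dlam <- deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

# Intermediate point at fraction f along the great circle from p1 to p2.
# Vectorised over f. Returns list(lat, lon).
gc_interpolate <- function(lat1, lon1, lat2, lon2, f) {
  phi1 <- deg2rad(lat1); lam1 <- deg2rad(lon1)
  phi2 <- deg2rad(lat2); lam2 <- deg2rad(lon2)
  d <- 2 * asin(sqrt(pmin(pmax(
    sin((phi2 - phi1) / 2)^2 + cos(phi1) * cos(phi2) * sin((lam2 - lam1) / 2)^2,
    0), 1)))
  if (d < 1e-12) {
    return(list(lat = rep(lat1, length(f)), lon = rep(lon1, length(f))))
  }
  A <- sin((1 - f) * d) / sin(d)
  B <- sin(f * d) / sin(d)
  x <- A * cos(phi1) * cos(lam1) + B * cos(phi2) * cos(lam2)
  y <- A * cos(phi1) * sin(lam1) + B * cos(phi2) * sin(lam2)
  z <- A * sin(phi1) + B * sin(phi2)
  list(lat = rad2deg(atan2(z, sqrt(x^2 + y^2))), lon = rad2deg(atan2(y, x)))
}

# Displace a point by (dx, dy) km in a local tangent plane (east, north).
# Used for isotropic positional noise; adequate for offsets << Earth radius.
offset_km <- function(lat, lon, dx_km, dy_km) {
  dlat <- (dy_km / EARTH_RADIUS_KM) * 180 / pi
  dlon <- (dx_km / (EARTH_RADIUS_KM * cos(deg2rad(lat)))) * 180 / pi
  list(lat = lat + dlat, lon = lon + dlon)
}
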