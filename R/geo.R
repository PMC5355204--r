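# Spherical geometry helpers shared by the filter, distance and UD code.
# All distances are great-circle on a sphere of radius 6371 km.

EARTH_RADIUS_KM <- 6371.0

check_lonlat <- function(lon, lat, what = "coordinate") {
  if (any(!is.finite(lon)) || any(!is.finite(lat)) ||
      any(lon < -180 | lon > 180) || any(lat < -90 | lat > 90)) {
    stop(what, "s must be finite, with lon in [-180, 180] and lat in [-90, 90]",
         call. = FALSE)
  }
  invisible(NULL)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance between points on a sphere of radius 6371 km.
#' Vectorised over both arguments (recycled to a common length).
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84 lon/lat).
#' @return Numeric vector of distances in km.
#' @examples
#' great_circle_km(0, 0, 0, 1) # one degree of latitude, ~111.19 km
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  check_lonlat(c(lon1, lon2), c(lat1, lat2))
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM)
}

#' Turning angle at an intermediate fix
#'
#' Deviation, in degrees, of the leg b -> c from the straight continuation of
#' a -> b, measured on the sphere. 0 means the track continues straight,
#' 180 means an exact back-track. Vectorised.
#'
#' @param lon_a,lat_a,lon_b,lat_b,lon_c,lat_c Coordinates of the three fixes
#'   in decimal degrees.
#' @return Angle in degrees in \[0, 180\]; `NA` where consecutive points
#'   coincide (the angle is undefined there).
#' @export
turning_angle_deg <- function(lon_a, lat_a, lon_b, lat_b, lon_c, lat_c) {
  check_lonlat(c(lon_a, lon_b, lon_c), c(lat_a, lat_b, lat_c))
  a <- cbind(lon_a, lat_a)
  b <- cbind(lon_b, lat_b)
  cc <- cbind(lon_c, lat_c)
  incoming <- geosphere::finalBearing(a, b, a = EARTH_RADIUS_KM * 1000, f = 0)
  outgoing <- geosphere::bearing(b, cc, a = EARTH_RADIUS_KM * 1000, f = 0)
  dev <- abs(((outgoing - incoming + 180) %% 360) - 180)
  coincident <- (a[, 1] == b[, 1] & a[, 2] == b[, 2]) |
    (b[, 1] == cc[, 1] & b[, 2] == cc[, 2])
  dev[coincident] <- NA_real_
  dev
}

# Local azimuthal-equidistant projection about (lon0, lat0). Returns planar
# km coordinates; exact inverse via destination-point. Used by the UD code
# and the track simulator, where study areas span well under 10 degrees.
project_aeqd <- function(lon, lat, lon0, lat0) {
  d <- great_circle_km(lon0, lat0, lon, lat)
  brg <- geosphere::bearing(cbind(lon0, lat0), cbind(lon, lat),
                            a = EARTH_RADIUS_KM * 1000, f = 0)
  brg[d == 0] <- 0
  rad <- brg * pi / 180
  cbind(x = d * sin(rad), y = d * cos(rad))
}

unproject_aeqd <- function(x, y, lon0, lat0) {
  d <- sqrt(x^2 + y^2)
  brg <- atan2(x, y) * 180 / pi
  out <- geosphere::destPoint(cbind(lon0, lat0), brg, d,
                              r = EARTH_RADIUS_KM)
  colnames(out) <- c("lon", "lat")
  out
}
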