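# Great-circle geometry on the WGS84 mean sphere. All package distances use
# the haversine formula with R = 6371.0088 km; at study-area scales (< 100 km)
# ellipsoidal corrections are below GPS fix error.

EARTH_RADIUS_M <- 6371008.8

#' Great-circle distance between points (km)
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Inputs are
#' recycled; either argument may be a single point.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84).
#' @return Numeric vector of distances in kilometres.
#' @export
gc_dist_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_M) / 1000
}

#' Cumulative along-path length of a track (km)
#'
#' @param lon,lat Coordinate vectors in decimal degrees.
#' @return Numeric vector of cumulative great-circle distance, starting at 0.
#' @export
path_cumdist_km <- function(lon, lat) {
  n <- length(lon)
  if (n < 2L) return(rep(0, n))
  legs <- gc_dist_km(lon[-n], lat[-n], lon[-1L], lat[-1L])
  c(0, cumsum(legs))
}

# Local azimuthal-equidistant projection centred on `origin` (lon, lat).
# x = d sin(theta), y = d cos(theta) with d the great-circle distance (km)
# and theta the initial bearing; exact in distance-from-origin, and accurate
# to well under 0.1% for inter-point distances at < 100 km from the origin.
project_local <- function(lon, lat, origin) {
  p <- cbind(lon, lat)
  d <- geosphere::distHaversine(origin, p, r = EARTH_RADIUS_M) / 1000
  b <- geosphere::bearing(matrix(origin, nrow = 1), p) * pi / 180
  b[is.na(b)] <- 0  # coincident with origin
  cbind(x = d * sin(b), y = d * cos(b))
}

unproject_local <- function(x, y, origin) {
  d <- sqrt(x^2 + y^2)
  b <- atan2(x, y) * 180 / pi
  out <- geosphere::destPoint(matrix(origin, nrow = 1), b, d * 1000,
                              r = EARTH_RADIUS_M)
  out[d == 0, 1] <- origin[1]
  out[d == 0, 2] <- origin[2]
  colnames(out) <- c("lon", "lat")
  out
}
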