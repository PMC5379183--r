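#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the IUGG mean Earth
#' radius). At the regional extents this package targets (up to country scale)
#' ellipsoidal corrections are immaterial to percentile ranks, so a spherical
#' model is used throughout.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84).
#'   Vectorised; the usual recycling rules apply.
#' @return Numeric vector of distances in kilometres.
#' @examples
#' haversine_km(52.52, 13.405, 48.857, 2.352) # Berlin - Paris, ~878 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371.0088
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}
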