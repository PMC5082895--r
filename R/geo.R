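# Spherical-earth conventions used throughout: haversine great-circle
# distances with R = 6371 km, reported in nautical miles (1 nmi = 1852 m).
# Sub-0.5% error vs a geodesic at subarctic latitudes.
EARTH_RADIUS_M <- 6371000
NMI_M <- 1852

#' Great-circle distance in nautical miles
#'
#' Haversine distance (sphere of radius 6371 km) between points given in
#' decimal degrees WGS84. Vectorised over pairs.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Distance(s) in nautical miles.
#' @export
gc_dist_nmi <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lon2))
  if (n == 0) return(numeric(0))
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_M) / NMI_M
}

#' Initial great-circle bearing in degrees
#' @inheritParams gc_dist_nmi
#' @return Bearing(s) in degrees clockwise from north.
#' @export
gc_bearing <- function(lon1, lat1, lon2, lat2) {
  geosphere::bearing(cbind(lon1, lat1), cbind(lon2, lat2))
}

#' Dead-reckon along a great circle
#'
#' Destination point(s) after travelling `dist_nmi` on bearing `bearing_deg`.
#'
#' @param lon,lat Start coordinates, decimal degrees.
#' @param bearing_deg Bearing, degrees clockwise from north.
#' @param dist_nmi Distance(s) in nautical miles.
#' @return Matrix with columns `lon`, `lat`.
#' @export
gc_destination <- function(lon, lat, bearing_deg, dist_nmi) {
  p <- geosphere::destPoint(cbind(lon, lat), bearing_deg, dist_nmi * NMI_M,
                            r = EARTH_RADIUS_M)
  colnames(p) <- c("lon", "lat")
  p
}

#' Unit conversions
#'
#' Conversions between nautical miles, kilometres, knots and km/h, with
#' 1 nmi = 1.852 km exactly.
#'
#' @param x Numeric vector.
#' @return Converted numeric vector.
#' @export
nmi_to_km <- function(x) x * 1.852

#' @rdname nmi_to_km
#' @export
km_to_nmi <- function(x) x / 1.852

#' @rdname nmi_to_km
#' @export
kn_to_kph <- function(x) x * 1.852

#' @rdname nmi_to_km
#' @export
kph_to_kn <- function(x) x / 1.852

# cross-track distance (nmi) from point p to the great circle through a->b
gc_cross_track_nmi <- function(plon, plat, alon, alat, blon, blat) {
  abs(geosphere::dist2gc(cbind(alon, alat), cbind(blon, blat),
                         cbind(plon, plat), r = EARTH_RADIUS_M)) / NMI_M
}
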