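# Mean Earth radius, km (IUGG mean radius, the conventional haversine value)
EARTH_RADIUS_KM <- 6371.0

#' Great-circle distance between points on the Earth
#'
#' Haversine great-circle distance between pairs of WGS84 coordinates,
#' using a spherical Earth of radius 6371.0 km. Inputs are recycled to a
#' common length. Longitudes outside \[-180, 180\] are wrapped back into
#' range; latitudes outside \[-90, 90\] are an error.
#'
#' @param lat1,lon1 Numeric vectors, decimal degrees of the first point(s).
#' @param lat2,lon2 Numeric vectors, decimal degrees of the second point(s).
#' @return Numeric vector of distances in kilometres.
#' @examples
#' haversine_km(0, 0, 0, 1)    # one degree of longitude on the equator
#' haversine_km(25.04, 121.56, 25.03, 121.50)
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  lat1 <- check_lat(lat1)
  lat2 <- check_lat(lat2)
  lon1 <- wrap_lon(lon1)
  lon2 <- wrap_lon(lon2)
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dphi <- (lat2 - lat1) * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

check_lat <- function(lat) {
  if (!is.numeric(lat) || anyNA(lat)) {
    stop("latitudes must be numeric and non-missing", call. = FALSE)
  }
  if (any(lat < -90 | lat > 90)) {
    stop("latitude out of range [-90, 90]", call. = FALSE)
  }
  as.numeric(lat)
}

# Wrap longitudes into [-180, 180); 180 itself is preserved.
wrap_lon <- function(lon) {
  if (!is.numeric(lon) || anyNA(lon)) {
    stop("longitudes must be numeric and non-missing", call. = FALSE)
  }
  out <- ((as.numeric(lon) + 180) %% 360) - 180
  out[lon == 180] <- 180
  out
}
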