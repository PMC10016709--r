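#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. Thin wrapper around
#' [geosphere::distHaversine()] taking latitude/longitude in decimal degrees
#' (WGS84). Vectorized and recycling over its arguments.
#'
#' Spherical rather than ellipsoidal distance is used throughout: vessel
#' routes are modelled as straight-line single-mode legs, and the sphere
#' approximation error is far below the uncertainty of the cost parameters
#' it multiplies.
#'
#' @param lat1,lon1 first point(s), decimal degrees.
#' @param lat2,lon2 second point(s), decimal degrees.
#' @return distance(s) in km; zero iff the points coincide.
#' @export
#' @examples
#' haversine_km(-16.92, 145.78, -19.26, 146.82) # Cairns to Townsville, ~282 km
haversine_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

check_coords <- function(lat, lon, where = NULL) {
  bad <- !is.finite(lat) | !is.finite(lon) | abs(lat) > 90 | abs(lon) > 180
  if (any(bad)) {
    stop(sprintf("invalid coordinates%s at position(s) %s",
                 if (is.null(where)) "" else paste0(" in ", where),
                 paste(utils::head(which(bad), 5L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}
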