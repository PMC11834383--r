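# Great-circle geometry for site networks.

EARTH_RADIUS_KM <- 6371.0

#' Haversine great-circle distance in kilometres
#'
#' Distance between points given as decimal-degree latitude/longitude,
#' computed on a sphere of radius 6371 km. Vectorised over its arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in kilometres.
#' @export
#' @examples
#' haversine_km(51.77, -1.34, 52.16, 5.59)  # Wytham -> Hoge Veluwe
haversine_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  n <- max(length(lat1), length(lat2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  as.numeric(geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM))
}

check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop_demosync("non-finite coordinates")
  if (any(lat < -90 | lat > 90))
    stop_demosync("latitude out of range [-90, 90]")
  if (any(lon < -180 | lon > 180))
    stop_demosync("longitude out of range [-180, 180]")
  invisible(TRUE)
}

#' Pairwise distance matrix for a set of study sites
#'
#' @param sites Data frame with columns `population_id`, `lat`, `lon`.
#' @return An object of class `site_geometry`: a list with `ids` and the
#'   symmetric, zero-diagonal distance matrix `dist_km` (row/column names are
#'   the population ids).
#' @export
haversine_matrix <- function(sites) {
  stopifnot(is.data.frame(sites),
            all(c("population_id", "lat", "lon") %in% names(sites)))
  if (anyDuplicated(sites$population_id))
    stop_demosync("duplicated population_id in sites")
  check_coords(sites$lat, sites$lon)
  ids <- as.character(sites$population_id)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    pts <- cbind(sites$lon, sites$lat)
    d[] <- geosphere::distm(pts, pts,
      fun = function(p1, p2) geosphere::distHaversine(p1, p2,
                                                      r = EARTH_RADIUS_KM))
    d <- (d + t(d)) / 2  # enforce exact symmetry
    diag(d) <- 0
  }
  structure(list(ids = ids, dist_km = d,
                 lat = setNames(sites$lat, ids),
                 lon = setNames(sites$lon, ids)),
            class = "site_geometry")
}

#' @export
print.site_geometry <- function(x, ...) {
  cat("site_geometry:", length(x$ids), "sites, max separation",
      sprintf("%.0f km\n", max(x$dist_km)))
  invisible(x)
}
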