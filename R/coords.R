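#' Coordinate conventions and distance matrices
#'
#' The synthetic landscape lives in a projected plane with coordinates in
#' kilometres. Real monitor tables carry lon/lat, so a fixed affine
#' equirectangular mapping anchored at a reference point converts between the
#' two; it is exact enough over a few hundred kilometres that both conventions
#' can be exercised by the same pipeline.
#'
#' @name coords
NULL

# Reference anchor for the projected <-> geographic affine map.
# One degree of latitude ~ 110.574 km; longitude scaled by cos(lat0).
.airlur_lon0 <- -95
.airlur_lat0 <- 38
.airlur_km_per_deg_lat <- 110.574
.airlur_km_per_deg_lon <- 111.320 * cos(38 * pi / 180)

#' Convert projected km coordinates to lon/lat
#'
#' @param xy two-column matrix (or data.frame) of x/y in km.
#' @return two-column matrix with columns `lon`, `lat`.
#' @export
km_to_lonlat <- function(xy) {
  xy <- as.matrix(xy)
  cbind(lon = .airlur_lon0 + xy[, 1] / .airlur_km_per_deg_lon,
        lat = .airlur_lat0 + xy[, 2] / .airlur_km_per_deg_lat)
}

#' Convert lon/lat to projected km coordinates
#'
#' Inverse of [km_to_lonlat()].
#' @param ll two-column matrix (or data.frame) of lon/lat.
#' @return two-column matrix with columns `x`, `y` (km).
#' @export
lonlat_to_km <- function(ll) {
  ll <- as.matrix(ll)
  cbind(x = (ll[, 1] - .airlur_lon0) * .airlur_km_per_deg_lon,
        y = (ll[, 2] - .airlur_lat0) * .airlur_km_per_deg_lat)
}

#' Pairwise distance matrix in kilometres
#'
#' Euclidean distance for projected km coordinates; great-circle (haversine)
#' distance for lon/lat input. Kriging needs a metric, and the choice is
#' exposed because monitor tables are natively geographic while the synthetic
#' truth is planar.
#'
#' @param a,b two-column coordinate matrices; `b` defaults to `a`.
#' @param metric `"euclidean"` (input in km) or `"greatcircle"` (input lon/lat).
#' @return a `nrow(a)` x `nrow(b)` matrix of distances in km.
#' @export
dist_km <- function(a, b = a, metric = c("euclidean", "greatcircle")) {
  metric <- match.arg(metric)
  a <- as.matrix(a); b <- as.matrix(b)
  if (metric == "euclidean") {
    dx <- outer(a[, 1], b[, 1], "-")
    dy <- outer(a[, 2], b[, 2], "-")
    sqrt(dx * dx + dy * dy)
  } else {
    m <- matrix(0, nrow(a), nrow(b))
    for (j in seq_len(nrow(b))) {
      m[, j] <- geosphere::distHaversine(a, b[j, , drop = FALSE]) / 1000
    }
    m
  }
}
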