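#' Buffer-based geographic predictor variables
#'
#' Land-use-regression predictors are summaries of geographic layers around
#' each site: counts of point features, clipped road length, area fractions
#' and areally apportioned population within circular buffers (radii 50 m to
#' 15 km), distances to the nearest source, raw position, and nearest-cell
#' samples of coarse satellite pollution-proxy rasters. Buffers are planar
#' circles in the projected km plane; clipping is exact (segment-circle and
#' rectangle-circle intersection in closed form), not rasterised.
#'
#' @name geo-features
NULL

.buffer_radius_bounds_m <- c(50, 15000)

check_radius <- function(radius_m) {
  if (radius_m < .buffer_radius_bounds_m[1] || radius_m > .buffer_radius_bounds_m[2])
    stop("buffer radius must be within [50 m, 15 km], got ", radius_m, " m")
  radius_m / 1000
}

# length of the part of segment (x0,y0)-(x1,y1) inside the disk of radius r
# centred at (cx,cy): solve |p(t)-c|^2 = r^2 for t on [0,1]
segment_in_circle_length <- function(x0, y0, x1, y1, cx, cy, r) {
  dx <- x1 - x0; dy <- y1 - y0
  fx <- x0 - cx; fy <- y0 - cy
  a <- dx * dx + dy * dy
  seg_len <- sqrt(a)
  if (a == 0) return(0)
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx * fx + fy * fy - r * r
  disc <- b * b - 4 * a * cc
  if (disc <= 0) return(0)
  sq <- sqrt(disc)
  t1 <- max((-b - sq) / (2 * a), 0)
  t2 <- min((-b + sq) / (2 * a), 1)
  if (t2 <= t1) return(0)
  (t2 - t1) * seg_len
}

# exact area of intersection between the disk of radius r centred at (cx,cy)
# and the axis-aligned rectangle [ax,bx] x [ay,by]; piecewise-analytic
# integration of the vertical chord length over x
circle_rect_area <- function(cx, cy, r, ax, bx, ay, by) {
  x0 <- max(ax - cx, -r); x1 <- min(bx - cx, r)
  if (x1 <= x0) return(0)
  y0 <- ay - cy; y1 <- by - cy
  if (y1 <= y0) return(0)
  # antiderivative of sqrt(r^2 - x^2)
  G <- function(x) {
    x <- pmin(pmax(x, -r), r)
    (x * sqrt(pmax(r^2 - x^2, 0)) + r^2 * asin(pmin(pmax(x / r, -1), 1))) / 2
  }
  brk <- c(x0, x1)
  for (yy in c(y0, y1)) {
    if (abs(yy) < r) {
      xb <- sqrt(r^2 - yy^2)
      brk <- c(brk, -xb, xb)
    }
  }
  brk <- sort(unique(pmin(pmax(brk, x0), x1)))
  area <- 0
  for (k in seq_len(length(brk) - 1)) {
    a <- brk[k]; b <- brk[k + 1]
    if (b <= a) next
    xm <- (a + b) / 2
    s <- sqrt(max(r^2 - xm * xm, 0))
    top <- min(y1, s); bot <- max(y0, -s)
    if (top <= bot) next
    top_int <- if (y1 < s) y1 * (b - a) else G(b) - G(a)
    bot_int <- if (y0 > -s) y0 * (b - a) else -(G(b) - G(a))
    area <- area + top_int - bot_int
  }
  area
}

#' Aggregate a geographic layer within a circular buffer
#'
#' @param layer one of: a point layer (data.frame with `x`, `y` and
#'   optionally a weight column), a line layer (data.frame with `x0`, `y0`,
#'   `x1`, `y1`), a rectangle/polygon layer (data.frame with `xmin`, `xmax`,
#'   `ymin`, `ymax`), or an `airlur_grid` raster.
#' @param site length-2 projected km coordinates of the buffer centre.
#' @param radius_m buffer radius in metres, within [50, 15000].
#' @param measure `"count"` (points within radius; for a raster, the
#'   cell values apportioned by exact cell-circle overlap — used for
#'   population), `"length"` (total clipped line length inside the buffer,
#'   km), or `"area_fraction"` (clipped rectangle area / buffer area).
#' @return a single numeric value.
#' @export
buffer_aggregate <- function(layer, site, radius_m,
                             measure = c("count", "length", "area_fraction")) {
  measure <- match.arg(measure)
  r <- check_radius(radius_m)
  cx <- site[[1]]; cy <- site[[2]]
  if (measure == "count") {
    if (inherits(layer, "airlur_grid")) {
      return(grid_disk_weighted_sum(layer, cx, cy, r))
    }
    if (!all(c("x", "y") %in% names(layer)))
      stop("count requires a point layer (columns x, y) or a raster")
    if (nrow(layer) == 0) return(0)
    d <- sqrt((layer$x - cx)^2 + (layer$y - cy)^2)
    return(sum(d <= r))
  }
  if (measure == "length") {
    if (!all(c("x0", "y0", "x1", "y1") %in% names(layer)))
      stop("length requires a line layer (columns x0, y0, x1, y1)")
    if (nrow(layer) == 0) return(0)
    tot <- 0
    for (i in seq_len(nrow(layer)))
      tot <- tot + segment_in_circle_length(layer$x0[i], layer$y0[i],
                                            layer$x1[i], layer$y1[i], cx, cy, r)
    return(tot)
  }
  # area_fraction
  if (!all(c("xmin", "xmax", "ymin", "ymax") %in% names(layer)))
    stop("area_fraction requires a rectangle layer (xmin, xmax, ymin, ymax)")
  if (nrow(layer) == 0) return(0)
  a <- 0
  for (i in seq_len(nrow(layer)))
    a <- a + circle_rect_area(cx, cy, r, layer$xmin[i], layer$xmax[i],
                              layer$ymin[i], layer$ymax[i])
  min(a / (pi * r^2), 1)
}

# sum of raster cell values apportioned by the fraction of each cell inside
# the disk (areal weighting); only cells whose bounding box touches the disk
# are visited
grid_disk_weighted_sum <- function(grid, cx, cy, r) {
  cs <- grid$cellsize
  ix0 <- max(1L, floor((cx - r - grid$xll) / cs) + 1L)
  ix1 <- min(grid$nx, floor((cx + r - grid$xll) / cs) + 1L)
  iy0 <- max(1L, floor((cy - r - grid$yll) / cs) + 1L)
  iy1 <- min(grid$ny, floor((cy + r - grid$yll) / cs) + 1L)
  if (ix1 < ix0 || iy1 < iy0) return(0)
  tot <- 0
  cell_area <- cs * cs
  for (ix in ix0:ix1) {
    ax <- grid$xll + (ix - 1) * cs
    for (iy in iy0:iy1) {
      ay <- grid$yll + (iy - 1) * cs
      ov <- circle_rect_area(cx, cy, r, ax, ax + cs, ay, ay + cs)
      if (ov > 0) tot <- tot + grid$values[iy, ix] * ov / cell_area
    }
  }
  tot
}

#' Distance to the nearest point source
#'
#' @param sources non-empty point layer (data.frame with `x`, `y`, projected
#'   km) or, with `metric = "greatcircle"`, columns `lon`, `lat`.
#' @param site site coordinates matching the metric's convention.
#' @param metric distance metric, see [dist_km()].
#' @return distance in metres.
#' @export
distance_to_nearest <- function(sources, site,
                                metric = c("euclidean", "greatcircle")) {
  metric <- match.arg(metric)
  pts <- if (metric == "euclidean") cbind(sources$x, sources$y)
         else cbind(sources$lon, sources$lat)
  if (is.null(pts) || nrow(pts) == 0)
    stop("distance_to_nearest requires a non-empty source set")
  min(dist_km(matrix(as.numeric(site), ncol = 2), pts, metric = metric)) * 1000
}

#' Sample a raster at a point (nearest cell, no interpolation)
#'
#' Cells are half-open so a site exactly on a shared edge falls in the
#' lower-left cell. Sites outside the extent take the nearest cell and are
#' flagged via the `"clamped"` attribute.
#'
#' @param grid an `airlur_grid`.
#' @param site length-2 projected km coordinates.
#' @return the containing cell's value, with attribute `clamped` (logical).
#' @export
sample_grid <- function(grid, site) {
  relx <- (site[[1]] - grid$xll) / grid$cellsize
  rely <- (site[[2]] - grid$yll) / grid$cellsize
  ix <- ceiling(relx); iy <- ceiling(rely)
  if (relx <= 0) ix <- 1L
  if (rely <= 0) iy <- 1L
  clamped <- ix < 1 || ix > grid$nx || iy < 1 || iy > grid$ny
  ix <- min(max(ix, 1L), grid$nx)
  iy <- min(max(iy, 1L), grid$ny)
  structure(grid$values[iy, ix], clamped = clamped)
}

#' Default synthetic predictor-variable specification
#'
#' The analogue of a national predictor list: road length, source count and
#' areally weighted population within each of a set of buffers, plus point
#' variables (satellite sample, distance to nearest source, raw x/y
#' position).
#'
#' @param buffers_m buffer radii in metres.
#' @return data.frame: name, layer, measure, radius_m (NA for point
#'   variables).
#' @export
default_variable_spec <- function(buffers_m = c(100, 500, 1000, 5000, 15000)) {
  buf <- expand.grid(layer = c("roads", "sources", "population"),
                     radius_m = buffers_m, stringsAsFactors = FALSE)
  buf$measure <- c(roads = "length", sources = "count",
                   population = "count")[buf$layer]
  buf$name <- sprintf("%s_%s_%dm",
                      c(roads = "road", sources = "source",
                        population = "pop")[buf$layer],
                      buf$measure, buf$radius_m)
  pointvars <- data.frame(
    name = c("satellite", "dist_source_km", "pos_x", "pos_y"),
    layer = c("satellite", "sources", "position", "position"),
    measure = c("grid_sample", "distance", "coord_x", "coord_y"),
    radius_m = NA_real_, stringsAsFactors = FALSE)
  rbind(buf[, c("name", "layer", "measure", "radius_m")], pointvars)
}

#' Assemble the sites-by-variables feature matrix
#'
#' Evaluates each variable of `spec` at each site, in spec order, so the
#' column layout is identical across training and prediction calls.
#'
#' @param landscape a `landscape`.
#' @param sites matrix or data.frame of projected km coordinates (columns
#'   x, y), one row per site; a `site_id` column is carried through if
#'   present.
#' @param spec variable specification as from [default_variable_spec()];
#'   duplicate names are rejected.
#' @param empty_distance_cap distance (m) substituted when a distance
#'   variable is requested but the source layer is empty; defaults to the
#'   domain diagonal.
#' @return object of class `feature_matrix`: list(site_ids, values,
#'   variable_names, spec).
#' @export
assemble_feature_matrix <- function(landscape, sites,
                                    spec = default_variable_spec(),
                                    empty_distance_cap = NULL) {
  if (nrow(spec) == 0) stop("variable spec must be non-empty")
  if (anyDuplicated(spec$name)) stop("duplicate variable names in spec")
  if (is.data.frame(sites)) {
    ids <- if ("site_id" %in% names(sites)) as.character(sites$site_id)
           else sprintf("site%04d", seq_len(nrow(sites)))
    xy <- cbind(sites$x, sites$y)
  } else {
    xy <- as.matrix(sites)
    ids <- sprintf("site%04d", seq_len(nrow(xy)))
  }
  if (is.null(empty_distance_cap)) {
    db <- landscape$domain_bounds
    empty_distance_cap <- 1000 * sqrt((db["xmax"] - db["xmin"])^2 +
                                        (db["ymax"] - db["ymin"])^2)
  }
  n <- nrow(xy)
  vals <- matrix(NA_real_, n, nrow(spec),
                 dimnames = list(ids, spec$name))
  layer_of <- function(nm) switch(nm,
    roads = landscape$road_segments,
    sources = landscape$point_sources,
    population = landscape$population_grid,
    satellite = landscape$satellite_grid,
    position = NULL,
    stop("unknown layer: ", nm))
  for (j in seq_len(nrow(spec))) {
    lay <- layer_of(spec$layer[j])
    meas <- spec$measure[j]
    vals[, j] <- switch(meas,
      count = , length = , area_fraction =
        vapply(seq_len(n), function(i)
          buffer_aggregate(lay, xy[i, ], spec$radius_m[j], meas), 0),
      grid_sample =
        vapply(seq_len(n), function(i) as.numeric(sample_grid(lay, xy[i, ])), 0),
      distance =
        if (nrow(lay) == 0) rep(empty_distance_cap / 1000, n)
        else vapply(seq_len(n), function(i)
          distance_to_nearest(lay, xy[i, ]) / 1000, 0),
      coord_x = xy[, 1],
      coord_y = xy[, 2],
      stop("unknown measure: ", meas))
  }
  structure(list(site_ids = ids, values = vals,
                 variable_names = spec$name, spec = spec),
            class = "feature_matrix")
}
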