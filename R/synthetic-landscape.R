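#' Synthetic landscape generation
#'
#' The pipeline's real inputs are regulatory monitor extracts plus national
#' GIS layers (roads, point sources, population, coarse satellite pollution
#' products). Those cannot ship with a test suite, so the package generates a
#' synthetic analogue with known parameters: a projected rectangular domain
#' holding urban foci, road segments, emission point sources, a fine
#' population raster and a strictly coarser satellite-proxy raster. Every
#' downstream stage (QC, feature extraction, model fitting, aggregation) is
#' exercised against this recoverable truth.
#'
#' @name synthetic-landscape
NULL

# Run expr with the RNG seeded by `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Simple raster container: values[iy, ix], row 1 = southernmost row.
make_grid <- function(xll, yll, cellsize, nx, ny, values) {
  stopifnot(nrow(values) == ny, ncol(values) == nx)
  structure(list(xll = xll, yll = yll, cellsize = cellsize,
                 nx = nx, ny = ny, values = values),
            class = "airlur_grid")
}

grid_cell_centers <- function(grid) {
  xs <- grid$xll + (seq_len(grid$nx) - 0.5) * grid$cellsize
  ys <- grid$yll + (seq_len(grid$ny) - 0.5) * grid$cellsize
  list(x = xs, y = ys)
}

#' Generate a synthetic landscape
#'
#' Creates urban foci, road segments (anchored near foci with a uniform
#' background share), emission point sources, a 2-km population raster built
#' from Gaussian urban kernels with multiplicative lognormal texture, and a
#' 25-km satellite-proxy raster correlated with the urban/traffic structure.
#'
#' @param seed integer seed; identical seeds give bit-identical landscapes.
#' @param n_roads,n_sources feature counts (may be 0).
#' @param domain_km side length of the square domain in km (> 0).
#' @param n_foci number of urban foci.
#' @param pop_cell_km,sat_cell_km raster resolutions; the satellite grid must
#'   be strictly coarser than the population grid.
#' @return an object of class `landscape`.
#' @export
generate_landscape <- function(seed, n_roads = 60, n_sources = 25,
                               domain_km = 300, n_foci = 4,
                               pop_cell_km = 2, sat_cell_km = 25) {
  if (!is.numeric(domain_km) || length(domain_km) != 1 || domain_km <= 0)
    stop("domain_km must be a single positive extent in km")
  if (n_roads < 0 || n_sources < 0) stop("feature counts must be >= 0")
  if (sat_cell_km <= pop_cell_km)
    stop("satellite grid must be strictly coarser than the population grid")
  with_seed(seed, {
    L <- domain_km
    foci <- data.frame(
      x = runif(n_foci, 0.15 * L, 0.85 * L),
      y = runif(n_foci, 0.15 * L, 0.85 * L),
      weight = as.numeric(rgamma(n_foci, 2, 1))
    )
    foci$weight <- foci$weight / sum(foci$weight)

    roads <- if (n_roads > 0) {
      near <- runif(n_roads) < 0.7
      fi <- sample.int(n_foci, n_roads, replace = TRUE, prob = foci$weight)
      ax <- ifelse(near, foci$x[fi] + rnorm(n_roads, 0, 20), runif(n_roads, 0, L))
      ay <- ifelse(near, foci$y[fi] + rnorm(n_roads, 0, 20), runif(n_roads, 0, L))
      ang <- runif(n_roads, 0, pi)
      len <- runif(n_roads, 5, 60)
      x0 <- ax - cos(ang) * len / 2; x1 <- ax + cos(ang) * len / 2
      y0 <- ay - sin(ang) * len / 2; y1 <- ay + sin(ang) * len / 2
      clamp <- function(v) pmin(pmax(v, 0), L)
      data.frame(x0 = clamp(x0), y0 = clamp(y0), x1 = clamp(x1), y1 = clamp(y1),
                 class = sample(c("highway", "major", "local"), n_roads,
                                replace = TRUE, prob = c(0.2, 0.35, 0.45)))
    } else {
      data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                 y1 = numeric(0), class = character(0))
    }

    sources <- if (n_sources > 0) {
      near <- runif(n_sources) < 0.6
      fi <- sample.int(n_foci, n_sources, replace = TRUE, prob = foci$weight)
      sx <- ifelse(near, foci$x[fi] + rnorm(n_sources, 0, 25), runif(n_sources, 0, L))
      sy <- ifelse(near, foci$y[fi] + rnorm(n_sources, 0, 25), runif(n_sources, 0, L))
      data.frame(x = pmin(pmax(sx, 0), L), y = pmin(pmax(sy, 0), L),
                 emission = rlnorm(n_sources, 0, 0.8))
    } else {
      data.frame(x = numeric(0), y = numeric(0), emission = numeric(0))
    }

    # population raster: urban Gaussian kernels + background, lognormal texture
    nxp <- ceiling(L / pop_cell_km); nyp <- nxp
    cx <- (seq_len(nxp) - 0.5) * pop_cell_km
    cy <- (seq_len(nyp) - 0.5) * pop_cell_km
    dens <- matrix(0, nyp, nxp)
    for (f in seq_len(n_foci)) {
      dx2 <- outer(rep(1, nyp), (cx - foci$x[f])^2)
      dy2 <- outer((cy - foci$y[f])^2, rep(1, nxp))
      dens <- dens + foci$weight[f] * exp(-(dx2 + dy2) / (2 * 12^2))
    }
    pop <- 4000 * dens * matrix(rlnorm(nxp * nyp, 0, 0.5), nyp, nxp) +
      matrix(runif(nxp * nyp, 0, 3), nyp, nxp)
    population_grid <- make_grid(0, 0, pop_cell_km, nxp, nyp, pop)

    land <- structure(list(
      domain_bounds = c(xmin = 0, ymin = 0, xmax = L, ymax = L),
      foci = foci, road_segments = roads, point_sources = sources,
      population_grid = population_grid, satellite_grid = NULL,
      seed = seed), class = "landscape")

    # satellite-proxy raster: noisy coarse view of the urban/traffic structure
    nxs <- ceiling(L / sat_cell_km); nys <- nxs
    sx <- (seq_len(nxs) - 0.5) * sat_cell_km
    sy <- (seq_len(nys) - 0.5) * sat_cell_km
    pts <- cbind(x = rep(sx, each = nys), y = rep(sy, times = nxs))
    cv <- truth_covariates(land, pts)
    sat <- cv[, "urban"] + 0.5 * cv[, "traffic"] +
      rnorm(nrow(pts), 0, 0.08)
    land$satellite_grid <- make_grid(0, 0, sat_cell_km, nxs, nys,
                                     matrix(sat, nys, nxs))
    land
  })
}

# distance from points S (n x 2) to one segment (x0,y0)-(x1,y1)
point_segment_dist <- function(S, x0, y0, x1, y1) {
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx * vx + vy * vy
  if (len2 == 0) return(sqrt((S[, 1] - x0)^2 + (S[, 2] - y0)^2))
  t <- ((S[, 1] - x0) * vx + (S[, 2] - y0) * vy) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((S[, 1] - (x0 + t * vx))^2 + (S[, 2] - (y0 + t * vy))^2)
}

#' Smooth ground-truth covariates at arbitrary points
#'
#' Analytic covariates driving the true concentration surface: an urban
#' kernel (Gaussian bumps at the foci, 15-km bandwidth), a traffic proximity
#' index (exponential decay, 2-km scale, summed over road segments) and a
#' source proximity index (5-km scale, emission-weighted). These are the
#' quantities the buffer-extracted predictor variables are proxies for.
#'
#' @param landscape a `landscape`.
#' @param pts n x 2 matrix of projected km coordinates.
#' @return n x 3 matrix with columns urban, traffic, source.
#' @export
truth_covariates <- function(landscape, pts) {
  pts <- matrix(as.numeric(as.matrix(pts)), ncol = 2)
  n <- nrow(pts)
  foci <- landscape$foci
  urban <- numeric(n)
  for (f in seq_len(nrow(foci))) {
    d2 <- (pts[, 1] - foci$x[f])^2 + (pts[, 2] - foci$y[f])^2
    urban <- urban + foci$weight[f] * exp(-d2 / (2 * 15^2))
  }
  roads <- landscape$road_segments
  traffic <- numeric(n)
  if (nrow(roads) > 0) {
    for (i in seq_len(nrow(roads))) {
      traffic <- traffic +
        exp(-point_segment_dist(pts, roads$x0[i], roads$y0[i],
                                roads$x1[i], roads$y1[i]) / 2)
    }
    traffic <- traffic / nrow(roads) * 10
  }
  src <- landscape$point_sources
  source_ix <- numeric(n)
  if (nrow(src) > 0) {
    w <- src$emission / mean(src$emission)
    for (j in seq_len(nrow(src))) {
      d <- sqrt((pts[, 1] - src$x[j])^2 + (pts[, 2] - src$y[j])^2)
      source_ix <- source_ix + w[j] * exp(-d / 5)
    }
    source_ix <- source_ix / nrow(src) * 10
  }
  cbind(urban = urban, traffic = traffic, source = source_ix)
}
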