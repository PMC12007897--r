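test_that("buffer aggregates handle trivial geometries exactly", {
  # empty layers
  empty_pts <- data.frame(x = numeric(0), y = numeric(0))
  empty_lines <- data.frame(x0 = numeric(0), y0 = numeric(0),
                            x1 = numeric(0), y1 = numeric(0))
  expect_equal(buffer_aggregate(empty_pts, c(0, 0), 1000, "count"), 0)
  expect_equal(buffer_aggregate(empty_lines, c(0, 0), 1000, "length"), 0)

  # a straight segment through the buffer centre: clipped length = 2r
  seg <- data.frame(x0 = -50, y0 = 0, x1 = 50, y1 = 0)
  r_m <- 5000
  expect_equal(buffer_aggregate(seg, c(0, 0), r_m, "length"), 2 * r_m / 1000,
               tolerance = 1e-12)
  # chord off-centre: length = 2*sqrt(r^2 - h^2)
  seg2 <- data.frame(x0 = -50, y0 = 3, x1 = 50, y1 = 3)
  expect_equal(buffer_aggregate(seg2, c(0, 0), r_m, "length"),
               2 * sqrt(5^2 - 3^2), tolerance = 1e-12)

  # full-coverage polygon: area fraction 1
  domain <- data.frame(xmin = -100, xmax = 100, ymin = -100, ymax = 100)
  expect_equal(buffer_aggregate(domain, c(0, 0), 15000, "area_fraction"), 1,
               tolerance = 1e-12)

  # radius bounds and measure/geometry compatibility
  expect_error(buffer_aggregate(seg, c(0, 0), 20, "length"), "50 m")
  expect_error(buffer_aggregate(seg, c(0, 0), 20000, "length"), "15 km")
  expect_error(buffer_aggregate(seg, c(0, 0), 1000, "count"), "point layer")
})

test_that("circle-rectangle intersection area matches quadrature", {
  set.seed(11)
  f <- airlur:::circle_rect_area
  for (i in 1:25) {
    cx <- runif(1, -2, 2); cy <- runif(1, -2, 2); r <- runif(1, 0.5, 3)
    ax <- runif(1, -3, 0); bx <- ax + runif(1, 0.2, 4)
    ay <- runif(1, -3, 0); by <- ay + runif(1, 0.2, 4)
    want <- stats::integrate(function(x) {
      s <- sqrt(pmax(r^2 - (x - cx)^2, 0))
      pmax(0, pmin(by, cy + s) - pmax(ay, cy - s))
    }, max(ax, cx - r), min(bx, cx + r), subdivisions = 2000,
    rel.tol = 1e-10)$value
    expect_equal(f(cx, cy, r, ax, bx, ay, by), want, tolerance = 1e-7)
  }
  # disjoint and fully-contained cases
  expect_equal(f(0, 0, 1, 5, 6, 5, 6), 0)
  expect_equal(f(0, 0, 10, -1, 1, -1, 1), 4, tolerance = 1e-12)
})

test_that("point count and nearest distance match brute-force scans", {
  set.seed(21)
  pts <- data.frame(x = runif(100, 0, 50), y = runif(100, 0, 50))
  site <- c(25, 25)
  for (r_m in c(1000, 5000, 15000)) {
    want <- sum(sqrt((pts$x - site[1])^2 + (pts$y - site[2])^2) <= r_m / 1000)
    expect_equal(buffer_aggregate(pts, site, r_m, "count"), want)
  }
  want_d <- min(sqrt((pts$x - site[1])^2 + (pts$y - site[2])^2)) * 1000
  expect_equal(distance_to_nearest(pts, site), want_d)
  expect_equal(distance_to_nearest(data.frame(x = 25, y = 25), site), 0)
  expect_equal(distance_to_nearest(data.frame(x = c(26, 30), y = c(25, 25)),
                                   site), 1000)
  expect_error(distance_to_nearest(data.frame(x = numeric(0), y = numeric(0)),
                                   site), "non-empty")
})

test_that("grid sampling uses half-open cells with lower-left tie-break", {
  vals <- matrix(1:12, nrow = 3, ncol = 4)   # vals[iy, ix]
  g <- airlur:::make_grid(0, 0, 10, 4, 3, vals)
  # brute-force lookup oracle on random interior sites
  set.seed(3)
  for (i in 1:50) {
    s <- c(runif(1, 0.01, 39.99), runif(1, 0.01, 29.99))
    ix <- min(max(ceiling(s[1] / 10), 1), 4)
    iy <- min(max(ceiling(s[2] / 10), 1), 3)
    expect_equal(as.numeric(sample_grid(g, s)), vals[iy, ix])
  }
  # a site exactly on an interior cell edge falls in the lower-left cell
  expect_equal(as.numeric(sample_grid(g, c(10, 5))), vals[1, 1])
  expect_equal(as.numeric(sample_grid(g, c(15, 10))), vals[1, 2])
  # constant grid returns the constant anywhere
  gc <- airlur:::make_grid(0, 0, 10, 4, 3, matrix(7, 3, 4))
  expect_equal(as.numeric(sample_grid(gc, c(1, 1))), 7)
  # out-of-extent sites clamp to the nearest cell and are flagged
  out <- sample_grid(g, c(-5, 500))
  expect_true(attr(out, "clamped"))
  expect_equal(as.numeric(out), vals[3, 1])
  expect_false(attr(sample_grid(g, c(5, 5)), "clamped"))
})

test_that("population aggregation apportions grid cells by overlap area", {
  # uniform density: weighted count within r equals density * pi r^2
  g <- airlur:::make_grid(0, 0, 1, 60, 60, matrix(5, 60, 60))
  got <- buffer_aggregate(g, c(30, 30), 10000, "count")
  expect_equal(got, 5 * pi * 10^2, tolerance = 1e-9)
  # buffer fully inside one cell: value * (pi r^2 / cell area)
  g2 <- airlur:::make_grid(0, 0, 10, 4, 4, matrix(100, 4, 4))
  expect_equal(buffer_aggregate(g2, c(15, 15), 2000, "count"),
               100 * pi * 2^2 / 100, tolerance = 1e-9)
})

test_that("feature matrix assembly is deterministic, ordered and equivariant", {
  land <- tiny_landscape()
  spec <- default_variable_spec(buffers_m = c(500, 2000, 10000))
  sites <- data.frame(site_id = c("a", "b", "c"),
                      x = c(30, 75, 120), y = c(40, 80, 110))
  fm <- assemble_feature_matrix(land, sites, spec)
  expect_equal(dim(fm$values), c(3, nrow(spec)))
  expect_identical(colnames(fm$values), spec$name)
  # column count: |layer categories| x |buffers| + point variables
  expect_equal(nrow(spec), 3 * 3 + 4)
  # permuting sites permutes rows identically
  fm2 <- assemble_feature_matrix(land, sites[c(3, 1, 2), ], spec)
  expect_equal(fm2$values, fm$values[c(3, 1, 2), ])
  # single variable, 3 sites -> 3 x 1 matrix
  fm1 <- assemble_feature_matrix(land, sites, spec[1, ])
  expect_equal(dim(fm1$values), c(3, 1))
  # duplicate names rejected
  expect_error(assemble_feature_matrix(land, sites, spec[c(1, 1), ]),
               "duplicate")
  # no missing cells
  expect_false(anyNA(fm$values))
})

test_that("count and length features are monotone in buffer radius", {
  land <- tiny_landscape()
  set.seed(9)
  sites <- cbind(runif(10, 10, 140), runif(10, 10, 140))
  radii <- c(100, 500, 1000, 5000, 15000)
  for (i in seq_len(nrow(sites))) {
    lens <- vapply(radii, function(r)
      buffer_aggregate(land$road_segments, sites[i, ], r, "length"), 0)
    cnts <- vapply(radii, function(r)
      buffer_aggregate(land$point_sources, sites[i, ], r, "count"), 0)
    expect_true(all(diff(lens) >= -1e-12))
    expect_true(all(diff(cnts) >= 0))
  }
})

test_that("buffer features are invariant under joint translation", {
  set.seed(13)
  lines <- data.frame(x0 = runif(8, 0, 50), y0 = runif(8, 0, 50),
                      x1 = runif(8, 0, 50), y1 = runif(8, 0, 50))
  pts <- data.frame(x = runif(15, 0, 50), y = runif(15, 0, 50))
  site <- c(20, 30)
  shift <- c(-112.5, 47.25)
  lines2 <- data.frame(x0 = lines$x0 + shift[1], y0 = lines$y0 + shift[2],
                       x1 = lines$x1 + shift[1], y1 = lines$y1 + shift[2])
  pts2 <- data.frame(x = pts$x + shift[1], y = pts$y + shift[2])
  site2 <- site + shift
  expect_equal(buffer_aggregate(lines, site, 8000, "length"),
               buffer_aggregate(lines2, site2, 8000, "length"),
               tolerance = 1e-10)
  expect_equal(buffer_aggregate(pts, site, 8000, "count"),
               buffer_aggregate(pts2, site2, 8000, "count"))
  expect_equal(distance_to_nearest(pts, site),
               distance_to_nearest(pts2, site2), tolerance = 1e-8)
})
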