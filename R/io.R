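#' Plain-text serialisation of pipeline inputs and outputs
#'
#' Monitor series travel as long-format CSV (one row per measurement,
#' ISO-8601 datetimes for hourly series, dates for daily), blocks as CSV with
#' character FIPS, and landscape layers as GeoJSON (roads, sources) plus
#' ESRI ASCII-grid rasters (population, satellite) with a JSON sidecar for
#' the domain metadata. No geospatial binary formats are involved, so
#' fixtures stay text and diffable.
#'
#' @name io
NULL

#' Write / read monitor series CSV
#'
#' Columns: site_id, lon, lat, datetime (hourly) or date (daily), pollutant,
#' value.
#'
#' @param series_list list of `monitor_series` (one cadence per file).
#' @param path file path.
#' @export
write_monitor_csv <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    r <- s$records
    tm <- if (s$cadence == "hourly")
      sprintf("%sT%02d:00:00", format(r$date, "%Y-%m-%d"), r$hour)
    else format(r$date, "%Y-%m-%d")
    data.frame(site_id = unname(s$site_id), lon = unname(s$lon),
               lat = unname(s$lat), time = tm,
               pollutant = unname(s$pollutant), value = unname(r$value),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  df <- do.call(rbind, rows)
  names(df)[names(df) == "time"] <-
    if (series_list[[1]]$cadence == "hourly") "datetime" else "date"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_monitor_csv
#' @param year calendar year the series belong to (recorded on each series).
#' @export
read_monitor_csv <- function(path, year = NULL) {
  df <- utils::read.csv(path, colClasses = c(site_id = "character",
                                             pollutant = "character"))
  hourly <- "datetime" %in% names(df)
  if (hourly) {
    df$date <- as.Date(substr(df$datetime, 1, 10))
    df$hour <- as.integer(substr(df$datetime, 12, 13))
  } else {
    df$date <- as.Date(df$date)
    df$hour <- NA_integer_
  }
  if (is.null(year)) year <- as.integer(format(min(df$date), "%Y"))
  xy <- lonlat_to_km(cbind(df$lon, df$lat))
  df$x <- xy[, "x"]; df$y <- xy[, "y"]
  lapply(split(df, df$site_id), function(d) {
    d <- d[order(d$date, d$hour), ]
    structure(list(site_id = d$site_id[1], lon = d$lon[1], lat = d$lat[1],
                   x = d$x[1], y = d$y[1], pollutant = tolower(d$pollutant[1]),
                   cadence = if (hourly) "hourly" else "daily", year = year,
                   schedule_design = NA_character_,
                   truth_sqrt = NA_real_, truth_native = NA_real_,
                   records = data.frame(date = d$date, hour = d$hour,
                                        value = d$value)),
              class = "monitor_series")
  })
}

#' Write / read the census-block CSV
#'
#' Columns: block_fips, bg_fips, tract_fips, county_fips, lon, lat,
#' population (FIPS as character). Projected km coordinates are recomputed
#' on read.
#'
#' @param blocks block table from [generate_blocks()].
#' @param path file path.
#' @export
write_blocks_csv <- function(blocks, path) {
  utils::write.csv(blocks[, c("block_fips", "bg_fips", "tract_fips",
                              "county_fips", "lon", "lat", "population")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_blocks_csv
#' @export
read_blocks_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(block_fips = "character",
                                             bg_fips = "character",
                                             tract_fips = "character",
                                             county_fips = "character"))
  xy <- lonlat_to_km(cbind(df$lon, df$lat))
  df$x <- xy[, "x"]; df$y <- xy[, "y"]
  df
}

# --- ESRI ASCII grid ---------------------------------------------------------

write_ascii_grid <- function(grid, path) {
  hdr <- c(sprintf("ncols %d", grid$nx), sprintf("nrows %d", grid$ny),
           sprintf("xllcorner %.10g", grid$xll),
           sprintf("yllcorner %.10g", grid$yll),
           sprintf("cellsize %.10g", grid$cellsize),
           "NODATA_value -9999")
  # ASC rows run north to south; internal row 1 is the southernmost
  body <- apply(grid$values[grid$ny:1, , drop = FALSE], 1,
                function(r) paste(format(r, digits = 10, trim = TRUE),
                                  collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hv <- function(i) strsplit(trimws(lines[i]), "\\s+")[[1]][2]
  nx <- as.integer(hv(1)); ny <- as.integer(hv(2))
  xll <- as.numeric(hv(3)); yll <- as.numeric(hv(4))
  cs <- as.numeric(hv(5))
  vals <- matrix(as.numeric(unlist(strsplit(trimws(lines[7:(6 + ny)]), "\\s+"))),
                 nrow = ny, byrow = TRUE)
  make_grid(xll, yll, cs, nx, ny, vals[ny:1, , drop = FALSE])
}

# --- GeoJSON (hand-rolled: no GDAL-backed package in the dependency set) -----

write_landscape_geojson <- function(landscape, roads_path, sources_path) {
  seg_feature <- function(i) {
    r <- landscape$road_segments[i, ]
    a <- km_to_lonlat(cbind(r$x0, r$y0)); b <- km_to_lonlat(cbind(r$x1, r$y1))
    list(type = "Feature",
         properties = list(class = r$class),
         geometry = list(type = "LineString",
                         coordinates = list(c(a[1], a[2]), c(b[1], b[2]))))
  }
  src_feature <- function(i) {
    s <- landscape$point_sources[i, ]
    p <- km_to_lonlat(cbind(s$x, s$y))
    list(type = "Feature",
         properties = list(emission = s$emission),
         geometry = list(type = "Point", coordinates = c(p[1], p[2])))
  }
  fc <- function(feats) list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc(lapply(seq_len(nrow(landscape$road_segments)),
                                 seg_feature)),
                       roads_path, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(fc(lapply(seq_len(nrow(landscape$point_sources)),
                                 src_feature)),
                       sources_path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Write / read a landscape as a directory of plain-text layers
#'
#' `roads.geojson`, `sources.geojson` (lon/lat geometry), `population.asc`,
#' `satellite.asc` (ESRI ASCII grids in projected km) and `meta.json`
#' (domain bounds, seed, urban foci).
#'
#' @param landscape a `landscape`.
#' @param dir directory (created if needed).
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_landscape_geojson(landscape, file.path(dir, "roads.geojson"),
                          file.path(dir, "sources.geojson"))
  write_ascii_grid(landscape$population_grid, file.path(dir, "population.asc"))
  write_ascii_grid(landscape$satellite_grid, file.path(dir, "satellite.asc"))
  jsonlite::write_json(list(domain_bounds = as.list(landscape$domain_bounds),
                            seed = landscape$seed,
                            foci = landscape$foci),
                       file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  gj <- function(p) jsonlite::read_json(file.path(dir, p),
                                        simplifyVector = FALSE)
  roads_raw <- gj("roads.geojson")$features
  roads <- if (length(roads_raw) == 0) {
    data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
               y1 = numeric(0), class = character(0))
  } else {
    do.call(rbind, lapply(roads_raw, function(f) {
      cc <- f$geometry$coordinates
      a <- lonlat_to_km(matrix(unlist(cc[[1]]), ncol = 2))
      b <- lonlat_to_km(matrix(unlist(cc[[2]]), ncol = 2))
      data.frame(x0 = a[1], y0 = a[2], x1 = b[1], y1 = b[2],
                 class = f$properties$class, stringsAsFactors = FALSE)
    }))
  }
  src_raw <- gj("sources.geojson")$features
  sources <- if (length(src_raw) == 0) {
    data.frame(x = numeric(0), y = numeric(0), emission = numeric(0))
  } else {
    do.call(rbind, lapply(src_raw, function(f) {
      p <- lonlat_to_km(matrix(unlist(f$geometry$coordinates), ncol = 2))
      data.frame(x = p[1], y = p[2], emission = f$properties$emission)
    }))
  }
  db <- unlist(meta$domain_bounds)
  structure(list(domain_bounds = db,
                 foci = as.data.frame(meta$foci),
                 road_segments = roads, point_sources = sources,
                 population_grid = read_ascii_grid(file.path(dir, "population.asc")),
                 satellite_grid = read_ascii_grid(file.path(dir, "satellite.asc")),
                 seed = meta$seed),
            class = "landscape")
}

#' Write / read the annual-observation CSV produced by QC
#'
#' @param annual data.frame from [qc_annual()].
#' @param path file path.
#' @export
write_annual_csv <- function(annual, path) {
  utils::write.csv(annual[, c("site_id", "lon", "lat", "pollutant", "year",
                              "value_native", "value_sqrt", "n_valid_days",
                              "schedule", "qc_status", "qc_reason")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annual_csv
#' @export
read_annual_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(site_id = "character"))
  xy <- lonlat_to_km(cbind(df$lon, df$lat))
  df$x <- xy[, "x"]; df$y <- xy[, "y"]
  df
}

#' Write / read a feature matrix as CSV plus a JSON metadata sidecar
#'
#' The CSV holds site_id as its first column followed by the variables in
#' spec order; the sidecar records each variable's layer, measure and buffer
#' radius so train/predict calls can verify alignment.
#'
#' @param fm a `feature_matrix`.
#' @param csv_path,meta_path output paths.
#' @export
write_feature_matrix <- function(fm, csv_path, meta_path) {
  df <- data.frame(site_id = fm$site_ids, fm$values, check.names = FALSE,
                   row.names = NULL)
  utils::write.csv(df, csv_path, row.names = FALSE)
  jsonlite::write_json(fm$spec, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(csv_path, meta_path) {
  df <- utils::read.csv(csv_path, check.names = FALSE,
                        colClasses = c(site_id = "character"))
  spec <- as.data.frame(jsonlite::read_json(meta_path, simplifyVector = TRUE))
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$site_id
  if (!identical(colnames(vals), spec$name))
    stop("feature CSV columns do not match the metadata sidecar")
  structure(list(site_ids = df$site_id, values = vals,
                 variable_names = spec$name, spec = spec),
            class = "feature_matrix")
}

#' Serialise a CV report as JSON plus a per-site prediction CSV
#'
#' @param report a `cv_report`.
#' @param json_path,csv_path output paths (either may be NULL to skip).
#' @export
write_cv_report <- function(report, json_path, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(scheme = report$scheme, mse_r2 = report$mse_r2,
           srmse = report$srmse, n_predictors = report$n_predictors,
           k_pls = report$k_pls, seed = report$seed,
           fold_of_site = as.list(report$fold_of_site)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path))
    utils::write.csv(report$predictions, csv_path, row.names = FALSE)
  invisible(report)
}
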