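#' Read and write rasters as ESRI ASCII grids
#'
#' Single layers are stored as one `.asc` file (plain-text ESRI ASCII grid
#' with a `NODATA_value` of -9999 by default); values are printed with 17
#' significant digits so a write/read round trip is bit-exact for doubles.
#' Categorical layers carry their code-to-label map in a `<path>.codes.json`
#' sidecar. Stacks are stored as a directory of `band_###.asc` files plus a
#' `time.csv` manifest (`band,year,month`).
#'
#' @param path File path (`.asc`) for a layer, or a directory for a stack.
#' @return `read_raster` returns a `dfrfa_raster`; `read_raster_stack` a
#'   `dfrfa_stack`; the writers return `path` invisibly.
#' @name raster_io
NULL

#' @rdname raster_io
#' @param layer A `dfrfa_raster`.
#' @param nodata Sentinel written to file for missing cells.
#' @export
write_raster <- function(layer, path, nodata = -9999) {
  stopifnot(inherits(layer, "dfrfa_raster"))
  g <- layer$grid
  v <- layer$values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.17g", g$origin[1]),
           sprintf("yllcorner %.17g", g$origin[2] - g$n_rows * g$cell_size),
           sprintf("cellsize %.17g", g$cell_size),
           sprintf("NODATA_value %.17g", nodata))
  rows <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  if (layer$kind == "categorical") {
    jsonlite::write_json(as.list(layer$codes), paste0(path, ".codes.json"),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname raster_io
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 7) stop("format error: truncated ASCII grid: ", path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1))
  vals <- as.numeric(vapply(hdr, `[`, "", 2))
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!identical(keys, need))
    stop("format error: bad ASCII grid header in ", path)
  n_cols <- as.integer(vals[1]); n_rows <- as.integer(vals[2])
  cell <- vals[5]; nodata <- vals[6]
  body <- scan(text = lines[-(1:6)], quiet = TRUE)
  if (length(body) != n_rows * n_cols)
    stop("shape error: cell count does not match header in ", path)
  v <- matrix(body, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  v[v == nodata] <- NA
  grid <- grid_create(n_rows, n_cols, cell,
                      origin = c(vals[3], vals[4] + n_rows * cell))
  sidecar <- paste0(path, ".codes.json")
  if (file.exists(sidecar)) {
    codes <- unlist(jsonlite::read_json(sidecar))
    raster_layer(grid, v, kind = "categorical",
                 codes = structure(as.integer(codes), names = names(codes)))
  } else {
    raster_layer(grid, v)
  }
}

#' @rdname raster_io
#' @param stack A `dfrfa_stack`.
#' @export
write_raster_stack <- function(stack, path, nodata = -9999) {
  stopifnot(inherits(stack, "dfrfa_stack"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  nt <- n_layers(stack)
  files <- sprintf("band_%03d.asc", seq_len(nt))
  for (t in seq_len(nt)) {
    write_raster(raster_layer(stack$grid, stack$values[, , t]),
                 file.path(path, files[t]), nodata = nodata)
  }
  utils::write.csv(cbind(data.frame(band = files), stack$time),
                   file.path(path, "time.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname raster_io
#' @export
read_raster_stack <- function(path) {
  manifest <- file.path(path, "time.csv")
  if (!file.exists(manifest)) stop("format error: no time.csv manifest in ", path)
  tm <- utils::read.csv(manifest)
  layers <- lapply(file.path(path, tm$band), read_raster)
  grid <- layers[[1]]$grid
  arr <- array(NA_real_, c(grid$n_rows, grid$n_cols, length(layers)))
  for (t in seq_along(layers)) {
    if (!grid_identical(layers[[t]]$grid, grid))
      stop("shape error: bands on different grids in ", path)
    arr[, , t] <- layers[[t]]$values
  }
  raster_stack(grid, arr, tm[c("year", "month")])
}

geojson_geometry <- function(kind, coords) {
  switch(kind,
    points    = list(type = "Point", coordinates = coords[1, ]),
    polylines = list(type = "LineString", coordinates = coords),
    polygons  = list(type = "Polygon", coordinates = list(coords)))
}

#' Read and write vector layers as GeoJSON
#'
#' Geometries are FeatureCollections of Point, LineString or Polygon
#' features (one geometry type per layer); feature attributes round-trip
#' through GeoJSON `properties`.
#'
#' @param vec A `dfrfa_vector`.
#' @param path Output `.geojson` path.
#' @return `read_vector` returns a `dfrfa_vector`; `write_vector` returns
#'   `path` invisibly.
#' @export
write_vector <- function(vec, path) {
  stopifnot(inherits(vec, "dfrfa_vector"))
  feats <- lapply(seq_along(vec$features), function(i) {
    props <- if (is.null(vec$attributes)) structure(list(), names = character()) else
      as.list(vec$attributes[i, , drop = FALSE])
    list(type = "Feature", properties = props,
         geometry = geojson_geometry(vec$geometry_kind, vec$features[[i]]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_vector
#' @export
read_vector <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop("format error: not a GeoJSON FeatureCollection: ", path)
  gtype <- vapply(gj$features, function(f) f$geometry$type, "")
  kind <- switch(gtype[1], Point = "points", LineString = "polylines",
                 Polygon = "polygons",
                 stop("format error: unsupported geometry ", gtype[1]))
  coords <- lapply(gj$features, function(f) {
    cc <- f$geometry$coordinates
    if (f$geometry$type == "Point") {
      matrix(unlist(cc), ncol = 2)
    } else if (f$geometry$type == "LineString") {
      do.call(rbind, lapply(cc, unlist))
    } else {
      do.call(rbind, lapply(cc[[1]], unlist))   # outer ring only
    }
  })
  props <- lapply(gj$features, function(f) f$properties)
  attrs <- NULL
  if (length(props) && length(props[[1]]))
    attrs <- do.call(rbind, lapply(props, function(p) as.data.frame(p)))
  vector_layer(kind, coords, attrs)
}

#' Read and write polygon series matrices as CSV
#'
#' Rows are polygons (first column `polygon_id`), remaining columns are
#' months labelled `YYYY-MM`.
#'
#' @param series A `dfrfa_series`.
#' @param path Output `.csv` path.
#' @return `read_series` returns a `dfrfa_series`; `write_series` returns
#'   `path` invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "dfrfa_series"))
  df <- data.frame(polygon_id = series$polygon_ids, series$values,
                   check.names = FALSE)
  names(df)[-1] <- time_labels(series$time)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  labs <- names(df)[-1]
  yr <- as.integer(substr(labs, 1, 4)); mo <- as.integer(substr(labs, 6, 7))
  polygon_series(as.matrix(df[, -1, drop = FALSE]), df$polygon_id,
                 data.frame(year = yr, month = mo))
}
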