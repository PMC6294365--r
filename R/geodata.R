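## Covariate derivations on the planar grid: Euclidean distance surfaces,
## buffer masks, Horn slope/aspect, MAP-band x catchment partition, zonal
## means. All distances are planar meters from cell centers.

dist_point_to_segments <- function(px, py, seg) {
  # seg: matrix with columns x1,y1,x2,y2 (one row per segment)
  d2 <- rep(Inf, length(px))
  for (s in seq_len(nrow(seg))) {
    x1 <- seg[s, 1]; y1 <- seg[s, 2]; x2 <- seg[s, 3]; y2 <- seg[s, 4]
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx * dx + dy * dy
    tt <- if (L2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2))
    dd <- (px - (x1 + tt * dx))^2 + (py - (y1 + tt * dy))^2
    d2 <- pmin(d2, dd)
  }
  sqrt(d2)
}

segments_of <- function(coords) {
  n <- nrow(coords)
  cbind(coords[-n, 1], coords[-n, 2], coords[-1, 1], coords[-1, 2])
}

point_in_polygon <- function(px, py, ring) {
  # even-odd ray casting; boundary points handled separately by distance = 0
  n <- nrow(ring) - 1L            # ring closed: last vertex == first
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Euclidean distance surface to a vector layer
#'
#' Per-cell planar distance in meters from the cell center to the nearest
#' feature. Cells whose center lies on a feature (or inside a polygon
#' feature) get 0.
#'
#' @param features A `dfrfa_vector` with at least one feature.
#' @param grid A `dfrfa_grid`.
#' @return A continuous `dfrfa_raster` of distances.
#' @export
euclidean_distance <- function(features, grid) {
  stopifnot(inherits(features, "dfrfa_vector"), inherits(grid, "dfrfa_grid"))
  if (length(features$features) == 0) stop("input error: empty feature set")
  ctr <- grid_cell_centers(grid)
  px <- ctr[, 1]; py <- ctr[, 2]
  d <- rep(Inf, nrow(ctr))
  for (f in features$features) {
    df <- switch(features$geometry_kind,
      points = sqrt((px - f[1, 1])^2 + (py - f[1, 2])^2),
      polylines = dist_point_to_segments(px, py, segments_of(f)),
      polygons = {
        db <- dist_point_to_segments(px, py, segments_of(f))
        db[point_in_polygon(px, py, f)] <- 0
        db
      })
    d <- pmin(d, df)
  }
  raster_layer(grid, matrix(d, nrow = grid$n_rows, byrow = TRUE))
}

#' Binary buffer mask around a vector layer
#'
#' Cell value is 1 iff the Euclidean distance from the cell center to the
#' nearest feature is `<= radius`; identical to thresholding
#' [euclidean_distance()].
#'
#' @inheritParams euclidean_distance
#' @param radius Buffer radius in meters (>= 0).
#' @return A categorical `dfrfa_raster` with codes 0/1.
#' @export
buffer_mask <- function(features, grid, radius) {
  if (!is.numeric(radius) || length(radius) != 1 || is.na(radius) || radius < 0)
    stop("input error: radius must be a single non-negative number")
  d <- euclidean_distance(features, grid)
  raster_layer(grid, (d$values <= radius) * 1L, kind = "categorical",
               codes = c(outside = 0L, inside = 1L))
}

horn_gradients <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 2 || nc < 2) stop("input error: DEM too small for terrain analysis")
  # pad by linear extrapolation so edge cells get one-sided differences
  z <- rbind(2 * z[1, ] - z[2, ], z, 2 * z[nr, ] - z[nr - 1, ])
  z <- cbind(2 * z[, 1] - z[, 2], z, 2 * z[, nc] - z[, nc - 1])
  i <- 2:(nr + 1); j <- 2:(nc + 1)
  cell <- dem$grid$cell_size
  # Horn 3x3 kernel; x east-positive, y north-positive (rows go south)
  gx <- ((z[i - 1, j + 1] + 2 * z[i, j + 1] + z[i + 1, j + 1]) -
         (z[i - 1, j - 1] + 2 * z[i, j - 1] + z[i + 1, j - 1])) / (8 * cell)
  gy <- ((z[i - 1, j - 1] + 2 * z[i - 1, j] + z[i - 1, j + 1]) -
         (z[i + 1, j - 1] + 2 * z[i + 1, j] + z[i + 1, j + 1])) / (8 * cell)
  list(gx = gx, gy = gy)
}

#' Terrain slope and aspect from a DEM (Horn's method)
#'
#' Slope in degrees (>= 0); aspect in degrees clockwise from north in
#' [0, 360), pointing in the downslope direction. Flat cells (zero
#' gradient) get the distinguished aspect code -1.
#'
#' @param dem A continuous `dfrfa_raster` of elevations (meters).
#' @param flat_code Aspect value assigned where slope is 0.
#' @return A continuous `dfrfa_raster`.
#' @export
terrain_slope <- function(dem) {
  g <- horn_gradients(dem)
  raster_layer(dem$grid, atan(sqrt(g$gx^2 + g$gy^2)) * 180 / pi)
}

#' @rdname terrain_slope
#' @export
terrain_aspect <- function(dem, flat_code = -1) {
  g <- horn_gradients(dem)
  asp <- (atan2(-g$gx, -g$gy) * 180 / pi) %% 360
  asp[g$gx == 0 & g$gy == 0] <- flat_code
  asp[is.na(g$gx) | is.na(g$gy)] <- NA
  raster_layer(dem$grid, asp)
}

#' Partition a landscape by MAP band and catchment
#'
#' Bins the mean-annual-precipitation climatology into half-open bands of
#' width `interval` (anchored at the landscape minimum rounded down to the
#' nearest interval), intersects the bands with catchment membership, and
#' relabels the nonempty combinations 1..n in (band, catchment) order.
#'
#' @param map_climatology Continuous `dfrfa_raster`, mm/yr, positive.
#' @param catchments Categorical `dfrfa_raster` of catchment ids.
#' @param interval Band width in mm (default 50).
#' @return A `dfrfa_partition`.
#' @export
partition_by_map <- function(map_climatology, catchments, interval = 50) {
  stopifnot(grid_identical(map_climatology$grid, catchments$grid))
  map <- map_climatology$values
  if (any(map <= 0, na.rm = TRUE)) stop("input error: MAP must be positive")
  anchor <- floor(min(map, na.rm = TRUE) / interval) * interval
  band <- floor((map - anchor) / interval)
  key <- ifelse(is.na(band) | is.na(catchments$values), NA,
                paste(band, catchments$values, sep = ":"))
  u <- unique(key[!is.na(key)])
  parts <- do.call(rbind, strsplit(u, ":", fixed = TRUE))
  u <- u[order(as.numeric(parts[, 1]), as.numeric(parts[, 2]))]
  labels <- matrix(match(key, u), nrow = nrow(map))
  polygon_partition(map_climatology$grid, labels)
}

#' Zonal mean of a raster stack over a polygon partition
#'
#' Entry (p, t) is the mean over the valid pixels of polygon p in month t;
#' nodata pixels are excluded, and a polygon with no valid pixel in a month
#' yields NA.
#'
#' @param stack A `dfrfa_stack`.
#' @param partition A `dfrfa_partition` on the same grid.
#' @return A `dfrfa_series` with one row per polygon.
#' @export
zonal_mean <- function(stack, partition) {
  if (!grid_identical(stack$grid, partition$grid))
    stop("shape error: stack and partition grids differ")
  lab <- as.vector(partition$labels)
  keep <- !is.na(lab)
  nt <- n_layers(stack)
  vmat <- matrix(stack$values, ncol = nt)[keep, , drop = FALSE]
  lab <- lab[keep]
  ok <- !is.na(vmat)
  v0 <- vmat; v0[!ok] <- 0
  sums <- rowsum(v0, lab, reorder = TRUE)
  cnts <- rowsum(ok * 1, lab, reorder = TRUE)
  out <- sums / cnts
  out[cnts == 0] <- NA
  ids <- as.integer(rownames(sums))
  dimnames(out) <- NULL
  polygon_series(out, ids, stack$time)
}
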