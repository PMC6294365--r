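#' Regular analysis grid
#'
#' A grid of square cells in a projected coordinate system (meters), with
#' pixel-center semantics: the center of cell (row, col) is at
#' `x = origin_x + (col - 0.5) * cell_size`,
#' `y = origin_y - (row - 0.5) * cell_size`. Rows count down from the
#' northern (top) edge, columns across from the western (left) edge,
#' 0-based offsets with 1-based R indexing.
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param cell_size Cell edge length in meters (> 0).
#' @param origin Numeric length-2, (x, y) of the upper-left pixel corner.
#' @return An object of class `dfrfa_grid`.
#' @export
grid_create <- function(n_rows, n_cols, cell_size, origin = c(0, n_rows * cell_size)) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0, length(origin) == 2,
            all(is.finite(origin)))
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = as.numeric(cell_size), origin = as.numeric(origin)),
            class = "dfrfa_grid")
}

#' @export
print.dfrfa_grid <- function(x, ...) {
  cat(sprintf("<grid %d x %d, cell %g m, UL corner (%g, %g)>\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2]))
  invisible(x)
}

grid_identical <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Cell-center coordinates of every cell in a grid
#'
#' @param grid A `dfrfa_grid`.
#' @return A two-column matrix (x, y) in row-major cell order, i.e. the
#'   order of `as.vector(t(values))`... Cells are enumerated with column
#'   varying fastest within each row (row-major).
#' @export
grid_cell_centers <- function(grid) {
  rows <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  cols <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  cbind(x = grid$origin[1] + (cols - 0.5) * grid$cell_size,
        y = grid$origin[2] - (rows - 0.5) * grid$cell_size)
}

#' Single-band raster layer
#'
#' @param grid A `dfrfa_grid`.
#' @param values Numeric matrix `n_rows x n_cols`; `NA` marks nodata.
#' @param kind `"continuous"` or `"categorical"`.
#' @param codes For categorical layers, a named integer vector mapping
#'   labels to codes (names are labels).
#' @return A `dfrfa_raster`.
#' @export
raster_layer <- function(grid, values, kind = c("continuous", "categorical"),
                         codes = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (!identical(dim(values), c(grid$n_rows, grid$n_cols)))
    stop("shape error: value matrix dimensions do not match grid")
  if (kind == "categorical" && is.null(codes)) {
    u <- sort(unique(values[!is.na(values)]))
    codes <- structure(as.integer(u), names = as.character(u))
  }
  structure(list(grid = grid, values = values, kind = kind, codes = codes),
            class = "dfrfa_raster")
}

#' @export
print.dfrfa_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster %s %d x %d, %d valid cells, range [%g, %g]>\n",
              x$kind, x$grid$n_rows, x$grid$n_cols, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Monthly raster stack
#'
#' An ordered set of monthly layers on a shared grid with a strictly
#' increasing, consecutive (year, month) time axis.
#'
#' @param grid A `dfrfa_grid`.
#' @param values Numeric array `n_rows x n_cols x T`.
#' @param time Data frame with integer columns `year`, `month`.
#' @return A `dfrfa_stack`.
#' @export
raster_stack <- function(grid, values, time) {
  values <- as.array(values)
  if (length(dim(values)) != 3 ||
      !identical(dim(values)[1:2], c(grid$n_rows, grid$n_cols)))
    stop("shape error: value array dimensions do not match grid")
  if (dim(values)[3] != nrow(time))
    stop("shape error: band count inconsistent with declared time axis")
  idx <- time$year * 12L + (time$month - 1L)
  if (nrow(time) > 1 && any(diff(idx) != 1L))
    stop("shape error: time axis must be strictly increasing consecutive months")
  if (any(time$month < 1L | time$month > 12L))
    stop("shape error: month out of range")
  structure(list(grid = grid, values = values,
                 time = data.frame(year = as.integer(time$year),
                                   month = as.integer(time$month))),
            class = "dfrfa_stack")
}

#' @export
print.dfrfa_stack <- function(x, ...) {
  t1 <- x$time[1, ]; t2 <- x$time[nrow(x$time), ]
  cat(sprintf("<stack %d x %d x %d layers, %04d-%02d .. %04d-%02d>\n",
              x$grid$n_rows, x$grid$n_cols, dim(x$values)[3],
              t1$year, t1$month, t2$year, t2$month))
  invisible(x)
}

n_layers <- function(stack) dim(stack$values)[3]

#' Vector layer (points, polylines or polygons)
#'
#' Coordinates live in the grid's projected system (meters). Polygons are
#' closed rings (first vertex repeated last); this is enforced at
#' construction.
#'
#' @param geometry_kind One of `"points"`, `"polylines"`, `"polygons"`.
#' @param features List of two-column coordinate matrices (one per feature;
#'   points features are 1 x 2).
#' @param attributes Optional data frame with one row per feature.
#' @return A `dfrfa_vector`.
#' @export
vector_layer <- function(geometry_kind = c("points", "polylines", "polygons"),
                         features, attributes = NULL) {
  geometry_kind <- match.arg(geometry_kind)
  features <- lapply(features, function(f) {
    f <- matrix(as.numeric(f), ncol = 2)
    if (!all(is.finite(f))) stop("input error: non-finite coordinates")
    if (geometry_kind == "polygons" && !all(f[1, ] == f[nrow(f), ]))
      f <- rbind(f, f[1, , drop = FALSE])    # close the ring
    f
  })
  if (geometry_kind == "polylines" &&
      any(vapply(features, nrow, 1L) < 2))
    stop("input error: polylines need >= 2 vertices")
  if (!is.null(attributes) && nrow(attributes) != length(features))
    stop("input error: one attribute row per feature required")
  structure(list(geometry_kind = geometry_kind, features = features,
                 attributes = attributes),
            class = "dfrfa_vector")
}

#' Polygon partition of a grid
#'
#' Per-cell polygon labels; valid cells carry a contiguous integer id in
#' `1..n_polygons`, nodata cells are `NA`.
#'
#' @param grid A `dfrfa_grid`.
#' @param labels Integer matrix of polygon ids (NA = nodata).
#' @return A `dfrfa_partition`.
#' @export
polygon_partition <- function(grid, labels) {
  labels <- matrix(as.integer(labels), nrow = grid$n_rows)
  ids <- sort(unique(labels[!is.na(labels)]))
  if (length(ids) == 0) stop("input error: partition has no valid cells")
  if (!identical(ids, seq_along(ids)))
    stop("input error: labels must be contiguous integers 1..n_polygons")
  structure(list(grid = grid, labels = labels, n_polygons = length(ids)),
            class = "dfrfa_partition")
}

#' Polygon-by-time series matrix
#'
#' @param values Numeric matrix `n_polygons x T`.
#' @param polygon_ids Integer vector of polygon ids (row order).
#' @param time Data frame with `year`, `month` columns.
#' @return A `dfrfa_series`.
#' @export
polygon_series <- function(values, polygon_ids, time) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(polygon_ids), ncol(values) == nrow(time))
  structure(list(values = values, polygon_ids = as.integer(polygon_ids),
                 time = data.frame(year = as.integer(time$year),
                                   month = as.integer(time$month))),
            class = "dfrfa_series")
}

time_labels <- function(time) sprintf("%04d-%02d", time$year, time$month)
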