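test_that("euclidean distances honor cell-center geometry", {
  g <- tiny_grid()
  # a settlement point at the center of cell (5, 2)
  pt <- vector_layer("points", list(rbind(c(1.5 * 30, (10 - 4.5) * 30))))
  d <- euclidean_distance(pt, g)
  expect_equal(d$values[5, 2], 0)
  expect_equal(d$values[5, 5], 90)         # 3 cells due east on a 30 m grid
  expect_equal(d$values[5, 8], 180)
  expect_equal(d$values[2, 2], 90)

  # cell center lying on a road polyline -> 0
  road <- vector_layer("polylines", list(rbind(c(0, 135), c(300, 135))))
  dr <- euclidean_distance(road, g)
  expect_true(all(dr$values[6, ] == 0))    # row 6 centers at y = 135

  expect_error(euclidean_distance(vector_layer("points", list()), g),
               "input error")
})

test_that("multi-feature distance equals the minimum of per-feature maps", {
  g <- tiny_grid()
  p1 <- vector_layer("points", list(rbind(c(40, 250))))
  p2 <- vector_layer("points", list(rbind(c(222, 33))))
  both <- vector_layer("points", list(rbind(c(40, 250)), rbind(c(222, 33))))
  expect_equal(euclidean_distance(both, g)$values,
               pmin(euclidean_distance(p1, g)$values,
                    euclidean_distance(p2, g)$values))
})

test_that("distance maps are 1-Lipschitz in cell adjacency", {
  g <- tiny_grid()
  f <- vector_layer("polylines", list(rbind(c(10, 10), c(150, 280))))
  d <- euclidean_distance(f, g)$values
  lim <- g$cell_size * sqrt(2) + 1e-9
  expect_true(all(abs(diff(d)) <= lim))            # vertical neighbors
  expect_true(all(abs(diff(t(d))) <= lim))         # horizontal neighbors
  expect_true(all(abs(d[-1, -1] - d[-10, -10]) <= lim))  # diagonal
})

test_that("buffer masks threshold the distance map and nest by radius", {
  g <- tiny_grid()
  road <- vector_layer("polylines", list(rbind(c(0, 135), c(300, 135))))
  d <- euclidean_distance(road, g)
  for (r in c(0, 90, 1000)) {
    m <- buffer_mask(road, g, r)
    expect_equal(m$values, (d$values <= r) * 1L)
  }
  m90 <- buffer_mask(road, g, 90)$values
  m1000 <- buffer_mask(road, g, 1000)$values
  expect_true(all(m1000 >= m90))                   # monotone in radius
  expect_equal(buffer_mask(road, g, 0)$values, (d$values == 0) * 1L)
  expect_error(buffer_mask(road, g, -5), "input error")
})

test_that("slope and aspect recover an inclined plane analytically", {
  g <- tiny_grid()
  flat <- raster_layer(g, matrix(100, 10, 10))
  expect_true(all(terrain_slope(flat)$values == 0))
  expect_true(all(terrain_aspect(flat)$values == -1))

  # plane rising 1 m per 30 m northward: downslope faces south
  rows <- matrix(rep(1:10, each = 10), 10, 10, byrow = TRUE)
  north_up <- raster_layer(g, (10 - rows) * 1)
  expect_equal(terrain_slope(north_up)$values[5, 5], atan(1 / 30) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(terrain_aspect(north_up)$values[5, 5], 180)
  # linear-extrapolation padding makes edge cells exact on a plane too
  expect_equal(terrain_slope(north_up)$values[1, 1], atan(1 / 30) * 180 / pi,
               tolerance = 1e-12)

  # rotating the plane 90 degrees rotates aspect by 90 degrees:
  # elevation now falls eastward, so the downslope faces east
  east_up <- raster_layer(g, t((10 - rows) * 1))
  expect_equal(terrain_aspect(east_up)$values[5, 5], 90)
  expect_equal(terrain_slope(east_up)$values[5, 5],
               terrain_slope(north_up)$values[5, 5])
})

test_that("MAP banding by 50 mm intervals intersected with catchments", {
  g <- tiny_grid()
  one <- raster_layer(g, matrix(1L, 10, 10), "categorical")
  uniform <- raster_layer(g, matrix(500, 10, 10))
  expect_equal(partition_by_map(uniform, one)$n_polygons, 1)

  # MAP spanning 400..1399 in one catchment -> 20 distinct bands
  map_vals <- matrix(seq(400, 1399, length.out = 100), 10, 10)
  p <- partition_by_map(raster_layer(g, map_vals), one)
  expect_equal(p$n_polygons, length(unique(floor((map_vals - 400) / 50))))
  expect_equal(p$n_polygons, 20)

  # labels: contiguous, cover exactly the valid pixels, deterministic
  two <- raster_layer(g, matrix(rep(1:2, each = 50), 10, 10), "categorical")
  p2 <- partition_by_map(raster_layer(g, map_vals), two)
  expect_equal(sort(unique(as.vector(p2$labels))), seq_len(p2$n_polygons))
  expect_identical(p2$labels,
                   partition_by_map(raster_layer(g, map_vals), two)$labels)
  expect_error(partition_by_map(raster_layer(g, map_vals - 500), one),
               "input error")
})

test_that("zonal means respect masks and affine rescaling", {
  g <- tiny_grid(4, 4)
  labels <- matrix(rep(1:2, each = 8), 4, 4)
  part <- polygon_partition(g, labels)
  tm <- data.frame(year = 2001, month = 1:3)

  const <- raster_stack(g, array(0.5, c(4, 4, 3)), tm)
  expect_true(all(zonal_mean(const, part)$values == 0.5))

  vals <- array(stats::runif(48), c(4, 4, 3))
  zm <- zonal_mean(raster_stack(g, vals, tm), part)
  # brute-force oracle for polygon 2, month 3
  expect_equal(zm$values[2, 3], mean(vals[, , 3][labels == 2]))
  # affine equivariance
  zm2 <- zonal_mean(raster_stack(g, 3 * vals - 1, tm), part)
  expect_equal(zm2$values, 3 * zm$values - 1)

  # nodata pixels drop out of the mean
  vals[1, 1, 1] <- NA
  zm3 <- zonal_mean(raster_stack(g, vals, tm), part)
  expect_equal(zm3$values[1, 1], mean(vals[, , 1][labels == 1], na.rm = TRUE))
  # two-cell polygon mean
  g2 <- tiny_grid(1, 2)
  p2 <- polygon_partition(g2, matrix(1L, 1, 2))
  st2 <- raster_stack(g2, array(c(0.2, 0.4), c(1, 2, 1)),
                      data.frame(year = 2001, month = 1))
  expect_equal(zonal_mean(st2, p2)$values[1, 1], 0.3)
  expect_error(zonal_mean(st2, part), "shape error")
})
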