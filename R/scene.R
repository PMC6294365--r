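## Seeded synthetic savanna landscapes: a north-south mean-annual-
## precipitation gradient (wet north ~1400 mm/yr down to <400 mm/yr in the
## south), a wet season from October to April, monthly driver stacks
## (precipitation, mean/max temperature, soil moisture, PET, fire), static
## social/physical covariates, and pixel NDVI generated from a known
## polygon-level factor structure with planted pixel-level residual-trend
## modifiers -- the ground truth for every downstream stage.

#' Configuration of a synthetic scene
#'
#' Defaults emulate the study conditions: a 60 x 60 grid of 250 m cells
#' (MODIS-like), 10 years of monthly data, MAP falling from 1400 mm/yr in
#' the north to 400 mm/yr in the south, 50-mm MAP bands intersected with
#' catchments, and residual-trend modifiers planted by a protected area
#' (positive: greener than the regional model predicts) and settlement
#' proximity (negative).
#'
#' @param n_rows,n_cols,cell_size Grid shape; cell size in meters.
#' @param n_years Years of monthly data (>= 2).
#' @param start_year First calendar year.
#' @param seed Master seed; every stochastic component draws from its own
#'   sub-seed so, e.g., changing `noise_sd` never perturbs the geography.
#' @param map_range (min, max) mean annual precipitation in mm/yr.
#' @param n_catchments Number of catchments (longitudinal bands with wavy
#'   boundaries).
#' @param n_trends Number of random-walk common trends in the generating
#'   factor structure.
#' @param driver_coefficients Named NDVI-units-per-sd effects of the six
#'   standardized polygon-mean drivers on the polygon NDVI signal.
#' @param modifier_effects Named residual-slope plants, NDVI units per
#'   year: `pa` inside the protected area, `settlement` within
#'   `settlement_radius` of a settlement, `road` within `road_radius` of a
#'   road, `lowland` below the `lowland_quantile` of elevation.
#' @param settlement_radius,road_radius Buffer radii in meters.
#' @param lowland_quantile DEM quantile defining "low elevation".
#' @param noise_sd Pixel-month NDVI noise standard deviation.
#' @param soil_memory AR(1) memory of soil moisture on precipitation.
#' @param min_effect Minimum |slope| (NDVI/yr) counted as a planted class
#'   in the truth labels.
#' @return A `scene_config` list.
#' @export
scene_config <- function(n_rows = 60, n_cols = 60, cell_size = 250,
                         n_years = 10, start_year = 2001, seed = 1,
                         map_range = c(400, 1400), n_catchments = 2,
                         n_trends = 2,
                         driver_coefficients = c(precipitation = 0.04,
                                                 temperature_mean = -0.010,
                                                 temperature_max = -0.015,
                                                 soil_moisture = 0.05,
                                                 pet = -0.02, fire = -0.01),
                         modifier_effects = c(pa = 0.010, settlement = -0.010,
                                              road = 0, lowland = 0),
                         settlement_radius = 1000, road_radius = 90,
                         lowland_quantile = 0.1,
                         noise_sd = 0.05, soil_memory = 0.6,
                         min_effect = 0.006) {
  stopifnot(n_years >= 2, map_range[1] < map_range[2], noise_sd >= 0,
            n_rows >= 16, n_cols >= 16, n_catchments >= 1, n_trends >= 0)
  structure(as.list(environment()), class = "scene_config")
}

smooth_noise <- function(n_rows, n_cols, passes = 8) {
  # gaussian-ish random field by repeated 3x3 mean smoothing, rescaled to sd 1
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  for (k in seq_len(passes)) {
    zp <- rbind(z[1, ], z, z[n_rows, ])
    zp <- cbind(zp[, 1], zp, zp[, n_cols])
    i <- 2:(n_rows + 1); j <- 2:(n_cols + 1)
    z <- matrix((zp[i - 1, j - 1] + zp[i - 1, j] + zp[i - 1, j + 1] +
                 zp[i, j - 1] + zp[i, j] + zp[i, j + 1] +
                 zp[i + 1, j - 1] + zp[i + 1, j] + zp[i + 1, j + 1]) / 9,
                n_rows, n_cols)
  }
  z / stats::sd(z)
}

categorize <- function(field, n_classes, labels) {
  q <- stats::quantile(field, probs = seq(0, 1, length.out = n_classes + 1))
  codes <- as.integer(cut(field, breaks = q, include.lowest = TRUE, labels = FALSE))
  list(values = codes, codes = structure(seq_len(n_classes), names = labels))
}

#' Generate the static landscape of a synthetic scene
#'
#' DEM (north-high gradient plus smoothed noise), the MAP climatology
#' (decreasing north to south across `map_range`), catchments, categorical
#' land cover / soil / country fields, population, an inundated lowland
#' mask, the protected-area polygon, roads, settlements and a river, and
#' the MAP-band x catchment polygon partition. Deterministic given the
#' config seed.
#'
#' @param config A [scene_config()].
#' @return List of static `dfrfa_raster`s, `dfrfa_vector`s, the
#'   `partition`, and the modifier-slope truth (`m_p` raster).
#' @export
make_static_landscape <- function(config) {
  g <- grid_create(config$n_rows, config$n_cols, config$cell_size)
  nr <- g$n_rows; nc <- g$n_cols; cs <- g$cell_size
  rows <- matrix(seq_len(nr), nr, nc)

  set.seed(config$seed * 1000L + 1L)
  dem <- raster_layer(g, 1100 - 500 * (rows - 1) / (nr - 1) + 40 * smooth_noise(nr, nc))

  set.seed(config$seed * 1000L + 2L)
  map_lo <- config$map_range[1]; map_hi <- config$map_range[2]
  span <- map_hi - map_lo
  map_vals <- map_hi - (span - 1) * (rows - 1) / (nr - 1) +
    pmin(4, pmax(-4, 1.5 * smooth_noise(nr, nc)))
  # keep strictly inside [map_lo, map_hi] so the band count is stable
  map_vals <- pmin(pmax(map_vals, map_lo + 0.5), map_hi - 0.5)
  map <- raster_layer(g, map_vals)

  set.seed(config$seed * 1000L + 3L)
  wob <- round(3 * smooth_noise(nr, 1))
  catch_vals <- matrix(0L, nr, nc)
  bounds <- round(seq(0, nc, length.out = config$n_catchments + 1))
  for (r in seq_len(nr)) {
    b <- pmin(nc, pmax(0, bounds[-c(1, length(bounds))] + wob[r]))
    catch_vals[r, ] <- findInterval(seq_len(nc), c(0, b, nc) + 0.5)
  }
  catchments <- raster_layer(g, catch_vals, kind = "categorical",
    codes = structure(seq_len(config$n_catchments),
                      names = paste0("catchment_", seq_len(config$n_catchments))))

  set.seed(config$seed * 1000L + 4L)
  lc <- categorize(smooth_noise(nr, nc), 4,
                   c("woodland", "bushland", "shrubland", "grassland"))
  land_cover <- raster_layer(g, matrix(lc$values, nr, nc), "categorical", lc$codes)
  set.seed(config$seed * 1000L + 5L)
  so <- categorize(smooth_noise(nr, nc), 3, c("arenosol", "cambisol", "luvisol"))
  soil <- raster_layer(g, matrix(so$values, nr, nc), "categorical", so$codes)

  country_vals <- (rows > round(nr * 0.45)) + 1L
  country <- raster_layer(g, country_vals, "categorical",
                          codes = c(north_country = 1L, south_country = 2L))

  # vectors: protected area in the drier south, settlements in the north,
  # a road crossing the middle and a north-south river
  set.seed(config$seed * 1000L + 6L)
  cell_xy <- function(row, col) c(g$origin[1] + (col - 0.5) * cs,
                                  g$origin[2] - (row - 0.5) * cs)
  pa_r <- round(nr * c(0.62, 0.88)); pa_c <- round(nc * c(0.12, 0.26))
  pa_ul <- cell_xy(pa_r[1], pa_c[1]); pa_lr <- cell_xy(pa_r[2], pa_c[2])
  protected <- vector_layer("polygons", list(rbind(
    c(pa_ul[1] - cs / 2, pa_ul[2] + cs / 2), c(pa_lr[1] + cs / 2, pa_ul[2] + cs / 2),
    c(pa_lr[1] + cs / 2, pa_lr[2] - cs / 2), c(pa_ul[1] - cs / 2, pa_lr[2] - cs / 2))),
    attributes = data.frame(name = "synthetic_national_park"))

  n_set <- 4L
  set_rc <- cbind(row = sample(seq(round(nr * 0.08), round(nr * 0.38)), n_set),
                  col = round(seq(0.15, 0.85, length.out = n_set) * nc) +
                    sample(-3:3, n_set, replace = TRUE))
  settlements <- vector_layer("points",
    lapply(seq_len(n_set), function(i) rbind(cell_xy(set_rc[i, 1], set_rc[i, 2]))),
    attributes = data.frame(name = paste0("settlement_", seq_len(n_set))))

  road_rows <- round(nr * c(0.5, 0.42, 0.55, 0.47))
  road_cols <- round(nc * c(0.02, 0.3, 0.7, 0.98))
  roads <- vector_layer("polylines", list(do.call(rbind,
    lapply(1:4, function(i) cell_xy(road_rows[i], road_cols[i])))),
    attributes = data.frame(name = "main_road"))

  riv_col <- round(nc * 0.75)
  rivers <- vector_layer("polylines", list(do.call(rbind,
    lapply(c(1, round(nr * 0.33), round(nr * 0.66), nr), function(r)
      cell_xy(r, riv_col + round(2 * sin(r / 7)))))),
    attributes = data.frame(name = "river"))

  set.seed(config$seed * 1000L + 7L)
  pop_field <- exp(0.8 * smooth_noise(nr, nc))
  ctr <- grid_cell_centers(g)
  for (i in seq_len(n_set)) {
    xy <- cell_xy(set_rc[i, 1], set_rc[i, 2])
    d2 <- (ctr[, 1] - xy[1])^2 + (ctr[, 2] - xy[2])^2
    pop_field <- pop_field +
      matrix(30 * exp(-d2 / (2 * (3 * cs)^2)), nr, nc, byrow = TRUE)
  }
  population <- raster_layer(g, pop_field)

  lowland_thr <- stats::quantile(dem$values, config$lowland_quantile)
  inundated <- raster_layer(g, (dem$values <= lowland_thr) * 1L, "categorical",
                            codes = c(dry = 0L, inundated = 1L))

  partition <- partition_by_map(map, catchments)

  # planted residual-trend surface m_p (NDVI units / yr)
  pa_mask <- buffer_mask(protected, g, 0)
  set_mask <- buffer_mask(settlements, g, config$settlement_radius)
  road_mask <- buffer_mask(roads, g, config$road_radius)
  me <- config$modifier_effects
  m_p <- me[["pa"]] * pa_mask$values +
    me[["settlement"]] * set_mask$values +
    me[["road"]] * road_mask$values +
    me[["lowland"]] * inundated$values
  truth <- list(m_p = raster_layer(g, m_p),
                modifier_effects = me,
                driver_coefficients = config$driver_coefficients)

  list(grid = g, dem = dem, map = map, catchments = catchments,
       land_cover = land_cover, soil = soil, country = country,
       population = population, inundated = inundated,
       protected_areas = protected, settlements = settlements,
       roads = roads, rivers = rivers, partition = partition, truth = truth)
}

season_weights <- function() {
  # wet season Oct-Apr peaking Dec-Feb; near-zero May-Sep
  w <- c(0.17, 0.16, 0.12, 0.06, 0.005, 0, 0, 0, 0.005, 0.05, 0.12, 0.17)
  w / sum(w)
}

#' Generate the monthly driver stacks of a synthetic scene
#'
#' Precipitation follows the MAP climatology scaled by a wet-season
#' profile (peak Dec-Feb, zero-inflated May-Sep) with lognormal
#' interannual multipliers; temperature is sinusoidal (hottest just before
#' the rains) with an elevation lapse; soil moisture is an AR(1) filter of
#' precipitation; PET runs anti-phase with soil moisture; fire counts
#' concentrate in the late dry season. All components are seeded.
#'
#' @param config A [scene_config()].
#' @param statics Output of [make_static_landscape()].
#' @return Named list of six `dfrfa_stack`s: `precipitation`,
#'   `temperature_mean`, `temperature_max`, `soil_moisture`, `pet`, `fire`.
#' @export
make_monthly_drivers <- function(config, statics) {
  g <- statics$grid
  nr <- g$n_rows; nc <- g$n_cols
  nt <- config$n_years * 12L
  time <- data.frame(year = rep(config$start_year + seq_len(config$n_years) - 1L,
                                each = 12L),
                     month = rep(1:12, config$n_years))
  mo <- time$month
  w <- season_weights()

  set.seed(config$seed * 1000L + 11L)
  annual_mult <- exp(stats::rnorm(config$n_years, 0, 0.3) - 0.045)
  precip <- array(0, c(nr, nc, nt))
  for (t in seq_len(nt)) {
    mult <- annual_mult[(t - 1) %/% 12 + 1]
    field <- statics$map$values * w[mo[t]] * mult *
      exp(stats::rnorm(nr * nc, 0, 0.2) - 0.02)
    if (mo[t] %in% 5:9) {
      dry_zero <- stats::runif(nr * nc) < 0.6
      field[dry_zero] <- 0
    }
    precip[, , t] <- field
  }

  set.seed(config$seed * 1000L + 12L)
  lapse <- -0.0065 * (statics$dem$values - mean(statics$dem$values))
  tmean <- array(0, c(nr, nc, nt)); tmax <- array(0, c(nr, nc, nt))
  for (t in seq_len(nt)) {
    seas <- 4 * sin(2 * pi * (mo[t] - 7.5) / 12)   # peak around Oct-Nov
    tmean[, , t] <- 23 + seas + lapse + stats::rnorm(nr * nc, 0, 0.7)
    tmax[, , t] <- 29.5 + 1.2 * seas + lapse + stats::rnorm(nr * nc, 0, 0.9)
  }

  set.seed(config$seed * 1000L + 13L)
  phi <- config$soil_memory
  sm <- array(0, c(nr, nc, nt))
  p_scaled <- precip / mean(precip)
  state <- matrix(mean(p_scaled), nr, nc)
  for (t in seq_len(nt)) {
    state <- phi * state + (1 - phi) * p_scaled[, , t] +
      matrix(stats::rnorm(nr * nc, 0, 0.02), nr, nc)
    sm[, , t] <- state
  }

  set.seed(config$seed * 1000L + 14L)
  pet <- array(0, c(nr, nc, nt))
  for (t in seq_len(nt)) {
    seas <- 25 * sin(2 * pi * (mo[t] - 7.5) / 12)
    pet[, , t] <- 120 + seas - 20 * sm[, , t] + stats::rnorm(nr * nc, 0, 4)
  }

  set.seed(config$seed * 1000L + 15L)
  fire_season <- c(0.02, 0.02, 0.02, 0.05, 0.2, 0.5, 1, 1.6, 1.8, 1.2, 0.2, 0.05)
  fire <- array(0, c(nr, nc, nt))
  fuel <- statics$map$values / mean(statics$map$values)
  for (t in seq_len(nt))
    fire[, , t] <- stats::rpois(nr * nc, fire_season[mo[t]] * 0.4 * fuel)

  lapply(list(precipitation = precip, temperature_mean = tmean,
              temperature_max = tmax, soil_moisture = sm, pet = pet,
              fire = fire),
         function(a) raster_stack(g, a, time))
}

#' Generate NDVI from the polygon factor structure plus planted modifiers
#'
#' Each polygon's signal is
#' `s_p(t) = intercept_p + sum_k c_k z_kp(t) + gamma_p' alpha(t)`, with
#' `z` the standardized polygon-mean drivers and `alpha` seeded
#' random-walk common trends. Pixel NDVI is the polygon signal plus the
#' planted residual trend `m_pixel * (t / 12)` plus N(0, noise_sd) noise,
#' clamped to [-1, 1] (a warning fires if clamping touches more than 5%
#' of values: the configured signal is too large for the NDVI scale).
#'
#' @param config A [scene_config()].
#' @param statics Output of [make_static_landscape()].
#' @param drivers Output of [make_monthly_drivers()].
#' @return List: `ndvi` (a `dfrfa_stack`) and `truth` (modifier raster,
#'   generating states, loadings, intercepts, expected class raster).
#' @export
make_ndvi <- function(config, statics, drivers) {
  g <- statics$grid
  part <- statics$partition
  np <- part$n_polygons
  nt <- n_layers(drivers[[1]])
  time <- drivers[[1]]$time

  zmeans <- lapply(drivers, function(st) standardize_series(zonal_mean(st, part))$values)
  K <- length(zmeans)
  cf <- config$driver_coefficients
  stopifnot(identical(sort(names(cf)), sort(names(drivers))))

  set.seed(config$seed * 1000L + 21L)
  M <- config$n_trends
  states <- if (M > 0) {
    t(apply(matrix(stats::rnorm(M * nt), M, nt), 1, cumsum))
  } else matrix(0, 0, nt)
  if (M == 1) states <- matrix(states, 1, nt)
  loadings <- if (M > 0) matrix(stats::runif(np * M, 0.002, 0.008), np, M) else
    matrix(0, np, 0)

  map_p <- zonal_mean(raster_stack(g, array(statics$map$values, c(g$n_rows, g$n_cols, 1)),
                                   data.frame(year = 2000, month = 1)), part)$values[, 1]
  intercepts <- 0.25 + 0.35 * (map_p - config$map_range[1]) /
    (config$map_range[2] - config$map_range[1])

  signal <- matrix(intercepts, np, nt)
  for (k in seq_len(K)) signal <- signal + cf[[names(zmeans)[k]]] * zmeans[[k]]
  if (M > 0) signal <- signal + loadings %*% states

  lab <- as.vector(part$labels)
  m_p <- as.vector(statics$truth$m_p$values)
  t_years <- (seq_len(nt) - 1) / 12
  set.seed(config$seed * 1000L + 22L)
  pix <- signal[lab, , drop = FALSE] +
    outer(m_p, t_years) +
    matrix(stats::rnorm(length(lab) * nt, 0, config$noise_sd), length(lab), nt)
  clamped <- mean(pix < -1 | pix > 1)
  if (clamped > 0.05)
    warning(sprintf("clamping touched %.1f%% of NDVI values; signal too large for the NDVI scale",
                    100 * clamped))
  pix <- pmin(1, pmax(-1, pix))

  ndvi <- raster_stack(g, array(pix, c(g$n_rows, g$n_cols, nt)), time)
  truth <- c(statics$truth,
             list(states = states, loadings = loadings,
                  intercepts = intercepts, polygon_signal = signal,
                  expected_class = truth_labels(statics$truth$m_p,
                                                config$min_effect)))
  list(ndvi = ndvi, truth = truth)
}

#' Expected trend classes from the planted modifier surface
#'
#' @param m_p Raster of planted residual slopes (NDVI/yr).
#' @param min_effect Minimum |slope| counted as a plant.
#' @return Categorical raster: 1 under (m >= min_effect), -1 over
#'   (m <= -min_effect), 0 none.
#' @export
truth_labels <- function(m_p, min_effect) {
  v <- m_p$values
  cls <- matrix(0L, nrow(v), ncol(v))
  cls[v >= min_effect] <- 1L
  cls[v <= -min_effect] <- -1L
  raster_layer(m_p$grid, cls, "categorical",
               codes = c(over = -1L, none = 0L, under = 1L))
}

#' Generate a complete synthetic scene
#'
#' Convenience wrapper running [make_static_landscape()],
#' [make_monthly_drivers()] and [make_ndvi()].
#'
#' @param config A [scene_config()].
#' @return List with `config`, the statics, `drivers`, `ndvi`, `partition`
#'   and `truth`.
#' @export
make_scene <- function(config = scene_config()) {
  statics <- make_static_landscape(config)
  drivers <- make_monthly_drivers(config, statics)
  nd <- make_ndvi(config, statics, drivers)
  c(list(config = config), statics[setdiff(names(statics), "truth")],
    list(drivers = drivers, ndvi = nd$ndvi, truth = nd$truth))
}

#' Write a scene to disk
#'
#' Emits every raster as an ASCII grid (stacks as band directories),
#' vectors as GeoJSON, the truth surface as CSV, and a JSON manifest
#' listing all artifacts with the seed and a config hash.
#'
#' @param scene Output of [make_scene()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  statics <- c("dem", "map", "catchments", "land_cover", "soil", "country",
               "population", "inundated")
  for (nm in statics)
    write_raster(scene[[nm]], file.path(dir, paste0(nm, ".asc")))
  for (nm in names(scene$drivers))
    write_raster_stack(scene$drivers[[nm]], file.path(dir, nm))
  write_raster_stack(scene$ndvi, file.path(dir, "ndvi"))
  for (nm in c("protected_areas", "settlements", "roads", "rivers"))
    write_vector(scene[[nm]], file.path(dir, paste0(nm, ".geojson")))
  write_raster(scene$partition_raster %||%
                 raster_layer(scene$grid, scene$partition$labels),
               file.path(dir, "partition.asc"))
  lab <- as.vector(scene$partition$labels)
  truth_df <- data.frame(pixel = seq_along(lab),
                         m_p = as.vector(scene$truth$m_p$values),
                         class = as.vector(scene$truth$expected_class$values))
  utils::write.csv(truth_df, file.path(dir, "truth.csv"), row.names = FALSE)
  manifest <- list(seed = scene$config$seed,
                   config_hash = config_hash(scene$config),
                   artifacts = c(paste0(statics, ".asc"),
                                 names(scene$drivers), "ndvi",
                                 "protected_areas.geojson", "settlements.geojson",
                                 "roads.geojson", "rivers.geojson",
                                 "partition.asc", "truth.csv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
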