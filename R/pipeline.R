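## Pipeline orchestration: the five stages (simulate, dfa, trend,
## attribute, report) as plain functions over in-memory objects, plus
## disk-based cmd_* wrappers used by the command-line front-end
## (inst/cli/dfrfa.R). Every stage is deterministic given config + seed.

#' Pipeline configuration
#'
#' One nested list holding every constant of the analysis; defaults follow
#' the study settings where stated (alpha = 0.1, 500 trees, 50-mm MAP
#' bands, 90 m road/river buffers, 1 km settlement buffer).
#'
#' @param scene A [scene_config()] describing the synthetic scene (or NULL
#'   when the pipeline is run on user-supplied artifacts).
#' @param dfa List: `m_trends`, `tol`, `max_iter`.
#' @param trend List: `alpha`, `extreme` (see [classify_trends()]).
#' @param rf List: `n_trees`, `mtry` (NULL = floor(sqrt(p))), `n_points`,
#'   `min_spacing`, `seed`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scene = scene_config(),
                            dfa = list(m_trends = 2, tol = 1e-4, max_iter = 150),
                            trend = list(alpha = 0.1, extreme = "group_median"),
                            rf = list(n_trees = 500, mtry = NULL,
                                      n_points = 150, min_spacing = 0,
                                      seed = 1)) {
  stopifnot(trend$alpha > 0, trend$alpha < 1)
  structure(list(scene = scene, dfa = dfa, trend = trend, rf = rf),
            class = "pipeline_config")
}

#' Stable hash of a configuration
#'
#' MD5 of the deparsed configuration, used to stamp stage outputs so any
#' report is re-derivable.
#'
#' @param config Any R object.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config, control = "all"), f)
  unname(tools::md5sum(f))
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys `scene`, `dfa`, `trend`, `rf` override the corresponding
#' defaults field by field.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  if (!is.null(y$scene)) {
    known <- names(formals(scene_config))
    bad <- setdiff(names(y$scene), known)
    if (length(bad)) stop("validation error: unknown scene field(s): ",
                          paste0("scene.", bad, collapse = ", "))
    sc <- utils::modifyList(as.list(cfg$scene), y$scene)
    cfg$scene <- do.call(scene_config, sc[known[known %in% names(sc)]])
  }
  for (part in c("dfa", "trend", "rf")) {
    if (!is.null(y[[part]])) {
      bad <- setdiff(names(y[[part]]), names(cfg[[part]]))
      if (length(bad)) stop("validation error: unknown field(s): ",
                            paste0(part, ".", bad, collapse = ", "))
      cfg[[part]] <- utils::modifyList(cfg[[part]], y[[part]])
    }
  }
  stopifnot(cfg$trend$alpha > 0, cfg$trend$alpha < 1)
  cfg
}

#' Derive the discrete covariate layers of a scene
#'
#' Distance, buffer and terrain derivations in the fixed, documented
#' feature order used by the attribution stage.
#'
#' @param scene Output of [make_scene()] (or an equivalent list of statics
#'   and vectors).
#' @return Named list of `dfrfa_raster`s: elevation, slope, aspect,
#'   land_cover, soil, country, population, protected_area, inundated,
#'   dist_road, dist_settlement, dist_river, within_90m_road,
#'   within_90m_river, within_1km_settlement.
#' @export
covariate_layers <- function(scene) {
  g <- scene$grid
  sc <- scene$config$scene %||% scene$config    # accept either config shape
  set_r <- if (!is.null(sc$settlement_radius)) sc$settlement_radius else 1000
  road_r <- if (!is.null(sc$road_radius)) sc$road_radius else 90
  list(elevation = scene$dem,
       slope = terrain_slope(scene$dem),
       aspect = terrain_aspect(scene$dem),
       land_cover = scene$land_cover,
       soil = scene$soil,
       country = scene$country,
       population = scene$population,
       protected_area = buffer_mask(scene$protected_areas, g, 0),
       inundated = scene$inundated,
       dist_road = euclidean_distance(scene$roads, g),
       dist_settlement = euclidean_distance(scene$settlements, g),
       dist_river = euclidean_distance(scene$rivers, g),
       within_90m_road = buffer_mask(scene$roads, g, road_r),
       within_90m_river = buffer_mask(scene$rivers, g, road_r),
       within_1km_settlement = buffer_mask(scene$settlements, g, set_r))
}

#' Run the full pipeline in memory
#'
#' simulate -> DFA -> residual trend surface -> random-forest attribution
#' -> report.
#'
#' @param config A [pipeline_config()].
#' @return List with the scene, fitted `dfa` model, `pred` series,
#'   `residuals`, `trend`, `classes`, `summary`, `rf` results and the
#'   final `report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  scene <- make_scene(config$scene)
  stage_dfa <- pipeline_dfa(scene, config)
  stage_trend <- pipeline_trend(scene, stage_dfa$pred, config)
  stage_attr <- pipeline_attribute(scene, stage_trend$classes, config)
  report <- pipeline_report(stage_trend$summary, stage_attr, config)
  c(list(scene = scene), stage_dfa, stage_trend, stage_attr,
    list(report = report))
}

pipeline_dfa <- function(scene, config) {
  ndvi_p <- zonal_mean(scene$ndvi, scene$partition)
  std <- standardize_series(ndvi_p)
  x <- do.call(rbind, lapply(scene$drivers, function(st) {
    colMeans(standardize_series(zonal_mean(st, scene$partition))$values)
  }))
  # drivers enter as landscape-mean standardized series (K x T)
  model <- fit_dfa(std$values, x, m_trends = config$dfa$m_trends,
                   control = dfa_control(tol = config$dfa$tol,
                                         max_iter = config$dfa$max_iter),
                   std = std, time = ndvi_p$time,
                   polygon_ids = ndvi_p$polygon_ids)
  list(ndvi_polygon = ndvi_p, dfa = model, pred = stats::predict(model))
}

pipeline_trend <- function(scene, pred, config) {
  res <- difference(scene$ndvi, pred, scene$partition)
  tr <- trend_surface(res)
  cls <- classify_trends(tr, alpha = config$trend$alpha,
                         extreme = config$trend$extreme)
  list(residuals = res, trend = tr, classes = cls,
       summary = summarize_classes(cls))
}

pipeline_attribute <- function(scene, classes, config) {
  layers <- covariate_layers(scene)
  # binary under/over labels for the headline model: collapse extreme+sig
  v <- classes$values
  binary <- raster_layer(classes$grid, sign(v), "categorical",
                         codes = c(over = -1L, none = 0L, under = 1L))
  n_avail <- min(sum(v > 0, na.rm = TRUE), sum(v < 0, na.rm = TRUE))
  n_points <- min(config$rf$n_points, n_avail)
  pts <- sample_points(binary, classes = c(-1L, 1L), n_points = n_points,
                       min_spacing = config$rf$min_spacing,
                       seed = config$rf$seed)
  feat <- extract_features(pts, layers)
  model <- rf_fit(feat, n_trees = config$rf$n_trees, mtry = config$rf$mtry,
                  seed = config$rf$seed)
  # four-way labels retained for the histogram panels
  pts4 <- pts
  pts4$class <- classes$values[cbind(pts$row, pts$col)]
  feat4 <- extract_features(pts4, layers)
  cls_names <- names(classes$codes)[match(levels(feat4$label),
                                          as.character(classes$codes))]
  levels(feat4$label) <- cls_names
  list(points = pts, features = feat, rf = model,
       mda = importance_mda(model), gini = importance_gini(model),
       histograms = class_histograms(feat4))
}

pipeline_report <- function(summary, attr, config) {
  acc <- round(100 * oob_accuracy(attr$rf), 2)
  list(correct_pct = summary$correct_pct,
       under_pct = summary$under_pct,
       over_pct = summary$over_pct,
       changed_sum_pct = summary$changed_sum_pct,
       unexplained_pct = summary$unexplained_pct,
       rf_oob_accuracy_pct = acc,
       combined_explained_pct = combined_explained(summary$correct_pct, acc),
       per_class = summary$per_class,
       mda = attr$mda, gini = attr$gini,
       seeds = list(scene = config$scene$seed, rf = config$rf$seed),
       config_hash = config_hash(config))
}

## ---- disk-based stage commands (the CLI surface) ----

#' Pipeline stage commands
#'
#' Disk-based wrappers over the in-memory stages: each reads its
#' prerequisites from `outdir`, runs one stage, and writes self-describing
#' artifacts (config hash and seeds embedded). `cmd_report` writes
#' `report.json`. Stages error with a stage-order message when a
#' prerequisite artifact is missing.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @return The stage's main object, invisibly.
#' @export
cmd_simulate <- function(config, outdir) {
  scene <- make_scene(config$scene)
  write_scene(scene, file.path(outdir, "scene"))
  invisible(scene)
}

require_artifact <- function(path, stage) {
  if (!file.exists(path))
    stop("stage-order error: missing artifact ", path,
         "; run ", stage, " first")
  path
}

#' @rdname cmd_simulate
#' @export
cmd_dfa <- function(config, outdir) {
  require_artifact(file.path(outdir, "scene", "manifest.json"), "simulate")
  scene <- make_scene(config$scene)   # scene artifacts are seed-reproducible
  st <- pipeline_dfa(scene, config)
  write_series(st$pred, file.path(outdir, "ndvi_pred.csv"))
  m <- st$dfa
  jsonlite::write_json(list(
    loadings = m$loadings, coefficients = m$coefficients,
    intercepts = m$intercepts, obs_var = m$obs_var,
    loglik = m$loglik, aic = m$aic,
    iterations = m$convergence$iterations, converged = m$convergence$converged,
    config_hash = config_hash(config)),
    file.path(outdir, "dfa_fit.json"), auto_unbox = TRUE, digits = NA)
  invisible(st)
}

#' @rdname cmd_simulate
#' @export
cmd_trend <- function(config, outdir) {
  require_artifact(file.path(outdir, "ndvi_pred.csv"), "dfa")
  scene <- make_scene(config$scene)
  pred <- read_series(file.path(outdir, "ndvi_pred.csv"))
  st <- pipeline_trend(scene, pred, config)
  for (nm in c("tau", "p_value", "beta"))
    write_raster(st$trend[[nm]], file.path(outdir, paste0("trend_", nm, ".asc")))
  write_raster(st$classes, file.path(outdir, "trend_class.asc"))
  utils::write.csv(st$summary$per_class, file.path(outdir, "trend_summary.csv"),
                   row.names = FALSE)
  invisible(st)
}

#' @rdname cmd_simulate
#' @export
cmd_attribute <- function(config, outdir) {
  require_artifact(file.path(outdir, "trend_class.asc"), "trend")
  scene <- make_scene(config$scene)
  classes <- read_raster(file.path(outdir, "trend_class.asc"))
  st <- pipeline_attribute(scene, classes, config)
  utils::write.csv(st$mda, file.path(outdir, "importance_mda.csv"),
                   row.names = FALSE)
  utils::write.csv(st$gini, file.path(outdir, "importance_gini.csv"),
                   row.names = FALSE)
  utils::write.csv(st$histograms, file.path(outdir, "class_histograms.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(n_trees = st$rf$n_trees, mtry = st$rf$mtry,
                            seed = st$rf$seed, oob_error = st$rf$oob_error,
                            config_hash = config_hash(config)),
                       file.path(outdir, "rf_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(st)
}

#' @rdname cmd_simulate
#' @export
cmd_report <- function(config, outdir) {
  require_artifact(file.path(outdir, "trend_summary.csv"), "trend")
  require_artifact(file.path(outdir, "rf_summary.json"), "attribute")
  per_class <- utils::read.csv(file.path(outdir, "trend_summary.csv"))
  rfs <- jsonlite::read_json(file.path(outdir, "rf_summary.json"))
  correct <- per_class$pct[per_class$code == 0]
  under <- sum(per_class$pct[per_class$code > 0])
  over <- sum(per_class$pct[per_class$code < 0])
  acc <- round(100 * (1 - rfs$oob_error), 2)
  report <- list(correct_pct = correct, under_pct = round(under, 2),
                 over_pct = round(over, 2),
                 changed_sum_pct = round(under + over, 2),
                 unexplained_pct = round(100 - correct, 2),
                 rf_oob_accuracy_pct = acc,
                 combined_explained_pct = combined_explained(correct, acc),
                 seeds = list(scene = config$scene$seed, rf = config$rf$seed),
                 config_hash = config_hash(config))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
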