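## Attribution of residual-trend surfaces to discrete social / physical
## covariates: seeded point sampling inside the significant classes,
## feature extraction from the static and derived layers, a random-forest
## classifier with out-of-bag (OOB) accounting, permutation (mean decrease
## in accuracy) and Gini importances, per-class covariate histograms, and
## the combined explained-fraction arithmetic.
##
## Forest construction delegates to the randomForest package (bootstrap
## with replacement at full table size, Gini splits over mtry random
## features, trees grown to purity); majority votes, the documented
## tie-break and OOB error are computed here from the vote counts.

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Sample class-stratified points from a classified raster
#'
#' Draws `n_points` seeded random pixels from each requested class with a
#' minimum pairwise spacing, erroring (with the class and shortfall named)
#' if a class cannot supply them.
#'
#' @param class_raster Categorical raster of class codes.
#' @param classes Integer vector of class codes to sample (default: the
#'   significant codes present, i.e. everything but 0).
#' @param n_points Points per class.
#' @param min_spacing Minimum pairwise point distance in cell units.
#' @param seed Integer seed (sampling is deterministic given it).
#' @return Data frame with columns `row`, `col`, `class`.
#' @export
sample_points <- function(class_raster, classes = NULL, n_points = 1000,
                          min_spacing = 2, seed = 1) {
  stopifnot(n_points >= 1, min_spacing >= 0)
  v <- class_raster$values
  if (is.null(classes)) {
    classes <- sort(setdiff(unique(v[!is.na(v)]), 0))
    if (length(classes) == 0) stop("sampling error: no significant classes present")
  }
  out <- NULL
  for (cl in classes) {
    idx <- which(v == cl, arr.ind = TRUE)
    if (nrow(idx) < n_points)
      stop(sprintf("sampling error: class %s has %d eligible pixels, %d short of %d",
                   cl, nrow(idx), n_points - nrow(idx), n_points))
    ord <- local_seed(seed + as.integer(cl), sample.int(nrow(idx)))
    picked <- matrix(numeric(0), 0, 2)
    for (k in ord) {
      cand <- idx[k, ]
      if (nrow(picked) == 0 ||
          min((picked[, 1] - cand[1])^2 + (picked[, 2] - cand[2])^2) >=
            min_spacing^2) {
        picked <- rbind(picked, cand)
        if (nrow(picked) == n_points) break
      }
    }
    if (nrow(picked) < n_points)
      stop(sprintf(
        "sampling error: class %s supports only %d points at spacing %g (%d short of %d)",
        cl, nrow(picked), min_spacing, n_points - nrow(picked), n_points))
    out <- rbind(out, data.frame(row = picked[, 1], col = picked[, 2],
                                 class = cl))
  }
  rownames(out) <- NULL
  out
}

#' Extract the covariate feature table at sampled points
#'
#' One row per point, one column per covariate layer (fixed, documented
#' order = the order of `layers`), plus the trend-class label. Points that
#' hit nodata in any layer are rejected and reported.
#'
#' @param points Data frame from [sample_points()] (`row`, `col`, `class`).
#' @param layers Named list of `dfrfa_raster` covariate layers on one grid.
#'   Categorical layers become factors using their code maps.
#' @return A data frame (`FeatureTable`) with attribute `rejected` giving
#'   the indices of dropped points.
#' @export
extract_features <- function(points, layers) {
  stopifnot(length(layers) >= 1, !is.null(names(layers)))
  g <- layers[[1]]$grid
  for (ly in layers) if (!grid_identical(ly$grid, g))
    stop("shape error: covariate layers on different grids")
  ij <- cbind(points$row, points$col)
  cols <- lapply(layers, function(ly) {
    vals <- ly$values[ij]
    if (ly$kind == "categorical") {
      lv <- sort(unname(ly$codes))
      factor(vals, levels = lv,
             labels = names(sort(ly$codes)))
    } else vals
  })
  tab <- as.data.frame(cols)
  tab$label <- factor(points$class)
  bad <- which(!stats::complete.cases(tab))
  if (length(bad)) {
    message(length(bad), " point(s) rejected on nodata: rows ",
            paste(utils::head(bad, 10), collapse = ", "),
            if (length(bad) > 10) " ..." else "")
    tab <- tab[-bad, , drop = FALSE]
  }
  attr(tab, "rejected") <- bad
  tab
}

#' Fit a random-forest classifier with OOB bookkeeping
#'
#' Grows `n_trees` classification trees, each on a bootstrap sample drawn
#' with replacement at the size of the table (so the expected unique-row
#' fraction per tree approaches 1 - exp(-1), i.e. roughly 2/3), splitting
#' on the best of `mtry` randomly drawn features by Gini impurity decrease
#' and growing to purity without pruning. Deterministic under `seed`.
#'
#' @param table A FeatureTable from [extract_features()] (factor column
#'   `label` plus feature columns), or any data frame of that shape.
#' @param n_trees Number of trees (paper's worked example: 500).
#' @param mtry Features tried per split; default `floor(sqrt(p))`.
#' @param seed Integer seed.
#' @return An `rf_model`: the fitted ensemble plus bootstrap (in-bag)
#'   counts, the OOB vote matrix, OOB predictions under the smallest-code
#'   tie rule, and the OOB error.
#' @export
rf_fit <- function(table, n_trees = 500, mtry = NULL, seed = 1) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  y <- droplevels(as.factor(table$label))
  if (nlevels(y) < 2) stop("degenerate error: single-class table")
  if (any(tabulate(y) < 10))
    warning("fewer than 10 rows in some class; OOB estimates will be noisy")
  x <- table[, setdiff(names(table), "label"), drop = FALSE]
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(x))))
  fit <- local_seed(seed,
    randomForest::randomForest(x = x, y = y, ntree = n_trees, mtry = mtry,
                               importance = TRUE, keep.inbag = TRUE,
                               keep.forest = TRUE))
  oob_counts <- fit$votes * fit$oob.times      # back to vote counts
  never_oob <- fit$oob.times == 0
  if (any(never_oob))
    warning(sum(never_oob), " row(s) never out-of-bag; excluded from OOB error")
  oob_pred <- majority_vote(oob_counts, levels(y))
  err <- mean(oob_pred[!never_oob] != y[!never_oob])
  structure(list(forest = fit, n_trees = n_trees, mtry = mtry, seed = seed,
                 classes = levels(y), y = y, x = x,
                 inbag = fit$inbag, oob_votes = oob_counts,
                 oob_pred = oob_pred, oob_error = err),
            class = "rf_model")
}

majority_vote <- function(vote_counts, classes) {
  # ties broken by the smallest class code (first level)
  factor(classes[apply(vote_counts, 1, which.max)], levels = classes)
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("Random forest: %d trees, mtry %d, %d rows, classes {%s}\n",
              x$n_trees, x$mtry, length(x$y), paste(x$classes, collapse = ", ")))
  cat(sprintf("  OOB error %.4f (accuracy %.2f%%)\n",
              x$oob_error, 100 * (1 - x$oob_error)))
  invisible(x)
}

#' Predict classes by majority vote over the forest
#'
#' Each row gets the class most trees vote for; exact ties go to the
#' smallest class code.
#'
#' @param model An `rf_model`.
#' @param rows Data frame of feature columns (no missing values).
#' @return Factor of predicted classes.
#' @export
rf_predict <- function(model, rows) {
  if (anyNA(rows)) stop("input error: missing feature values")
  votes <- stats::predict(model$forest, rows, type = "vote", norm.votes = FALSE)
  majority_vote(votes, model$classes)
}

#' Out-of-bag error and accuracy
#'
#' The fraction of rows misclassified by the majority vote of the trees
#' for which the row was out-of-bag.
#'
#' @param model An `rf_model`.
#' @return `oob_error()` a fraction in [0, 1]; `oob_accuracy()` its
#'   complement.
#' @export
oob_error <- function(model) model$oob_error

#' @rdname oob_error
#' @export
oob_accuracy <- function(model) 1 - model$oob_error

#' Per-tree bootstrap bookkeeping
#'
#' @param model An `rf_model`.
#' @return Numeric vector: per-tree fraction of distinct table rows in the
#'   tree's bootstrap sample (expected to approach 1 - exp(-1) ~ 2/3).
#' @export
bootstrap_unique_fraction <- function(model) {
  colMeans(model$inbag > 0)
}

#' Variable importances: mean decrease in accuracy and Gini
#'
#' MDA is the mean over trees of the drop in OOB accuracy when the
#' feature's out-of-bag values are permuted; Gini importance is the total
#' Gini impurity decrease attributed to the feature over all splits and
#' trees. Both are returned raw and normalized to max = 1, with per-class
#' permutation importances alongside for separate under/over panels.
#'
#' @param model An `rf_model`.
#' @return `importance_mda()` and `importance_gini()` each return a data
#'   frame with `feature`, `importance`, `normalized` (and per-class
#'   columns for MDA), sorted by decreasing importance.
#' @export
importance_mda <- function(model) {
  imp <- randomForest::importance(model$forest, type = 1, scale = FALSE)
  per_class <- model$forest$importance[, model$classes, drop = FALSE]
  out <- data.frame(feature = rownames(imp), importance = imp[, 1],
                    normalized = imp[, 1] / max(imp[, 1]),
                    per_class, check.names = FALSE, row.names = NULL)
  out[order(-out$importance), ]
}

#' @rdname importance_mda
#' @export
importance_gini <- function(model) {
  imp <- randomForest::importance(model$forest, type = 2)
  out <- data.frame(feature = rownames(imp), importance = imp[, 1],
                    normalized = imp[, 1] / max(imp[, 1]), row.names = NULL)
  out[order(-out$importance), ]
}

#' Per-class covariate histograms
#'
#' For each covariate, the distribution of each labelled class across bins
#' (continuous covariates, equal-width bins) or categories; proportions
#' within a class sum to 1 across bins. Mirrors the four-way
#' extremely/significantly over/under histogram panels.
#'
#' @param table A FeatureTable (feature columns + factor `label`).
#' @param n_bins Bin count for continuous covariates.
#' @return Long data frame: `covariate`, `bin`, `class`, `n`, `proportion`.
#' @export
class_histograms <- function(table, n_bins = 10) {
  stopifnot("label" %in% names(table))
  lab <- droplevels(as.factor(table$label))
  empty <- setdiff(levels(as.factor(table$label)), levels(lab))
  if (length(empty)) warning("empty class(es) omitted: ",
                             paste(empty, collapse = ", "))
  feats <- setdiff(names(table), "label")
  out <- NULL
  for (f in feats) {
    v <- table[[f]]
    binned <- if (is.factor(v)) v else {
      br <- pretty(range(v, na.rm = TRUE), n_bins)
      cut(v, breaks = br, include.lowest = TRUE)
    }
    tab <- table(bin = binned, class = lab)
    prop <- prop.table(tab, margin = 2)
    df <- as.data.frame(tab, responseName = "n")
    df$proportion <- as.data.frame(prop)$Freq
    df$covariate <- f
    out <- rbind(out, df[, c("covariate", "bin", "class", "n", "proportion")])
  }
  out
}

#' Combined DFA + RF explained fraction
#'
#' The share of the landscape explained when the first-stage model
#' accounts for `correct_pct` percent directly and the classifier explains
#' `rf_accuracy_pct` percent of the remainder:
#' `correct + rf * (100 - correct) / 100`, rounded to 2 decimals.
#'
#' @param correct_pct Percentage of the landscape the first stage predicts
#'   correctly (0-100).
#' @param rf_accuracy_pct Classifier accuracy on the remaining area (0-100).
#' @return Percentage (2 decimals).
#' @export
combined_explained <- function(correct_pct, rf_accuracy_pct) {
  for (v in c(correct_pct, rf_accuracy_pct))
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 100)
      stop("input error: percentages must be single numbers in [0, 100]")
  round(correct_pct + rf_accuracy_pct * (100 - correct_pct) / 100, 2)
}
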