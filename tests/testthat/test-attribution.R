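class_raster_fixture <- function() {
  g <- grid_create(20, 20, 250)
  vals <- matrix(0, 20, 20)
  vals[1:8, 1:8] <- 1
  vals[13:20, 13:20] <- -1
  vals[1, 20] <- NA
  raster_layer(g, vals, "categorical",
               codes = c(over = -1L, none = 0L, under = 1L))
}

test_that("point sampling is stratified, spaced, seeded and exhaustive", {
  cls <- class_raster_fixture()
  pts <- sample_points(cls, n_points = 20, min_spacing = 0, seed = 3)
  expect_equal(as.vector(table(pts$class)), c(20, 20))
  expect_true(all(cls$values[cbind(pts$row, pts$col)] == pts$class))
  expect_identical(pts, sample_points(cls, n_points = 20, min_spacing = 0,
                                      seed = 3))

  # exhaustive case: n_points = available, spacing 0 -> all class pixels
  all_under <- sample_points(cls, classes = 1L, n_points = 64,
                             min_spacing = 0, seed = 1)
  expect_equal(nrow(all_under), 64)
  expect_equal(sort(unique(all_under$row)), 1:8)

  # spacing is enforced pairwise
  sp <- sample_points(cls, classes = 1L, n_points = 10, min_spacing = 2, seed = 2)
  dmat <- as.matrix(stats::dist(sp[, c("row", "col")]))
  expect_true(all(dmat[upper.tri(dmat)] >= 2))

  expect_error(sample_points(cls, classes = 1L, n_points = 65),
               "sampling error.*1 short")
  expect_error(sample_points(cls, classes = 1L, n_points = 60,
                             min_spacing = 4, seed = 1),
               "sampling error")
})

test_that("feature extraction reads layers at points and rejects nodata", {
  cls <- class_raster_fixture()
  g <- cls$grid
  elev <- raster_layer(g, matrix(stats::runif(400, 900, 1100), 20, 20))
  pa <- raster_layer(g, (row(matrix(0, 20, 20)) <= 8) * 1L, "categorical",
                     codes = c(outside = 0L, inside = 1L))
  holes <- elev; holes$values[5, 5] <- NA
  pts <- data.frame(row = c(2, 5, 15), col = c(3, 5, 15), class = c(1, 1, -1))

  tab <- extract_features(pts, list(elevation = elev, protected_area = pa))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$elevation, elev$values[cbind(pts$row, pts$col)])
  expect_equal(as.character(tab$protected_area), c("inside", "inside", "outside"))
  expect_equal(as.character(tab$label), c("1", "1", "-1"))

  expect_message(tab2 <- extract_features(pts, list(elevation = holes)),
                 "rejected")
  expect_equal(nrow(tab2), 2)
  expect_equal(attr(tab2, "rejected"), 2L)
})

test_that("a separable feature drives OOB error to zero and tops both importances", {
  tab <- separable_table(n = 1000, seed = 5)
  fit <- rf_fit(tab, n_trees = 100, seed = 5)
  expect_lt(oob_error(fit), 0.01)
  expect_equal(oob_accuracy(fit), 1 - oob_error(fit))
  expect_equal(as.character(importance_mda(fit)$feature[1]), "driver")
  expect_equal(as.character(importance_gini(fit)$feature[1]), "driver")

  # duplicating an irrelevant feature leaves the driver on top
  tab_dup <- cbind(tab[, setdiff(names(tab), "label")],
                   noise_dup = tab$noise_1, label = tab$label)
  fit_dup <- rf_fit(tab_dup, n_trees = 100, seed = 5)
  expect_equal(as.character(importance_mda(fit_dup)$feature[1]), "driver")

  # a constant feature is never split on: zero Gini importance
  tab_const <- cbind(tab, flatline = 1)
  tab_const <- tab_const[, c("driver", "noise_1", "flatline", "label")]
  fit_c <- rf_fit(tab_const, n_trees = 50, seed = 1)
  gi <- importance_gini(fit_c)
  expect_equal(gi$importance[gi$feature == "flatline"], 0)
})

test_that("shuffled labels push OOB error to one minus the majority prior", {
  tab <- separable_table(n = 900, seed = 6)
  tab$label <- factor(rep(c("over", "under", "under"), 300))  # 2/3 majority
  set.seed(99)
  tab$label <- sample(tab$label)
  fit <- rf_fit(tab, n_trees = 150, seed = 6)
  expect_lt(abs(oob_error(fit) - (1 - 2 / 3)), 0.08)
})

test_that("forests are deterministic under a seed and vote by majority", {
  tab <- separable_table(n = 300, seed = 7)
  f1 <- rf_fit(tab, n_trees = 60, seed = 11)
  f2 <- rf_fit(tab, n_trees = 60, seed = 11)
  expect_identical(f1$oob_error, f2$oob_error)
  expect_identical(importance_mda(f1), importance_mda(f2))
  expect_identical(f1$inbag, f2$inbag)

  newrows <- tab[1:10, setdiff(names(tab), "label")]
  pred <- rf_predict(f1, newrows)
  expect_equal(as.character(pred), as.character(tab$label[1:10]))
  expect_error(rf_predict(f1, transform(newrows, driver = NA)), "input error")

  # documented tie rule: equal votes go to the smallest class code
  votes <- matrix(c(250, 250, 100, 400), 2, 2, byrow = TRUE)
  expect_equal(as.character(dfrfa:::majority_vote(votes, c("1", "2"))),
               c("1", "2"))

  expect_error(rf_fit(data.frame(a = 1:20, label = factor(rep("x", 20)))),
               "degenerate error")
})

test_that("bootstrap bookkeeping shows the roughly-2/3 unique fraction", {
  tab <- separable_table(n = 2000, seed = 8)
  fit <- rf_fit(tab, n_trees = 40, seed = 8)
  fr <- bootstrap_unique_fraction(fit)
  expect_length(fr, 40)
  expect_equal(mean(fr), 1 - exp(-1), tolerance = 0.01)
})

test_that("class histograms tally proportions that sum to one per class", {
  set.seed(61)
  tab <- data.frame(
    elevation = stats::runif(200, 900, 1100),
    pa = factor(sample(c("inside", "outside"), 200, TRUE)),
    label = factor(sample(c("over_sig", "over_extreme", "under_sig",
                            "under_extreme"), 200, TRUE)))
  h <- class_histograms(tab, n_bins = 5)
  for (cl in levels(tab$label)) {
    for (cov_ in c("elevation", "pa")) {
      p <- h$proportion[h$class == cl & h$covariate == cov_]
      expect_equal(sum(p), 1)
    }
  }
  # brute-force tally oracle for one cell
  n_in_over <- sum(tab$pa == "inside" & tab$label == "over_sig")
  expect_equal(h$n[h$covariate == "pa" & h$bin == "inside" &
                     h$class == "over_sig"], n_in_over)

  # degenerate: all of one class inside the protected area
  tab2 <- data.frame(pa = factor(rep("inside", 10), levels = c("inside", "outside")),
                     label = factor(rep("under_sig", 10)))
  h2 <- class_histograms(tab2)
  expect_equal(h2$proportion[h2$bin == "inside"], 1)
})

test_that("combined explained fraction follows the two-stage arithmetic", {
  expect_equal(combined_explained(57.18, 75.2), 89.38)
  expect_equal(combined_explained(64, 0), 64)
  expect_equal(combined_explained(100, 33), 100)
  expect_equal(combined_explained(0, 50), 50)
  expect_error(combined_explained(-1, 50), "input error")
  expect_error(combined_explained(57, 120), "input error")
})
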