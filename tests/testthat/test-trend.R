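make_obs <- function(vals, nr = 2, nc = 2, nt = 24) {
  g <- grid_create(nr, nc, 250)
  tm <- data.frame(year = rep(2001:(2000 + nt / 12), each = 12),
                   month = rep(1:12, nt / 12))
  raster_stack(g, array(vals, c(nr, nc, nt)), tm)
}

test_that("differencing broadcasts polygon predictions to pixels", {
  obs <- make_obs(stats::runif(2 * 2 * 24))
  part <- polygon_partition(obs$grid, matrix(c(1, 1, 2, 2), 2, 2))
  pred <- polygon_series(matrix(stats::rnorm(48), 2), 1:2, obs$time)

  # obs equal to the broadcast prediction -> all-zero residuals
  lab <- as.vector(part$labels)
  obs_eq <- make_obs(array(pred$values[lab, ], c(2, 2, 24)))
  expect_true(all(difference(obs_eq, pred, part)$values == 0))

  # shifting one polygon's prediction moves only that polygon's residuals
  d0 <- difference(obs, pred, part)
  pred2 <- pred; pred2$values[2, ] <- pred2$values[2, ] + 0.1
  d1 <- difference(obs, pred2, part)
  delta <- d1$values - d0$values
  expect_equal(max(abs(delta[part$labels == 2] + 0.1)), 0, tolerance = 1e-12)
  expect_true(all(delta[part$labels == 1] == 0))

  # nodata propagates
  obs$values[1, 1, 3] <- NA
  expect_true(is.na(difference(obs, pred, part)$values[1, 1, 3]))

  bad_pred <- polygon_series(pred$values, 1:2,
                             data.frame(year = obs$time$year + 1,
                                        month = obs$time$month))
  expect_error(difference(obs, bad_pred, part), "shape error")
  expect_error(difference(obs, polygon_series(pred$values[1, , drop = FALSE],
                                              1L, obs$time), part),
               "labeling error")
})

test_that("monthly Kendall S and its tie-corrected variance are exact", {
  expect_equal(mk_month(c(1, 2, 3)), list(S = 3L, var_S = 66 / 18, D = 3))
  expect_equal(mk_month(c(2, 2, 2))$S, 0L)
  expect_equal(mk_month(c(2, 2, 2))$var_S, 0)  # full tie correction
  mk <- mk_month(c(3, 1, 2, 5))
  expect_equal(mk_month(rev(c(3, 1, 2, 5)))$S, -mk$S)     # antisymmetry
  expect_equal(mk_month(rev(c(3, 1, 2, 5)))$var_S, mk$var_S)
  expect_equal(mk_month(c(1, NA))$S, 0L)                   # skipped month
  # tie correction: n=4 with one pair tied
  mk_t <- mk_month(c(1, 1, 2, 3))
  expect_equal(mk_t$var_S, (4 * 3 * 13 - 2 * 1 * 9) / 18)
})

test_that("seasonal Mann-Kendall matches its definition and symmetries", {
  yrs <- 10
  # strictly increasing within every month -> tau = 1
  x <- as.vector(vapply(1:yrs, function(y) stats::rnorm(12, mean = y, sd = 1e-6), numeric(12)))
  smk <- seasonal_mk(x)
  expect_equal(smk$tau, 1)
  expect_lt(smk$p_value, 1e-6)

  # translation invariance; positive scaling invariance
  set.seed(21)
  z <- stats::rnorm(120)
  base <- seasonal_mk(z)
  expect_equal(seasonal_mk(z + 5), base)
  expect_equal(seasonal_mk(3 * z)[c("S", "tau", "p_value")],
               base[c("S", "tau", "p_value")])
  expect_equal(sens_slope(3 * z)$beta, 3 * sens_slope(z)$beta)
  expect_equal(sens_slope(z + 5)$beta, sens_slope(z)$beta)

  # all data in one month equals the single-season test
  x5 <- c(0.3, 1.1, 0.2, 1.9, 1.4)
  one_month <- rep(NA_real_, 60); one_month[seq(1, 60, 12)] <- x5
  expect_equal(seasonal_mk(one_month), seasonal_mk(x5, period = 1))

  # degenerate: no variance -> no information
  expect_equal(seasonal_mk(rep(1, 36))$p_value, 1)
  expect_equal(seasonal_mk(rep(1, 36))$tau, 0)
})

test_that("normal-approximation p stays near the exact permutation p (n = 5)", {
  x5 <- c(0.3, 1.1, 0.2, 1.9, 1.4)
  S_of <- function(v) { d <- outer(v, v, "-"); sum(sign(d[lower.tri(d)])) }
  all_perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  null_S <- vapply(all_perms(x5), S_of, 0)         # all 120 orderings
  p_exact <- mean(abs(null_S) >= abs(S_of(x5)))
  expect_equal(seasonal_mk(x5, period = 1)$p_value, p_exact, tolerance = 0.06)
})

test_that("Sen's slope is the median of month-wise pairwise slopes", {
  # month across 3 years: pair slopes {0.1, 0.15, 0.2} -> median 0.15
  x <- rep(NA_real_, 36); x[c(1, 13, 25)] <- c(0.2, 0.3, 0.5)
  sl <- sens_slope(x)
  expect_equal(sl$beta_month[1], 0.15)
  expect_equal(sl$beta, 0.15)

  # twelve identical per-month slopes -> that slope overall
  x12 <- as.vector(vapply(1:3, function(y) rep(0.15 * y, 12), numeric(12)))
  expect_equal(sens_slope(x12)$beta, 0.15)
  expect_true(all(abs(sens_slope(x12)$beta_month - 0.15) < 1e-12))

  # exact line: beta equals the slope in every month and overall
  tt <- 0:119
  line <- 0.1 + 0.0123 * (tt / 12)
  sl <- sens_slope(line)
  expect_equal(sl$beta, 0.0123, tolerance = 1e-12)
  expect_true(all(abs(sl$beta_month - 0.0123) < 1e-12))

  expect_true(is.na(sens_slope(c(1, NA, 2), period = 3)$beta))
})

test_that("random series match the brute-force Sen oracle exactly", {
  set.seed(31)
  for (r in 1:60) {
    ny <- sample(3:6, 1)
    x <- round(stats::rnorm(ny * 12), 1)           # rounding induces ties
    x[sample(length(x), sample(0:6, 1))] <- NA
    expect_equal(sens_slope(x), oracle_sens(x))
  }
})

test_that("pixels classify by significance, sign and the extreme rule", {
  g <- grid_create(2, 3, 250)
  tr <- structure(list(
    grid = g,
    tau = raster_layer(g, matrix(c(0.4, -0.3, 0.05, 0.9, -0.8, NA), 2, 3)),
    p_value = raster_layer(g, matrix(c(0.05, 0.02, 0.5, 0.001, 0.001, NA), 2, 3)),
    period = 12), class = "dfrfa_trend")
  cls <- classify_trends(tr, alpha = 0.1, extreme = 0.6)
  expect_equal(cls$values[1, 1], 1)      # positive, significant -> under
  expect_equal(cls$values[2, 1], -1)     # negative, significant -> over
  expect_equal(cls$values[1, 2], 0)      # p = 0.5 -> none regardless of tau
  expect_equal(cls$values[2, 2], 2)      # |tau| above threshold -> extreme
  expect_equal(cls$values[1, 3], -2)
  expect_true(is.na(cls$values[2, 3]))

  # alpha = 0 -> everything none (p <= 0 never holds)
  cls0 <- classify_trends(tr, alpha = 1e-300)
  expect_true(all(cls0$values[!is.na(cls0$values)] == 0))

  # group-median rule splits each significant sign group in two
  set.seed(41)
  gg <- grid_create(10, 10, 250)
  tau <- matrix(stats::runif(100, -1, 1), 10)
  trg <- structure(list(grid = gg, tau = raster_layer(gg, tau),
                        p_value = raster_layer(gg, matrix(0.01, 10, 10)),
                        period = 12), class = "dfrfa_trend")
  clsg <- classify_trends(trg, alpha = 0.1)
  n_up <- sum(clsg$values > 0); n_up_ex <- sum(clsg$values == 2)
  expect_true(abs(n_up_ex - n_up / 2) <= 1)
})

test_that("landscape percentages close to 100 and report both complements", {
  g <- grid_create(10, 10, 250)
  vals <- matrix(0, 10, 10)
  vals[1:25] <- 1; vals[26:35] <- -1; vals[36:40] <- 2
  cls <- raster_layer(g, vals, "categorical",
                      codes = c(over_extreme = -2L, over_sig = -1L, none = 0L,
                                under_sig = 1L, under_extreme = 2L))
  s <- summarize_classes(cls)
  expect_equal(s$under_pct, 30)
  expect_equal(s$over_pct, 10)
  expect_equal(s$correct_pct, 60)
  expect_equal(sum(s$per_class$pct), 100, tolerance = 0.02)
  expect_equal(s$unexplained_pct, 40)
  expect_equal(s$changed_sum_pct, 40)

  all_none <- raster_layer(g, matrix(0, 10, 10), "categorical",
                           codes = c(none = 0L))
  expect_equal(summarize_classes(all_none)$correct_pct, 100)
  empty <- raster_layer(g, matrix(NA_real_, 10, 10))
  expect_error(summarize_classes(empty), "input error")
})

test_that("the trend surface runs per pixel and flags planted trends", {
  set.seed(51)
  nt <- 120
  g <- grid_create(4, 4, 250)
  arr <- array(stats::rnorm(16 * nt, 0, 0.05), c(4, 4, nt))
  tt <- (seq_len(nt) - 1) / 12
  arr[1, 1, ] <- arr[1, 1, ] + 0.02 * tt          # strong planted trend
  arr[4, 4, ] <- arr[4, 4, ] - 0.02 * tt
  tm <- data.frame(year = rep(2001:2010, each = 12), month = rep(1:12, 10))
  tr <- trend_surface(raster_stack(g, arr, tm))
  expect_lt(tr$p_value$values[1, 1], 0.01)
  expect_gt(tr$tau$values[1, 1], 0)
  expect_lt(tr$tau$values[4, 4], 0)
  expect_equal(tr$beta$values[1, 1], 0.02, tolerance = 0.3)
  # per-pixel results agree with the series-level functions
  expect_equal(tr$tau$values[2, 3], seasonal_mk(arr[2, 3, ])$tau)
  expect_equal(tr$beta$values[2, 3], sens_slope(arr[2, 3, ])$beta)
})
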