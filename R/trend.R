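## Residual trend surfaces: difference pixel-level observations from
## polygon-level model predictions, test every pixel's monthly residual
## series with the seasonal Mann-Kendall test, estimate the trend magnitude
## with the month-wise Sen's slope (median of pairwise slopes per month,
## then the median across months), and classify pixels by significance and
## sign at alpha = 0.1.

#' Pixel-minus-polygon residual stack
#'
#' Subtracts the polygon-level prediction (broadcast to the pixels of each
#' polygon) from the observed stack. Nodata in either operand propagates.
#'
#' @param obs A `dfrfa_stack` of observed values.
#' @param pred A `dfrfa_series` of polygon-level predictions.
#' @param partition A `dfrfa_partition` mapping pixels to polygons.
#' @return A `dfrfa_stack` of residuals d = obs - pred.
#' @export
difference <- function(obs, pred, partition) {
  if (!grid_identical(obs$grid, partition$grid))
    stop("shape error: observation and partition grids differ")
  if (!identical(time_labels(obs$time), time_labels(pred$time)))
    stop("shape error: time axes of observations and predictions differ")
  lab <- as.vector(partition$labels)
  row_of <- match(lab, pred$polygon_ids)
  if (any(is.na(row_of) & !is.na(lab)))
    stop("labeling error: partition label(s) absent from predictions: ",
         paste(setdiff(unique(lab[!is.na(lab)]), pred$polygon_ids), collapse = ", "))
  nt <- n_layers(obs)
  omat <- matrix(obs$values, ncol = nt)
  pmat <- pred$values[row_of, , drop = FALSE]   # NA rows where lab is NA
  raster_stack(obs$grid, array(omat - pmat, dim(obs$values)), obs$time)
}

#' Mann-Kendall statistic for a single month
#'
#' Kendall's S and its tie-corrected variance for one month's values across
#' years. Months with fewer than two non-missing years contribute 0 to both.
#'
#' @param x Numeric vector, one value per year (NA allowed).
#' @return List with `S` (integer), `var_S`, and `D` (tie-adjusted maximal
#'   pair count used in the seasonal tau denominator).
#' @export
mk_month <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) return(list(S = 0L, var_S = 0, D = 0))
  dif <- outer(x, x, "-")
  S <- sum(sign(dif[lower.tri(dif)]))    # [row > col] pairs: x_j - x_k, j > k
  t_e <- table(x)
  t_e <- t_e[t_e > 1]
  var_S <- (n * (n - 1) * (2 * n + 5) - sum(t_e * (t_e - 1) * (2 * t_e + 5))) / 18
  np <- n * (n - 1) / 2
  D <- sqrt((np - sum(t_e * (t_e - 1) / 2)) * np)   # time axis has no ties
  list(S = as.integer(S), var_S = var_S, D = D)
}

#' Seasonal Mann-Kendall test for a monthly series
#'
#' Computes Kendall's S within each season (month), sums S and its variance
#' across seasons (treated as independent; no serial-correlation
#' correction), applies the continuity correction, and returns the
#' tie-adjusted seasonal tau, the normal-approximation z and the two-sided
#' p-value.
#'
#' @param x Numeric vector in time order (month 1 of year 1 first); NA
#'   allowed. Length need not be a multiple of `period`.
#' @param period Number of seasons per year (12 for monthly data).
#' @return List with `S`, `var_S`, `tau`, `z`, `p_value`.
#' @export
seasonal_mk <- function(x, period = 12) {
  n_yr <- ceiling(length(x) / period)
  xm <- matrix(c(x, rep(NA, n_yr * period - length(x))), nrow = period)
  S <- 0L; v <- 0; D <- 0
  for (i in seq_len(period)) {
    mk <- mk_month(xm[i, ])
    S <- S + mk$S; v <- v + mk$var_S; D <- D + mk$D
  }
  if (v <= 0) return(list(S = S, var_S = v, tau = 0, z = 0, p_value = 1))
  z <- if (S == 0) 0 else (S - sign(S)) / sqrt(v)
  list(S = S, var_S = v, tau = if (D > 0) S / D else 0, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Sen's slope of a monthly series
#'
#' The median of pairwise slopes within each month
#' (`(x_ij - x_ik) / (j - k)` over year pairs j > k, units per year),
#' then the median of the per-month slopes across months. Months with
#' fewer than two non-missing years are excluded from the outer median.
#'
#' @inheritParams seasonal_mk
#' @return List with `beta` (overall slope, NA if no month qualifies) and
#'   `beta_month` (per-month slopes, NA where undefined).
#' @export
sens_slope <- function(x, period = 12) {
  n_yr <- ceiling(length(x) / period)
  xm <- matrix(c(x, rep(NA, n_yr * period - length(x))), nrow = period)
  beta_month <- rep(NA_real_, period)
  for (i in seq_len(period)) {
    ok <- which(!is.na(xm[i, ]))
    if (length(ok) < 2) next
    v <- xm[i, ok]
    num <- outer(v, v, "-")
    den <- outer(ok, ok, "-")
    beta_month[i] <- stats::median(num[lower.tri(num)] / den[lower.tri(den)])
  }
  list(beta = if (all(is.na(beta_month))) NA_real_ else
         stats::median(beta_month, na.rm = TRUE),
       beta_month = beta_month)
}

#' Per-pixel residual trend surface
#'
#' Runs [seasonal_mk()] and [sens_slope()] on every valid pixel of a
#' residual stack.
#'
#' @param residuals A `dfrfa_stack` (typically from [difference()]).
#' @param period Seasons per year.
#' @return A `dfrfa_trend` holding tau, p-value, z, S and Sen's beta
#'   rasters.
#' @export
trend_surface <- function(residuals, period = 12) {
  g <- residuals$grid
  nt <- n_layers(residuals)
  vmat <- matrix(residuals$values, ncol = nt)      # cells x T, column-major
  valid <- rowSums(!is.na(vmat)) >= 2
  out <- matrix(NA_real_, nrow(vmat), 5)
  colnames(out) <- c("tau", "p_value", "z", "S", "beta")
  for (cell in which(valid)) {
    xi <- vmat[cell, ]
    mk <- seasonal_mk(xi, period)
    sl <- sens_slope(xi, period)
    out[cell, ] <- c(mk$tau, mk$p_value, mk$z, mk$S, sl$beta)
  }
  shape <- function(col) raster_layer(g, matrix(out[, col], g$n_rows, g$n_cols))
  structure(list(grid = g,
                 tau = shape("tau"), p_value = shape("p_value"),
                 z = shape("z"), S = shape("S"), beta = shape("beta"),
                 period = period),
            class = "dfrfa_trend")
}

#' Classify pixels from the trend surface
#'
#' Pixels with `p > alpha` are `none`; significant pixels split by the sign
#' of tau into under-prediction (positive residual trend: observed greener
#' than predicted) and over-prediction (negative). Within each significant
#' sign group, pixels whose |tau| reaches the group's extreme threshold are
#' promoted to the extreme class. The default threshold is the group median
#' of |tau| (parameter-free four-way split); a fixed numeric threshold may
#' be supplied instead.
#'
#' Class codes: 0 none, 1 under_sig, 2 under_extreme, -1 over_sig,
#' -2 over_extreme.
#'
#' @param trend A `dfrfa_trend` from [trend_surface()].
#' @param alpha Significance level (paper default 0.1).
#' @param extreme `"group_median"` or a numeric |tau| threshold.
#' @return A categorical `dfrfa_raster` of class codes.
#' @export
classify_trends <- function(trend, alpha = 0.1, extreme = "group_median") {
  tau <- trend$tau$values; p <- trend$p_value$values
  cls <- matrix(0, nrow(tau), ncol(tau))
  cls[is.na(tau) | is.na(p)] <- NA
  sig_up <- !is.na(p) & p <= alpha & tau > 0
  sig_dn <- !is.na(p) & p <= alpha & tau < 0
  cls[sig_up] <- 1; cls[sig_dn] <- -1
  thr_up <- if (identical(extreme, "group_median"))
    stats::median(abs(tau[sig_up])) else extreme
  thr_dn <- if (identical(extreme, "group_median"))
    stats::median(abs(tau[sig_dn])) else extreme
  if (any(sig_up)) cls[sig_up & abs(tau) >= thr_up] <- 2
  if (any(sig_dn)) cls[sig_dn & abs(tau) >= thr_dn] <- -2
  raster_layer(trend$grid, cls, kind = "categorical",
               codes = c(over_extreme = -2L, over_sig = -1L, none = 0L,
                         under_sig = 1L, under_extreme = 2L))
}

#' Landscape accounting of the trend classification
#'
#' Percentages of valid pixels per class (2 decimals), plus the headline
#' aggregates: correctly predicted (`none`), under-predicted, over-predicted,
#' the under+over sum, and the 100 - correct complement (the two can differ
#' in the second decimal through rounding).
#'
#' @param class_raster Categorical raster from [classify_trends()].
#' @return List with `per_class` (data frame: class, n, pct) and
#'   `correct_pct`, `under_pct`, `over_pct`, `changed_sum_pct`,
#'   `unexplained_pct`.
#' @export
summarize_classes <- function(class_raster) {
  v <- class_raster$values[!is.na(class_raster$values)]
  if (length(v) == 0) stop("input error: zero valid pixels")
  codes <- class_raster$codes
  n <- vapply(codes, function(cd) sum(v == cd), 0)
  pct <- round(100 * n / length(v), 2)
  per_class <- data.frame(class = names(codes), code = unname(codes),
                          n = unname(n), pct = unname(pct))
  correct <- round(100 * sum(v == 0) / length(v), 2)
  under <- round(100 * sum(v > 0) / length(v), 2)
  over <- round(100 * sum(v < 0) / length(v), 2)
  list(per_class = per_class,
       correct_pct = correct, under_pct = under, over_pct = over,
       changed_sum_pct = round(under + over, 2),
       unexplained_pct = round(100 - correct, 2))
}
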