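# Shared fixtures: everything is generated in code at test time.

tiny_grid <- function(nr = 10, nc = 10, cell = 30) grid_create(nr, nc, cell)

# A desk-scale scene: 24 x 24 cells, 4 years -- enough structure for the
# pipeline stages while keeping disk round-trip tests fast.
tiny_scene_config <- function(seed = 1, n_years = 4, ...) {
  scene_config(n_rows = 24, n_cols = 24, n_years = n_years, seed = seed, ...)
}

tiny_pipeline_config <- function(seed = 1) {
  pipeline_config(scene = tiny_scene_config(seed),
                  dfa = list(m_trends = 1, tol = 1e-3, max_iter = 30),
                  rf = list(n_trees = 50, mtry = NULL, n_points = 25,
                            min_spacing = 0, seed = seed))
}

# independent brute-force Sen's slope: all pairs, then medians
oracle_sens <- function(x, period = 12) {
  n_yr <- ceiling(length(x) / period)
  xm <- matrix(c(x, rep(NA, n_yr * period - length(x))), nrow = period)
  bm <- rep(NA_real_, period)
  for (i in seq_len(period)) {
    v <- xm[i, ]; idx <- which(!is.na(v))
    if (length(idx) < 2) next
    s <- c()
    for (a in seq_along(idx)) for (b in seq_len(a - 1))
      s <- c(s, (v[idx[a]] - v[idx[b]]) / (idx[a] - idx[b]))
    bm[i] <- stats::median(s)
  }
  list(beta = if (all(is.na(bm))) NA_real_ else stats::median(bm, na.rm = TRUE),
       beta_month = bm)
}

# separable two-class feature table: one feature splits the classes cleanly,
# the rest are noise
separable_table <- function(n = 1000, n_noise = 4, seed = 1) {
  set.seed(seed)
  lab <- factor(rep(c("over", "under"), length.out = n))
  driver <- ifelse(lab == "under", 1, 0) + stats::rnorm(n, 0, 0.05)
  noise <- as.data.frame(matrix(stats::rnorm(n * n_noise), n))
  names(noise) <- paste0("noise_", seq_len(n_noise))
  cbind(data.frame(driver = driver), noise, data.frame(label = lab))
}
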