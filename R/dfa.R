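## Dynamic factor analysis: N observed monthly series explained by M
## random-walk common trends plus covariate regression terms,
##
##   y_t = mu + Gamma alpha_t + D x_t + eps_t,  eps_t ~ N(0, diag(R))
##   alpha_t = alpha_{t-1} + eta_t,             eta_t ~ N(0, I_M)
##
## identified by zeros strictly above the diagonal of Gamma and a
## non-negative Gamma diagonal. Estimated by EM; the E-step is a Kalman
## filter with sequential (univariate) measurement updates -- which makes
## missing observations free to handle -- followed by an RTS smoother.

#' Control settings for the DFA EM algorithm
#'
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum EM iterations.
#' @param prior_var Variance of the diffuse-ish N(0, prior_var I) prior on
#'   the trend state at t = 1.
#' @param var_floor Lower bound kept on observation variances.
#' @return A list of class `dfa_control`.
#' @export
dfa_control <- function(tol = 1e-6, max_iter = 2000, prior_var = 5,
                        var_floor = 1e-8) {
  stopifnot(tol > 0, max_iter >= 1, prior_var > 0)
  structure(list(tol = tol, max_iter = max_iter, prior_var = prior_var,
                 var_floor = var_floor), class = "dfa_control")
}

#' Standardize each series of a polygon series matrix
#'
#' Centers and scales every row to mean 0, sd 1 over its non-missing
#' entries, keeping the parameters for the back-transform.
#'
#' @param series A `dfrfa_series` or a plain numeric matrix (rows = series).
#' @return List with `values` (standardized matrix), `center`, `scale`.
#' @export
standardize_series <- function(series) {
  m <- if (inherits(series, "dfrfa_series")) series$values else as.matrix(series)
  ctr <- apply(m, 1, mean, na.rm = TRUE)
  scl <- apply(m, 1, stats::sd, na.rm = TRUE)
  nok <- rowSums(!is.na(m))
  bad <- which(nok < 2 | scl == 0 | !is.finite(scl))
  if (length(bad)) {
    ids <- if (inherits(series, "dfrfa_series")) series$polygon_ids[bad] else bad
    stop("degenerate-input error: constant or empty series for polygon(s) ",
         paste(ids, collapse = ", "))
  }
  list(values = (m - ctr) / scl, center = ctr, scale = scl)
}

## E-step: sequential Kalman filter + RTS smoother.
## Returns smoothed states (M x T), smoothed covariances (M x M x T) and the
## exact marginal log-likelihood from the prediction-error decomposition.
dfa_smoother <- function(y, x, mu, D, G, R, prior_var) {
  N <- nrow(y); T_ <- ncol(y); M <- ncol(G)
  reg <- mu + if (is.null(x)) 0 else D %*% x           # N x T fixed part
  if (length(reg) == N) reg <- matrix(reg, N, T_)
  a_f <- matrix(0, M, T_); P_f <- array(0, c(M, M, T_))
  a_p <- matrix(0, M, T_); P_p <- array(0, c(M, M, T_))
  ll <- 0
  a <- rep(0, M); P <- diag(prior_var, M)
  for (t in seq_len(T_)) {
    if (t > 1) P <- P + diag(1, M)
    a_p[, t] <- a; P_p[, , t] <- P
    for (i in which(!is.na(y[, t]))) {
      ci <- G[i, ]
      Pc <- P %*% ci
      q <- sum(ci * Pc) + R[i]
      v <- y[i, t] - reg[i, t] - sum(ci * a)
      ll <- ll - 0.5 * (log(2 * pi * q) + v * v / q)
      K <- Pc / q
      a <- a + K * v
      P <- P - tcrossprod(K, Pc)
    }
    P <- (P + t(P)) / 2
    a_f[, t] <- a; P_f[, , t] <- P
  }
  # RTS smoother
  a_s <- a_f; P_s <- P_f
  if (T_ > 1) {
    for (t in (T_ - 1):1) {
      J <- P_f[, , t] %*% solve(P_p[, , t + 1])
      a_s[, t] <- a_f[, t] + J %*% (a_s[, t + 1] - a_p[, t + 1])
      P_s[, , t] <- P_f[, , t] +
        J %*% (P_s[, , t + 1] - P_p[, , t + 1]) %*% t(J)
    }
  }
  list(states = a_s, state_var = P_s, loglik = ll)
}

ols_fit <- function(y, x) {
  # per-series least squares of y on x plus intercept; NA-tolerant
  N <- nrow(y); T_ <- ncol(y); K <- if (is.null(x)) 0 else nrow(x)
  X <- if (K) cbind(t(x), 1) else matrix(1, T_, 1)
  D <- matrix(0, N, K); mu <- numeric(N); R <- numeric(N)
  for (i in seq_len(N)) {
    obs <- which(!is.na(y[i, ]))
    fit <- stats::lm.fit(X[obs, , drop = FALSE], y[i, obs])
    cf <- fit$coefficients
    if (K) D[i, ] <- cf[seq_len(K)]
    mu[i] <- cf[K + 1]
    R[i] <- sum(fit$residuals^2) / length(obs)     # MLE variance
  }
  list(D = D, mu = mu, R = R)
}

#' Fit a dynamic factor model by EM
#'
#' Maximizes the Gaussian state-space likelihood of `m_trends` random-walk
#' common trends plus covariate effects (see the model statement in the
#' package vignette). The EM log-likelihood is non-decreasing at every
#' iteration; estimation stops when the change drops below `control$tol` or
#' after `control$max_iter` iterations. With `m_trends = 0` the model
#' reduces exactly to per-series least-squares regression of y on x.
#'
#' @param y N x T matrix of (standardized) response series; NA allowed.
#' @param x K x T matrix of covariate series, or NULL.
#' @param m_trends Number of common trends M (0 <= M < N).
#' @param control A [dfa_control()] list.
#' @param std Optional standardization parameters (from
#'   [standardize_series()]) stored for back-transforming predictions.
#' @param time Optional data frame (`year`, `month`) carried to predictions.
#' @param polygon_ids Optional polygon ids carried to predictions.
#' @return A `dfa_model` with loadings, coefficients, intercepts, smoothed
#'   states, observation variances, log-likelihood, AIC and the iteration
#'   trace.
#' @export
fit_dfa <- function(y, x = NULL, m_trends = 1, control = dfa_control(),
                    std = NULL, time = NULL, polygon_ids = NULL) {
  y <- as.matrix(y)
  N <- nrow(y); T_ <- ncol(y)
  K <- if (is.null(x)) 0L else nrow(x)
  if (m_trends >= N) stop("identifiability error: m_trends must be < n_series")
  if (T_ <= K + m_trends) stop("input error: need T > K + m_trends")
  if (!is.null(x) && ncol(x) != T_) stop("shape error: x and y time lengths differ")
  M <- as.integer(m_trends)

  init <- ols_fit(y, x)
  D <- init$D; mu <- init$mu; R <- pmax(init$R, control$var_floor)

  if (M == 0) {
    ll <- sum(vapply(seq_len(N), function(i) {
      obs <- !is.na(y[i, ])
      sum(stats::dnorm(y[i, obs],
                       mu[i] + if (K) drop(D[i, , drop = FALSE] %*% x[, obs]) else 0,
                       sqrt(R[i]), log = TRUE))
    }, 0))
    model <- list(loadings = matrix(0, N, 0), coefficients = D, intercepts = mu,
                  states = matrix(0, 0, T_), state_var = array(0, c(0, 0, T_)),
                  obs_var = R, loglik = ll, trace = ll,
                  convergence = list(iterations = 0L, delta = 0, converged = TRUE),
                  n_series = N, n_cov = K, m_trends = 0L, n_time = T_,
                  std = std, x = x, time = time, polygon_ids = polygon_ids)
    model$aic <- dfa_aic_value(ll, N, M, K)
    class(model) <- "dfa_model"
    return(model)
  }

  G <- matrix(0, N, M)
  for (j in seq_len(M)) G[j:N, j] <- 0.1      # zeros above the diagonal
  obs_idx <- lapply(seq_len(N), function(i) which(!is.na(y[i, ])))

  trace <- numeric(0)
  ll_old <- -Inf; delta <- Inf; it <- 0L
  sm <- NULL
  repeat {
    sm <- dfa_smoother(y, x, mu, D, G, R, control$prior_var)
    ll <- sm$loglik
    if (!is.finite(ll))
      stop("numerical error: non-finite likelihood at EM iteration ", it,
           " (trace: ", paste(signif(trace, 8), collapse = ", "), ")")
    trace <- c(trace, ll)
    delta <- ll - ll_old
    if (it >= control$max_iter || (it > 0 && abs(delta) < control$tol)) break
    ll_old <- ll
    it <- it + 1L

    at <- sm$states; Vt <- sm$state_var
    for (i in seq_len(N)) {
      obs <- obs_idx[[i]]
      Ji <- seq_len(min(i, M))                 # factors allowed for series i
      A <- at[Ji, obs, drop = FALSE]
      Vsum <- matrix(0, length(Ji), length(Ji))
      for (t in obs) Vsum <- Vsum + Vt[Ji, Ji, t]
      Xi <- if (K) t(x[, obs, drop = FALSE]) else NULL
      W <- cbind(t(A), Xi, 1)                  # T_i x (m_i + K + 1)
      Sww <- crossprod(W)
      Sww[seq_along(Ji), seq_along(Ji)] <- Sww[seq_along(Ji), seq_along(Ji)] + Vsum
      Swy <- crossprod(W, y[i, obs])
      beta <- solve(Sww, Swy)
      mJ <- length(Ji)
      G[i, ] <- 0; G[i, Ji] <- beta[seq_len(mJ)]
      if (K) D[i, ] <- beta[mJ + seq_len(K)]
      mu[i] <- beta[mJ + K + 1]
      sse <- sum(y[i, obs]^2) - 2 * sum(beta * Swy) +
        drop(t(beta) %*% Sww %*% beta)
      R[i] <- max(sse / length(obs), control$var_floor)
    }
  }

  # sign convention: non-negative loading diagonal (likelihood-invariant)
  at <- sm$states; Vt <- sm$state_var
  for (j in seq_len(M)) {
    if (G[j, j] < 0) {
      G[, j] <- -G[, j]
      at[j, ] <- -at[j, ]
      Vt[j, -j, ] <- -Vt[j, -j, , drop = FALSE]
      Vt[-j, j, ] <- -Vt[-j, j, , drop = FALSE]
    }
  }

  model <- list(loadings = G, coefficients = D, intercepts = mu,
                states = at, state_var = Vt, obs_var = R,
                loglik = trace[length(trace)], trace = trace,
                convergence = list(iterations = it, delta = delta,
                                   converged = abs(delta) < control$tol),
                n_series = N, n_cov = K, m_trends = M, n_time = T_,
                std = std, x = x, time = time, polygon_ids = polygon_ids)
  model$aic <- dfa_aic_value(model$loglik, N, M, K)
  class(model) <- "dfa_model"
  model
}

dfa_aic_value <- function(loglik, N, M, K) {
  p <- (N * M - M * (M - 1) / 2) + N * K + N + N   # loadings + D + mu + R
  -2 * loglik + 2 * p
}

#' @export
print.dfa_model <- function(x, ...) {
  cat(sprintf(paste0("Dynamic factor model: %d series, %d trend(s), %d ",
                     "covariate(s), T = %d\n"),
              x$n_series, x$m_trends, x$n_cov, x$n_time))
  cat(sprintf("  logLik %.4f  AIC %.2f  (%d EM iterations, %s)\n",
              x$loglik, x$aic, x$convergence$iterations,
              if (x$convergence$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' AIC of a fitted DFA model
#'
#' `-2 logLik + 2p`, where p counts the free loading entries
#' (`N M - M(M-1)/2` under the upper-triangle-zero constraint), the N x K
#' covariate coefficients, N intercepts and N observation variances.
#'
#' @param model A fitted `dfa_model`.
#' @return The AIC (numeric scalar).
#' @export
dfa_aic <- function(model) model$aic

#' Model predictions (fitted values) from a DFA fit
#'
#' Computes `mu + Gamma alpha_t + D x_t` on the standardized scale and, if
#' standardization parameters were stored, back-transforms to the original
#' NDVI scale.
#'
#' @param object A fitted `dfa_model`.
#' @param ... Unused.
#' @return A `dfrfa_series` if time metadata is present, else a matrix.
#' @export
predict.dfa_model <- function(object, ...) {
  if (is.null(object$loglik)) stop("state error: model not fitted")
  yhat <- matrix(object$intercepts, object$n_series, object$n_time)
  if (object$m_trends > 0) yhat <- yhat + object$loadings %*% object$states
  if (object$n_cov > 0) yhat <- yhat + object$coefficients %*% object$x
  if (!is.null(object$std))
    yhat <- yhat * object$std$scale + object$std$center
  if (!all(is.finite(yhat))) stop("numerical error: non-finite predictions")
  if (!is.null(object$time)) {
    ids <- if (is.null(object$polygon_ids)) seq_len(object$n_series) else
      object$polygon_ids
    polygon_series(yhat, ids, object$time)
  } else yhat
}

#' Fit candidate DFA models and select by AIC
#'
#' Fits every combination of trend count and covariate subset and returns
#' the minimum-AIC model; ties go to the model with fewer free parameters.
#'
#' @param y,x As in [fit_dfa()].
#' @param m_candidates Integer vector of trend counts to try.
#' @param covariate_subsets List of integer vectors of row indices into x
#'   (NULL = use all covariates for every candidate).
#' @param control A [dfa_control()].
#' @param ... Passed to [fit_dfa()].
#' @return The selected `dfa_model`, with a `selection` attribute listing
#'   every candidate's AIC.
#' @export
select_dfa <- function(y, x = NULL, m_candidates = 0:2,
                       covariate_subsets = NULL, control = dfa_control(), ...) {
  if (length(m_candidates) == 0) stop("input error: no candidates")
  subsets <- if (is.null(covariate_subsets)) {
    list(if (is.null(x)) integer(0) else seq_len(nrow(x)))
  } else covariate_subsets
  fits <- list(); tab <- NULL; failures <- character(0)
  for (m in m_candidates) for (s in seq_along(subsets)) {
    xi <- if (length(subsets[[s]])) x[subsets[[s]], , drop = FALSE] else NULL
    f <- tryCatch(fit_dfa(y, xi, m_trends = m, control = control, ...),
                  error = function(e) e)
    if (inherits(f, "error")) {
      failures <- c(failures, sprintf("m=%d subset=%d: %s", m, s,
                                      conditionMessage(f)))
      next
    }
    npar <- (nrow(y) * m - m * (m - 1) / 2) + nrow(y) * (length(subsets[[s]]) + 2)
    fits[[length(fits) + 1]] <- f
    tab <- rbind(tab, data.frame(m_trends = m, subset = s, n_par = npar,
                                 aic = f$aic))
  }
  if (is.null(tab))
    stop("all candidate fits failed:\n", paste(failures, collapse = "\n"))
  ord <- order(tab$aic, tab$n_par)
  best <- fits[[ord[1]]]
  attr(best, "selection") <- tab
  best
}

#' Simulate data from a dynamic factor model
#'
#' Draws covariates, random-walk trends and observations from the model
#' that [fit_dfa()] estimates; used for parameter-recovery checks.
#'
#' @param n_series,n_cov,m_trends,n_time Model dimensions.
#' @param params Optional list with `D`, `G`, `mu`, `R` (generated
#'   reproducibly if absent).
#' @param noise_sd Observation noise sd (overrides `params$R` if given).
#' @param seed Integer seed.
#' @return List with `y`, `x`, and the generating `params` (including the
#'   simulated `states`).
#' @export
simulate_dfa <- function(n_series, n_cov, m_trends, n_time, params = NULL,
                         noise_sd = NULL, seed = 1) {
  set.seed(seed)
  N <- n_series; K <- n_cov; M <- m_trends; T_ <- n_time
  if (is.null(params)) {
    G <- matrix(stats::runif(N * M, 0.2, 0.8), N, M)
    if (M > 0) for (j in seq_len(M)) if (j < N) G[seq_len(j - 1), j] <- 0
    params <- list(
      D = matrix(stats::runif(N * K, -1, 1), N, K),
      G = if (M > 0) G else matrix(0, N, 0),
      mu = stats::runif(N, -0.5, 0.5),
      R = rep(0.25, N))
  }
  if (!is.null(noise_sd)) params$R <- rep(noise_sd^2, N)
  x <- if (K > 0) matrix(stats::rnorm(K * T_), K, T_) else NULL
  states <- if (M > 0) apply(matrix(stats::rnorm(M * T_), M, T_), 1, cumsum) else NULL
  if (M > 0) states <- t(states)             # M x T
  y <- matrix(params$mu, N, T_) +
    (if (M > 0) params$G %*% states else 0) +
    (if (K > 0) params$D %*% x else 0) +
    matrix(stats::rnorm(N * T_, 0, sqrt(params$R)), N, T_)
  params$states <- states
  list(y = y, x = x, params = params)
}
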