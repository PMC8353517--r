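#' Fit a Gaussian mixture model by expectation-maximisation
#'
#' Full-covariance GMM in d dimensions, fitted by EM from a seeded k-means
#' initialisation. The per-iteration log-likelihood trace is recorded; EM
#' guarantees it is non-decreasing.
#'
#' @param X numeric matrix (n x d) of observations.
#' @param k number of mixture components.
#' @param seed integer seed for the initialisation.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood improves
#'   by less than `tol`, or after `max_iter` iterations.
#' @param reg ridge added to covariance diagonals to keep them positive
#'   definite on tight clusters.
#' @return list with `means` (k x d), `covs` (d x d x k), `weights`,
#'   `loglik` (trace), `k`.
#' @keywords internal
fit_gmm <- function(X, k, seed = 1L, max_iter = 200L, tol = 1e-8, reg = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- ncol(X)
  if (n < k) stop("need at least as many observations as components", call. = FALSE)
  set.seed(seed)
  if (k == 1L) {
    km_centers <- matrix(colMeans(X), 1L, d)
    cl <- rep(1L, n)
  } else {
    km <- suppressWarnings(stats::kmeans(X, centers = k, nstart = 10L, iter.max = 50L))
    km_centers <- km$centers
    cl <- km$cluster
  }
  means <- km_centers
  covs <- array(0, c(d, d, k))
  weights <- numeric(k)
  for (j in seq_len(k)) {
    idx <- which(cl == j)
    weights[j] <- length(idx) / n
    cv <- if (length(idx) > d) stats::cov(X[idx, , drop = FALSE]) else diag(d)
    covs[, , j] <- cv + diag(reg, d)
  }
  weights <- pmax(weights, 1e-8)
  weights <- weights / sum(weights)

  loglik <- numeric(0)
  for (it in seq_len(max_iter)) {
    logd <- vapply(
      seq_len(k),
      function(j) dmvnorm_log(X, means[j, ], covs[, , j]) + log(weights[j]),
      numeric(n)
    )
    lse <- logsumexp_rows(logd)
    ll <- sum(lse)
    loglik <- c(loglik, ll)
    resp <- exp(logd - lse)
    nk <- colSums(resp)
    weights <- nk / n
    for (j in seq_len(k)) {
      mu <- colSums(resp[, j] * X) / nk[j]
      xc <- sweep(X, 2L, mu)
      covs[, , j] <- crossprod(xc * sqrt(resp[, j])) / nk[j] + diag(reg, d)
      means[j, ] <- mu
    }
    if (it > 1L && abs(loglik[it] - loglik[it - 1L]) < tol) break
  }
  list(means = means, covs = covs, weights = weights, loglik = loglik, k = k)
}

# Per-component log joint density log(w_j) + log N(x; mu_j, S_j) for rows of X.
gmm_log_components <- function(model, X) {
  X <- as.matrix(X)
  vapply(
    seq_len(model$k),
    function(j) {
      dmvnorm_log(X, model$means[j, ], model$covs[, , j]) + log(model$weights[j])
    },
    numeric(nrow(X))
  )
}
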