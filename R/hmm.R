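#' Fit a Gaussian-emission hidden Markov model by Baum-Welch
#'
#' Multi-sequence Baum-Welch (EM) with full-covariance Gaussian emissions.
#' Forward-backward recursions are scaled per frame, with per-frame shifting
#' of the emission log-densities so distant observations do not underflow.
#' The total log-likelihood over all sequences is recorded per iteration and
#' is non-decreasing (EM guarantee).
#'
#' @param seqs list of numeric matrices (T_i x d), one observation sequence
#'   per matrix. Sequences shorter than 2 frames are excluded with a warning.
#' @param n_states number of hidden states.
#' @param seed seed for the emission initialisation (GMM on pooled frames).
#' @param max_iter,tol stopping rule on the log-likelihood improvement.
#' @param reg ridge added to emission covariance diagonals.
#' @return list with `transition` (row-stochastic), `initial`,
#'   `emission_means` (k x d), `emission_covs` (d x d x k), `loglik` trace,
#'   `n_states`.
#' @keywords internal
fit_hmm <- function(seqs, n_states, seed = 1L, max_iter = 100L, tol = 1e-6,
                    reg = 1e-6) {
  lens <- vapply(seqs, nrow, integer(1))
  if (any(lens < 2L)) {
    warning(sprintf("excluding %d sequence(s) shorter than 2 frames", sum(lens < 2L)))
    seqs <- seqs[lens >= 2L]
  }
  if (!length(seqs)) stop("no usable sequences", call. = FALSE)
  d <- ncol(seqs[[1L]])
  k <- n_states
  pooled <- do.call(rbind, seqs)
  init_gmm <- fit_gmm(pooled, k, seed = seed, max_iter = 50L, reg = reg)
  means <- init_gmm$means
  covs <- init_gmm$covs
  transition <- matrix((1 - 0.8) / max(k - 1L, 1L), k, k)
  diag(transition) <- if (k > 1L) 0.8 else 1
  initial <- rep(1 / k, k)

  loglik <- numeric(0)
  for (it in seq_len(max_iter)) {
    ll_total <- 0
    gamma_sum <- numeric(k)        # sum of state posteriors (all t)
    gamma_first <- numeric(k)      # posteriors at t = 1
    xi_sum <- matrix(0, k, k)      # expected transition counts
    mean_num <- matrix(0, k, d)
    cov_num <- array(0, c(d, d, k))
    for (s in seqs) {
      Tn <- nrow(s)
      logb <- vapply(seq_len(k), function(j) dmvnorm_log(s, means[j, ], covs[, , j]),
                     numeric(Tn))
      shift <- apply(logb, 1L, max)
      b <- exp(logb - shift)       # T x k, per-row scaled emissions
      alpha <- matrix(0, Tn, k)
      cvec <- numeric(Tn)
      a <- initial * b[1L, ]
      cvec[1L] <- sum(a)
      alpha[1L, ] <- a / cvec[1L]
      for (t in 2:Tn) {
        a <- as.numeric(crossprod(transition, alpha[t - 1L, ])) * b[t, ]
        cvec[t] <- sum(a)
        alpha[t, ] <- a / cvec[t]
      }
      beta <- matrix(0, Tn, k)
      beta[Tn, ] <- 1
      for (t in (Tn - 1L):1L) {
        beta[t, ] <- as.numeric(transition %*% (b[t + 1L, ] * beta[t + 1L, ])) / cvec[t + 1L]
      }
      gam <- alpha * beta
      gam <- gam / rowSums(gam)
      ll_total <- ll_total + sum(log(cvec)) + sum(shift)
      gamma_sum <- gamma_sum + colSums(gam)
      gamma_first <- gamma_first + gam[1L, ]
      for (t in seq_len(Tn - 1L)) {
        xi <- (alpha[t, ] %o% (b[t + 1L, ] * beta[t + 1L, ])) * transition / cvec[t + 1L]
        xi_sum <- xi_sum + xi
      }
      mean_num <- mean_num + t(gam) %*% s
      for (j in seq_len(k)) {
        xc <- sweep(s, 2L, means[j, ])
        cov_num[, , j] <- cov_num[, , j] + crossprod(xc * sqrt(gam[, j]))
      }
    }
    loglik <- c(loglik, ll_total)
    # M-step (covariances use the previous means; standard EM variant with
    # means updated first would need a second pass — recompute properly below)
    new_means <- mean_num / gamma_sum
    new_covs <- array(0, c(d, d, k))
    for (s in seqs) {
      # second pass for covariances about the NEW means
      Tn <- nrow(s)
      logb <- vapply(seq_len(k), function(j) dmvnorm_log(s, means[j, ], covs[, , j]),
                     numeric(Tn))
      shift <- apply(logb, 1L, max)
      b <- exp(logb - shift)
      alpha <- matrix(0, Tn, k)
      cvec <- numeric(Tn)
      a <- initial * b[1L, ]
      cvec[1L] <- sum(a)
      alpha[1L, ] <- a / cvec[1L]
      for (t in 2:Tn) {
        a <- as.numeric(crossprod(transition, alpha[t - 1L, ])) * b[t, ]
        cvec[t] <- sum(a)
        alpha[t, ] <- a / cvec[t]
      }
      beta <- matrix(0, Tn, k)
      beta[Tn, ] <- 1
      for (t in (Tn - 1L):1L) {
        beta[t, ] <- as.numeric(transition %*% (b[t + 1L, ] * beta[t + 1L, ])) / cvec[t + 1L]
      }
      gam <- alpha * beta
      gam <- gam / rowSums(gam)
      for (j in seq_len(k)) {
        xc <- sweep(s, 2L, new_means[j, ])
        new_covs[, , j] <- new_covs[, , j] + crossprod(xc * sqrt(gam[, j]))
      }
    }
    for (j in seq_len(k)) {
      new_covs[, , j] <- new_covs[, , j] / gamma_sum[j] + diag(reg, d)
    }
    initial <- gamma_first / sum(gamma_first)
    transition <- xi_sum / rowSums(xi_sum)
    means <- new_means
    covs <- new_covs
    if (it > 1L && abs(loglik[it] - loglik[it - 1L]) < tol) break
  }
  list(transition = transition, initial = initial, emission_means = means,
       emission_covs = covs, loglik = loglik, n_states = k)
}

# Most likely hidden-state path (Viterbi), log-space.
hmm_viterbi <- function(model, s) {
  k <- model$n_states
  Tn <- nrow(s)
  logb <- vapply(seq_len(k), function(j) {
    dmvnorm_log(s, model$emission_means[j, ], model$emission_covs[, , j])
  }, numeric(Tn))
  if (Tn == 1L) logb <- matrix(logb, 1L, k)
  logA <- log(pmax(model$transition, 1e-300))
  delta <- log(pmax(model$initial, 1e-300)) + logb[1L, ]
  psi <- matrix(0L, Tn, k)
  if (Tn > 1L) {
    for (t in 2:Tn) {
      cand <- delta + logA # k x k: from-state rows, to-state cols
      psi[t, ] <- apply(cand, 2L, which.max)
      delta <- apply(cand, 2L, max) + logb[t, ]
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta)
  if (Tn > 1L) {
    for (t in (Tn - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  }
  path
}

# Total log-likelihood of one sequence under the HMM (scaled forward pass).
hmm_loglik <- function(model, s) {
  k <- model$n_states
  Tn <- nrow(s)
  logb <- vapply(seq_len(k), function(j) {
    dmvnorm_log(s, model$emission_means[j, ], model$emission_covs[, , j])
  }, numeric(Tn))
  if (Tn == 1L) logb <- matrix(logb, 1L, k)
  shift <- apply(logb, 1L, max)
  b <- exp(logb - shift)
  a <- model$initial * b[1L, ]
  ll <- log(sum(a)) + shift[1L]
  alpha <- a / sum(a)
  if (Tn > 1L) {
    for (t in 2:Tn) {
      a <- as.numeric(crossprod(model$transition, alpha)) * b[t, ]
      ll <- ll + log(sum(a)) + shift[t]
      alpha <- a / sum(a)
    }
  }
  ll
}
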