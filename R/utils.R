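# Field dimensions in yards (Big Data Bowl coordinate frame: x along the full
# 120-yard length including both end zones, y across the 53.3-yard width).
FIELD_LENGTH <- 120
FIELD_WIDTH <- 53.3

#' Logistic (sigmoid) link
#'
#' Maps a raw classifier score \eqn{f(X)} to a completion probability
#' \eqn{P(y=1|X) = 1 / (1 + e^{-f(X)})}.
#'
#' @param z numeric vector of raw scores (logits).
#' @return probabilities in (0, 1).
#' @seealso [logit()] for the inverse.
#' @export
sigmoid <- function(z) stats::plogis(z)

#' Logit (inverse sigmoid)
#'
#' @param p probabilities in (0, 1).
#' @return raw scores such that `sigmoid(logit(p)) == p`.
#' @export
logit <- function(p) stats::qlogis(p)

# Row-wise log-sum-exp of a matrix of log-weights.
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Log-density of rows of X (n x d) under a multivariate Gaussian.
dmvnorm_log <- function(X, mean, sigma) {
  d <- length(mean)
  ch <- chol(sigma)
  cx <- t(X) - mean
  z <- backsolve(ch, cx, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a stream of child seeds from one user-facing seed; kept below 2^31.
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 104729L * seq_len(n)) %% 2147483629L
}

stop_play <- function(play, msg) {
  stop(sprintf("play %s/%s: %s", play$game_id, play$play_id, msg), call. = FALSE)
}
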