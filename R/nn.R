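# Minimal batched neural-network primitives: a feed-forward classifier with
# batch normalization + dropout, and a multi-layer LSTM regressor, both
# trained with Adam. Written as plain matrix code (columns = batch) so the
# backward passes can be verified against numerical gradients.

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = rapply(params, function(p) p * 0, how = "replace"),
       v = rapply(params, function(p) p * 0, how = "replace"),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
  }
  out <- Map(walk, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = t))
}

# ---- Feed-forward classifier ----------------------------------------------

# Hidden layers with batch normalization and ReLU; dropout after the layers
# listed in `dropout_layers`; linear head producing one logit per column.
mlp_init <- function(input_dim, hidden = c(64, 64, 32), dropout = 0.3,
                     dropout_layers = c(1L, 2L), seed = 1L) {
  set.seed(seed)
  dims <- c(input_dim, hidden)
  layers <- lapply(seq_along(hidden), function(l) {
    fan_in <- dims[l]
    list(
      W = matrix(stats::rnorm(hidden[l] * fan_in, 0, sqrt(2 / fan_in)), hidden[l], fan_in),
      b = numeric(hidden[l]),
      gamma = rep(1, hidden[l]),
      beta = numeric(hidden[l])
    )
  })
  head <- list(
    W = matrix(stats::rnorm(hidden[length(hidden)], 0, sqrt(1 / hidden[length(hidden)])),
               1, hidden[length(hidden)]),
    b = 0
  )
  run <- lapply(hidden, function(h) list(mu = numeric(h), var = rep(1, h)))
  list(params = list(layers = layers, head = head), run = run,
       dropout = dropout, dropout_layers = dropout_layers, bn_eps = 1e-5)
}

# Forward pass. X: (d x B). In training mode batch statistics are used and
# cached; in inference mode the running statistics are used.
mlp_forward <- function(net, params, X, train = FALSE, drop_masks = NULL,
                        update_run = FALSE) {
  cache <- list(X = X, layers = list())
  a <- X
  B <- ncol(X)
  for (l in seq_along(params$layers)) {
    ly <- params$layers[[l]]
    z <- ly$W %*% a + ly$b
    if (train) {
      mu <- rowMeans(z)
      v <- rowMeans((z - mu)^2)
      if (update_run) {
        net$run[[l]]$mu <- 0.9 * net$run[[l]]$mu + 0.1 * mu
        net$run[[l]]$var <- 0.9 * net$run[[l]]$var + 0.1 * v * B / max(B - 1, 1)
      }
    } else {
      mu <- net$run[[l]]$mu
      v <- net$run[[l]]$var
    }
    istd <- 1 / sqrt(v + net$bn_eps)
    zhat <- (z - mu) * istd
    h <- ly$gamma * zhat + ly$beta
    h <- pmax(h, 0)
    relu_mask <- h > 0
    dmask <- NULL
    if (train && l %in% net$dropout_layers && net$dropout > 0) {
      dmask <- if (!is.null(drop_masks)) drop_masks[[l]] else {
        matrix(stats::runif(length(h)) >= net$dropout, nrow(h), ncol(h))
      }
      h <- h * dmask / (1 - net$dropout)
    }
    cache$layers[[l]] <- list(a_in = a, z = z, mu = mu, v = v, istd = istd,
                              zhat = zhat, relu = relu_mask, dmask = dmask)
    a <- h
  }
  f <- as.numeric(params$head$W %*% a + params$head$b)
  cache$a_last <- a
  list(logits = f, cache = cache, net = net)
}

# Backward pass for binary cross-entropy on the logits.
mlp_backward <- function(net, params, cache, logits, y) {
  B <- length(y)
  df <- matrix((sigmoid(logits) - y) / B, 1, B)
  g_head <- list(W = df %*% t(cache$a_last), b = sum(df))
  da <- t(params$head$W) %*% df
  g_layers <- vector("list", length(params$layers))
  for (l in rev(seq_along(params$layers))) {
    cc <- cache$layers[[l]]
    ly <- params$layers[[l]]
    if (!is.null(cc$dmask)) da <- da * cc$dmask / (1 - net$dropout)
    dh <- da * cc$relu
    dgamma <- rowSums(dh * cc$zhat)
    dbeta <- rowSums(dh)
    dzhat <- dh * ly$gamma
    Bn <- ncol(dh)
    zc <- cc$z - cc$mu
    dvar <- rowSums(dzhat * zc) * (-0.5) * cc$istd^3
    dmu <- -rowSums(dzhat) * cc$istd + dvar * rowMeans(-2 * zc)
    dz <- dzhat * cc$istd + dvar * 2 * zc / Bn + dmu / Bn
    g_layers[[l]] <- list(W = dz %*% t(cc$a_in), b = rowSums(dz),
                          gamma = dgamma, beta = dbeta)
    da <- t(ly$W) %*% dz
  }
  list(layers = g_layers, head = g_head)
}

bce_loss <- function(logits, y) {
  mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
}

# ---- LSTM regressor --------------------------------------------------------

# Stacked LSTM with a linear head. Gate rows are blocked [i; f; g; o].
lstm_init <- function(input_dim, hidden = 128L, n_layers = 2L, out_dim = 2L,
                      seed = 1L) {
  set.seed(seed)
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    d_in <- if (l == 1L) input_dim else hidden
    sd <- sqrt(1 / (d_in + hidden))
    b <- numeric(4L * hidden)
    b[(hidden + 1L):(2L * hidden)] <- 1 # forget-gate bias
    layers[[l]] <- list(
      W = matrix(stats::rnorm(4L * hidden * (d_in + hidden), 0, sd),
                 4L * hidden, d_in + hidden),
      b = b
    )
  }
  head <- list(W = matrix(stats::rnorm(out_dim * hidden, 0, sqrt(1 / hidden)),
                          out_dim, hidden),
               b = numeric(out_dim))
  list(params = list(layers = layers, head = head),
       hidden = as.integer(hidden), n_layers = as.integer(n_layers),
       input_dim = as.integer(input_dim), out_dim = as.integer(out_dim))
}

lstm_zero_state <- function(net, B) {
  lapply(seq_len(net$n_layers), function(l) {
    list(h = matrix(0, net$hidden, B), c = matrix(0, net$hidden, B))
  })
}

# One timestep through all layers. Returns output, new state and the cell
# cache needed for BPTT.
lstm_step <- function(net, params, x, state, want_cache = FALSE) {
  H <- net$hidden
  caches <- if (want_cache) vector("list", net$n_layers) else NULL
  a <- x
  for (l in seq_len(net$n_layers)) {
    st <- state[[l]]
    zin <- rbind(a, st$h)
    pre <- params$layers[[l]]$W %*% zin + params$layers[[l]]$b
    i <- sigmoid(pre[1:H, , drop = FALSE])
    f <- sigmoid(pre[(H + 1):(2 * H), , drop = FALSE])
    g <- tanh(pre[(2 * H + 1):(3 * H), , drop = FALSE])
    o <- sigmoid(pre[(3 * H + 1):(4 * H), , drop = FALSE])
    cc <- f * st$c + i * g
    tc <- tanh(cc)
    h <- o * tc
    if (want_cache) {
      caches[[l]] <- list(zin = zin, i = i, f = f, g = g, o = o,
                          c_prev = st$c, c = cc, tc = tc)
    }
    state[[l]] <- list(h = h, c = cc)
    a <- h
  }
  y <- params$head$W %*% a + params$head$b
  list(y = y, state = state, caches = caches, h_top = a)
}

# Full forward over a (D x B x T) input tensor.
lstm_forward <- function(net, params, X, want_cache = FALSE) {
  Tn <- dim(X)[3]
  B <- dim(X)[2]
  state <- lstm_zero_state(net, B)
  Y <- array(0, c(net$out_dim, B, Tn))
  caches <- if (want_cache) vector("list", Tn) else NULL
  tops <- if (want_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    xt <- matrix(X[, , t], dim(X)[1], B)
    out <- lstm_step(net, params, xt, state, want_cache = want_cache)
    Y[, , t] <- out$y
    if (want_cache) {
      caches[[t]] <- out$caches
      tops[[t]] <- out$h_top
    }
    state <- out$state
  }
  list(Y = Y, caches = caches, tops = tops)
}

# Masked MSE loss and its gradient wrt the outputs. mask: (B x T) with 1 for
# frames that carry a target.
lstm_mse <- function(Y, target, mask) {
  diff <- Y - target
  w <- array(rep(mask, each = dim(Y)[1]), dim(Y))
  n <- sum(w)
  list(loss = sum(w * diff^2) / n, dY = 2 * w * diff / n)
}

# Backpropagation through time. Returns grads matching the params structure.
lstm_backward <- function(net, params, X, fwd, dY) {
  H <- net$hidden
  Tn <- dim(X)[3]
  B <- dim(X)[2]
  gW_head <- matrix(0, net$out_dim, H)
  gb_head <- numeric(net$out_dim)
  g_layers <- lapply(params$layers, function(ly) list(W = ly$W * 0, b = ly$b * 0))
  dh_next <- lapply(seq_len(net$n_layers), function(l) matrix(0, H, B))
  dc_next <- lapply(seq_len(net$n_layers), function(l) matrix(0, H, B))
  headW <- params$head$W
  for (t in Tn:1) {
    dy <- matrix(dY[, , t], net$out_dim, B)
    gW_head <- gW_head + dy %*% t(fwd$tops[[t]])
    gb_head <- gb_head + rowSums(dy)
    d_from_above <- t(headW) %*% dy
    for (l in net$n_layers:1) {
      cc <- fwd$caches[[t]][[l]]
      dh <- dh_next[[l]] + d_from_above
      dc <- dc_next[[l]] + dh * cc$o * (1 - cc$tc^2)
      do <- dh * cc$tc
      di <- dc * cc$g
      dg <- dc * cc$i
      df <- dc * cc$c_prev
      dc_next[[l]] <- dc * cc$f
      da <- rbind(
        di * cc$i * (1 - cc$i),
        df * cc$f * (1 - cc$f),
        dg * (1 - cc$g^2),
        do * cc$o * (1 - cc$o)
      )
      g_layers[[l]]$W <- g_layers[[l]]$W + da %*% t(cc$zin)
      g_layers[[l]]$b <- g_layers[[l]]$b + rowSums(da)
      dzin <- t(params$layers[[l]]$W) %*% da
      d_in <- nrow(cc$zin) - H
      d_from_above <- dzin[seq_len(d_in), , drop = FALSE]
      dh_next[[l]] <- dzin[(d_in + 1):(d_in + H), , drop = FALSE]
    }
  }
  list(layers = g_layers, head = list(W = gW_head, b = gb_head))
}

# Fit the LSTM on a list of (X, target, mask) batches with Adam.
# Returns the net with updated params and the per-epoch loss trace.
lstm_fit <- function(net, batches, epochs, lr = 2e-3, seed = 1L,
                     adam_state = NULL) {
  set.seed(seed)
  state <- adam_state %||% adam_init(net$params)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    total <- 0
    wsum <- 0
    for (bi in sample(seq_along(batches))) {
      b <- batches[[bi]]
      fwd <- lstm_forward(net, net$params, b$X, want_cache = TRUE)
      ls <- lstm_mse(fwd$Y, b$target, b$mask)
      grads <- lstm_backward(net, net$params, b$X, fwd, ls$dY)
      upd <- adam_step(net$params, grads, state, lr)
      net$params <- upd$params
      state <- upd$state
      nb <- sum(b$mask)
      total <- total + ls$loss * nb
      wsum <- wsum + nb
    }
    trace[ep] <- total / wsum
  }
  net$adam_state <- state
  net$loss_trace <- c(net$loss_trace, trace)
  net
}
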