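# Feature vector layout: five 13-entry receiver blocks, then a 3-entry QB
# block, then a 3-entry meta block (71 features total). Each receiver block
# is (x', y', speed) of the receiver followed by, for each of its two nearest
# defenders (nearer first), the defender's absolute position, position
# relative to the receiver, and speed.
RECEIVER_BLOCK_LEN <- 13L
N_RECEIVER_BLOCKS <- 5L
PASS_FEATURE_LEN <- N_RECEIVER_BLOCKS * RECEIVER_BLOCK_LEN + 3L + 3L

receiver_block_cols <- function(k) ((k - 1L) * RECEIVER_BLOCK_LEN + 1L):(k * RECEIVER_BLOCK_LEN)

#' Build the formation feature vector at the pass event
#'
#' Encodes the full formation at the `pass_forward` frame of a normalized
#' play: per receiver, its position and speed plus the absolute position,
#' receiver-relative position and speed of its two nearest defenders
#' (Euclidean distance at the pass frame, nearer first, ties broken by
#' entity id ascending; defenders may repeat across blocks); the quarterback
#' position and speed as a separate block; and the game-state block
#' (distance to the end zone, down, yards to go).
#'
#' @param play a normalized `gh_play` with 7 defenders and 6 offensive
#'   players.
#' @param frame_idx index on the play's frame grid at which to evaluate;
#'   defaults to the `pass_forward` frame.
#' @param receiver_order optional permutation of 1:5 fixing the receiver
#'   block order (e.g. from a receiver role model); default is roster order.
#' @return numeric vector of length 71 with named entries.
#' @export
build_feature_vector <- function(play, frame_idx = NULL, receiver_order = NULL) {
  if (!isTRUE(play$normalized)) stop_play(play, "play must be normalized")
  if (is.null(frame_idx)) {
    frame_idx <- event_index(play, "pass_forward")
    if (is.na(frame_idx)) stop_play(play, "no pass_forward frame")
  }
  rids <- receiver_ids(play)
  dids <- defense_ids(play)
  if (length(rids) != 5L || length(dids) != 7L) {
    stop_play(play, "feature vector requires 5 receivers and 7 defenders")
  }
  if (!is.null(receiver_order)) rids <- rids[receiver_order]
  rj <- match(rids, play$roster$entity_id)
  dj <- match(dids, play$roster$entity_id)
  rx <- play$x[frame_idx, rj]; ry <- play$y[frame_idx, rj]; rs <- play$s[frame_idx, rj]
  dx <- play$x[frame_idx, dj]; dy <- play$y[frame_idx, dj]; ds <- play$s[frame_idx, dj]
  out <- numeric(PASS_FEATURE_LEN)
  nms <- character(PASS_FEATURE_LEN)
  for (k in 1:5) {
    dist <- sqrt((dx - rx[k])^2 + (dy - ry[k])^2)
    near <- order(dist, dids)[1:2] # ties broken by entity id ascending
    block <- c(rx[k], ry[k], rs[k],
               dx[near[1]], dy[near[1]], dx[near[1]] - rx[k], dy[near[1]] - ry[k], ds[near[1]],
               dx[near[2]], dy[near[2]], dx[near[2]] - rx[k], dy[near[2]] - ry[k], ds[near[2]])
    out[receiver_block_cols(k)] <- block
    nms[receiver_block_cols(k)] <- paste0(
      "r", k, "_", c("x", "y", "s", "d1x", "d1y", "d1rx", "d1ry", "d1s",
                     "d2x", "d2y", "d2rx", "d2ry", "d2s")
    )
  }
  qj <- match(qb_id(play), play$roster$entity_id)
  qcols <- (N_RECEIVER_BLOCKS * RECEIVER_BLOCK_LEN + 1L):(N_RECEIVER_BLOCKS * RECEIVER_BLOCK_LEN + 3L)
  out[qcols] <- c(play$x[frame_idx, qj], play$y[frame_idx, qj], play$s[frame_idx, qj])
  nms[qcols] <- c("qb_x", "qb_y", "qb_s")
  mcols <- (PASS_FEATURE_LEN - 2L):PASS_FEATURE_LEN
  out[mcols] <- c(play$meta$absolute_field_position, play$meta$down, play$meta$yards_to_go)
  nms[mcols] <- c("field_position", "down", "yards_to_go")
  names(out) <- nms
  out
}

#' Build a pass-completion dataset from a collection
#'
#' Normalizes each play, builds the feature vector at the pass frame and the
#' binary label (1 = complete; incomplete and intercepted are negatives).
#'
#' @param collection a filtered `gh_collection`.
#' @return list with `X` (n x 71 matrix) and `y` (0/1 integer vector).
#' @export
build_pass_dataset <- function(collection) {
  plays <- as_play_list(collection)
  X <- t(vapply(plays, function(p) build_feature_vector(normalize_play(p)),
                numeric(PASS_FEATURE_LEN)))
  y <- vapply(plays, function(p) {
    as.integer(identical(p$meta$pass_outcome, "complete"))
  }, integer(1))
  list(X = X, y = y)
}

#' Permute the receiver blocks of feature vectors
#'
#' Reorders the five receiver blocks by a permutation; the QB and meta blocks
#' are untouched. With `perm = NULL`, one uniform-random permutation is drawn
#' per row under the seed (the augmentation used to make training order
#' invariant).
#'
#' @param X feature matrix (n x 71) or a single length-71 vector.
#' @param perm explicit permutation of 1:5, or NULL for seeded random
#'   per-row permutations.
#' @param seed seed used when `perm` is NULL.
#' @return the permuted matrix/vector.
#' @export
permute_receivers <- function(X, perm = NULL, seed = 1L) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, 1L, dimnames = list(NULL, names(X)))
  stopifnot(ncol(X) == PASS_FEATURE_LEN)
  out <- X
  if (!is.null(perm)) {
    stopifnot(length(perm) == 5L, sort(perm) == 1:5)
    for (k in 1:5) out[, receiver_block_cols(k)] <- X[, receiver_block_cols(perm[k])]
  } else {
    set.seed(seed)
    for (i in seq_len(nrow(X))) {
      p <- sample.int(5L)
      for (k in 1:5) out[i, receiver_block_cols(k)] <- X[i, receiver_block_cols(p[k])]
    }
  }
  if (vec) out[1L, ] else out
}

#' Classifier configuration
#'
#' Hyperparameters for the completion classifiers: a feed-forward network
#' (three hidden layers 64/64/32 with batch normalization, dropout 0.3 after
#' the first two, Adam at learning rate 2e-3, batch size 1024) or gradient
#' boosted trees (maximum depth 10, 60 leaves, learning rate 0.03).
#'
#' @param backend `"nn"` or `"gbt"`.
#' @param augment permute receiver blocks during training (each epoch for
#'   the network; replicated permuted copies for the trees).
#' @param seed training seed.
#' @param epochs,patience network stopping rule: early stop when validation
#'   loss fails to improve for `patience` epochs, up to `epochs`.
#' @param lr,batch_size,hidden,dropout network hyperparameters.
#' @param nrounds,gbt_augment_copies tree hyperparameters; augmentation
#'   replicates the training rows under that many receiver permutations.
#' @param cv_folds stratified folds for [cross_validate_classifier()].
#' @param val_frac fraction of the training data held out (stratified) for
#'   early stopping and score recalibration.
#' @param calibrate recalibrate the raw score on the held-out validation
#'   split (spline-logistic map with enough data, affine Platt scaling
#'   otherwise) so predicted probabilities match observed frequencies; the
#'   sigmoid/logit score contract is preserved.
#' @return a `gh_classifier_config`.
#' @export
classifier_config <- function(backend = c("nn", "gbt"), augment = TRUE, seed = 1L,
                              epochs = 200L, patience = 10L, lr = 2e-3,
                              batch_size = 1024L, hidden = c(64L, 64L, 32L),
                              dropout = 0.3, nrounds = 400L,
                              gbt_augment_copies = 8L, cv_folds = 7L,
                              val_frac = 0.15, calibrate = TRUE) {
  backend <- match.arg(backend)
  stopifnot(epochs > 0, lr > 0, batch_size > 0, all(hidden > 0), nrounds > 0,
            cv_folds > 0, dropout >= 0, dropout < 1)
  structure(
    list(backend = backend, augment = augment, seed = as.integer(seed),
         epochs = as.integer(epochs), patience = as.integer(patience), lr = lr,
         batch_size = as.integer(batch_size), hidden = as.integer(hidden),
         dropout = dropout, nrounds = as.integer(nrounds),
         gbt_augment_copies = as.integer(gbt_augment_copies),
         cv_folds = as.integer(cv_folds), val_frac = val_frac,
         calibrate = isTRUE(calibrate)),
    class = "gh_classifier_config"
  )
}

#' Train a pass-completion classifier
#'
#' Fits the configured backend on feature vectors and binary labels. With
#' `augment = TRUE`, the network sees an independent random receiver-block
#' permutation of every sample each epoch; the tree backend trains on the
#' data plus `gbt_augment_copies` permuted replicates. Training is
#' deterministic given (data, config).
#'
#' @param X feature matrix (n x 71).
#' @param y binary labels.
#' @param config a [classifier_config()].
#' @return a `gh_classifier` with a training manifest.
#' @export
train_classifier <- function(X, y, config = classifier_config()) {
  stopifnot(nrow(X) == length(y))
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("training data has a single class", call. = FALSE)
  model <- if (config$backend == "nn") {
    train_nn_backend(X, y, config)
  } else {
    train_gbt_backend(X, y, config)
  }
  manifest <- list(
    backend = config$backend, augment = config$augment, seed = config$seed,
    n = nrow(X), n_features = ncol(X),
    data_hash = digest_numeric(c(X, y))
  )
  structure(list(backend = config$backend, fit = model, config = config,
                 manifest = manifest),
            class = "gh_classifier")
}

digest_numeric <- function(v) {
  # order-sensitive 64-bit-ish rolling hash; enough to fingerprint a dataset
  v <- as.numeric(v)
  h <- 0
  chunks <- split(v, ceiling(seq_along(v) / 4096))
  for (ch in chunks) {
    h <- (h * 31 + sum(ch * seq_along(ch))) %% 9007199254740881
  }
  sprintf("%.0f", h)
}

# Score recalibration fitted on held-out (score, label) pairs. With enough
# validation data a smooth spline-logistic map (natural cubic spline, 3 df)
# corrects the curved miscalibration typical of boosted trees; smaller sets
# fall back to affine Platt scaling; degenerate sets to the identity.
# Returns a list consumed by calibration_apply().
calibration_fit <- function(f, y) {
  if (length(unique(y)) < 2L || stats::sd(f) < 1e-8) {
    return(list(type = "affine", coef = c(0, 1)))
  }
  if (length(y) >= 100L && min(table(y)) >= 20L) {
    sp <- splines::ns(f, df = 3L)
    fit <- suppressWarnings(stats::glm(y ~ sp, family = stats::binomial()))
    co <- stats::coef(fit)
    if (all(is.finite(co))) {
      return(list(type = "spline", basis = sp, coef = unname(co)))
    }
  }
  fit <- suppressWarnings(stats::glm(y ~ f, family = stats::binomial()))
  co <- stats::coef(fit)
  if (!all(is.finite(co))) return(list(type = "affine", coef = c(0, 1)))
  list(type = "affine", coef = unname(co))
}

# Map raw scores to calibrated scores (logits).
calibration_apply <- function(cal, f) {
  if (is.null(cal)) return(f)
  if (identical(cal$type, "spline")) {
    as.numeric(cbind(1, stats::predict(cal$basis, f)) %*% cal$coef)
  } else {
    cal$coef[1] + cal$coef[2] * f
  }
}

stratified_split <- function(y, frac, seed) {
  set.seed(seed)
  hold <- integer(0)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n_h <- max(1L, floor(length(idx) * frac))
    hold <- c(hold, sample(idx, n_h))
  }
  sort(hold)
}

train_nn_backend <- function(X, y, config) {
  set.seed(config$seed)
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd < 1e-8] <- 1
  val <- stratified_split(y, config$val_frac, config$seed + 1L)
  tr <- setdiff(seq_len(nrow(X)), val)
  scale_rows <- function(M) t((t(M) - mu) / sd)
  net <- mlp_init(ncol(X), hidden = config$hidden, dropout = config$dropout,
                  seed = config$seed)
  state <- adam_init(net$params)
  Xva <- scale_rows(permute_or_not(X[val, , drop = FALSE], config, config$seed + 2L))
  yva <- y[val]
  best <- list(loss = Inf, params = net$params, run = net$run, epoch = 0L)
  bad <- 0L
  trace <- numeric(0)
  for (ep in seq_len(config$epochs)) {
    Xep <- permute_or_not(X[tr, , drop = FALSE], config, config$seed + 100L + ep)
    Xep <- scale_rows(Xep)
    idx <- sample(length(tr))
    starts <- seq(1L, length(tr), by = config$batch_size)
    ep_loss <- 0
    for (st in starts) {
      take <- idx[st:min(st + config$batch_size - 1L, length(tr))]
      if (length(take) < 2L) next # batch norm needs >= 2 samples
      xb <- t(Xep[take, , drop = FALSE])
      yb <- y[tr][take]
      fw <- mlp_forward(net, net$params, xb, train = TRUE, update_run = TRUE)
      net <- fw$net
      grads <- mlp_backward(net, net$params, fw$cache, fw$logits, yb)
      upd <- adam_step(net$params, grads, state, config$lr)
      net$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + bce_loss(fw$logits, yb) * length(take)
    }
    val_logits <- mlp_forward(net, net$params, t(Xva), train = FALSE)$logits
    vloss <- bce_loss(val_logits, yva)
    trace <- c(trace, vloss)
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, params = net$params, run = net$run, epoch = ep)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= config$patience) break
    }
  }
  net$params <- best$params
  net$run <- best$run
  calibration <- NULL
  if (config$calibrate) {
    f_val <- mlp_forward(net, net$params, t(Xva), train = FALSE)$logits
    calibration <- calibration_fit(f_val, yva)
  }
  list(net = net, mu = mu, sd = sd, val_loss_trace = trace,
       best_epoch = best$epoch, calibration = calibration)
}

permute_or_not <- function(X, config, seed) {
  if (config$augment) permute_receivers(X, seed = seed) else X
}

train_gbt_backend <- function(X, y, config) {
  # hold out validation rows BEFORE augmentation so no permuted copy of a
  # training formation leaks into early stopping or calibration
  val <- stratified_split(y, config$val_frac, config$seed + 1L)
  tr <- setdiff(seq_len(nrow(X)), val)
  Xtr <- X[tr, , drop = FALSE]
  ytr_lab <- y[tr]
  if (config$augment && config$gbt_augment_copies > 0L) {
    for (cp in seq_len(config$gbt_augment_copies)) {
      Xtr <- rbind(Xtr, permute_receivers(X[tr, , drop = FALSE],
                                          seed = config$seed + 1000L + cp))
      ytr_lab <- c(ytr_lab, y[tr])
    }
  }
  dtrain <- xgboost::xgb.DMatrix(Xtr, label = ytr_lab)
  dval <- xgboost::xgb.DMatrix(X[val, , drop = FALSE], label = y[val])
  booster <- xgboost::xgb.train(
    params = list(
      objective = "binary:logistic", eta = 0.03, max_depth = 10L,
      max_leaves = 60L, grow_policy = "lossguide", tree_method = "hist",
      subsample = 0.8, colsample_bytree = 0.8,
      nthread = 1L, seed = config$seed, eval_metric = "logloss"
    ),
    data = dtrain, nrounds = config$nrounds,
    evals = list(val = dval), early_stopping_rounds = 20L, verbose = 0
  )
  calibration <- NULL
  if (config$calibrate) {
    f_val <- stats::predict(booster, dval, outputmargin = TRUE)
    calibration <- calibration_fit(f_val, y[val])
  }
  list(booster = booster, calibration = calibration)
}

#' Predict completion probability
#'
#' Applies the fitted score function \eqn{f(X)} and the logistic link: the
#' returned probability satisfies `logit(p) == raw score` exactly.
#'
#' @param model a `gh_classifier`.
#' @param X feature matrix (n x 71) or single vector.
#' @param type `"prob"` for probabilities, `"logit"` for the raw score.
#' @return numeric vector.
#' @export
predict_proba <- function(model, X, type = c("prob", "logit")) {
  type <- match.arg(type)
  if (is.null(dim(X))) X <- matrix(X, 1L)
  if (ncol(X) != model$manifest$n_features) {
    stop(sprintf("feature dimension mismatch: got %d, model expects %d",
                 ncol(X), model$manifest$n_features), call. = FALSE)
  }
  f <- if (model$backend == "nn") {
    b <- model$fit
    Xs <- t((t(X) - b$mu) / b$sd)
    mlp_forward(b$net, b$net$params, t(Xs), train = FALSE)$logits
  } else {
    stats::predict(model$fit$booster, xgboost::xgb.DMatrix(X), outputmargin = TRUE)
  }
  f <- calibration_apply(model$fit$calibration, f)
  if (type == "logit") f else sigmoid(f)
}

#' Evaluate a classifier
#'
#' Accuracy at the 0.5 threshold, miss-classification rate, the full ROC
#' curve (one point per distinct score threshold), trapezoidal AUROC, and
#' the naive all-catch baseline accuracy.
#'
#' @param model a `gh_classifier`, or a numeric vector of predicted
#'   probabilities.
#' @param X feature matrix (ignored when `model` is already a probability
#'   vector).
#' @param y binary labels.
#' @return a `gh_eval_report` list.
#' @export
evaluate_classifier <- function(model, X = NULL, y) {
  p <- if (is.numeric(model)) model else predict_proba(model, X)
  if (!length(y)) stop("empty evaluation set", call. = FALSE)
  stopifnot(length(p) == length(y))
  acc <- mean((p >= 0.5) == (y == 1L))
  roc <- roc_points(p, y)
  structure(
    list(accuracy = acc, miss_classification = 1 - acc,
         roc_points = roc, auroc = auroc_trapezoid(roc),
         baseline_accuracy = mean(y == 1L), n = length(y)),
    class = "gh_eval_report"
  )
}

# ROC by threshold sweep over the distinct scores (plus sentinels), FPR/TPR
# nondecreasing from (0,0) to (1,1).
roc_points <- function(p, y) {
  ths <- c(Inf, sort(unique(p), decreasing = TRUE), -Inf)
  pos <- sum(y == 1L)
  neg <- sum(y != 1L)
  tpr <- vapply(ths, function(th) if (pos) sum(p >= th & y == 1L) / pos else 0, numeric(1))
  fpr <- vapply(ths, function(th) if (neg) sum(p >= th & y != 1L) / neg else 0, numeric(1))
  data.frame(threshold = ths, fpr = fpr, tpr = tpr)
}

auroc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Receiver-order sensitivity of a classifier
#'
#' For each evaluation vector, predicts under all 120 permutations of the
#' receiver blocks and takes the spread (max minus min probability); returns
#' the maximum spread over vectors. A perfectly order-invariant model scores
#' 0.
#'
#' @param model a `gh_classifier`.
#' @param X feature matrix (n x 71).
#' @return non-negative scalar.
#' @export
order_invariance_score <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, 1L)
  perms <- permutations_all(5L)
  probs <- matrix(0, nrow(X), nrow(perms))
  for (pi in seq_len(nrow(perms))) {
    probs[, pi] <- predict_proba(model, permute_receivers(X, perm = perms[pi, ]))
  }
  max(apply(probs, 1L, max) - apply(probs, 1L, min))
}

#' Stratified k-fold cross-validation
#'
#' Trains and evaluates the configured classifier over label-stratified
#' folds.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param config a [classifier_config()]; `cv_folds` controls k.
#' @return list of per-fold `gh_eval_report`s plus `mean_accuracy` and
#'   `mean_auroc`.
#' @export
cross_validate_classifier <- function(X, y, config = classifier_config()) {
  folds <- stratified_folds(y, config$cv_folds, config$seed)
  reports <- lapply(seq_len(config$cv_folds), function(k) {
    te <- which(folds == k)
    tr <- which(folds != k)
    m <- train_classifier(X[tr, , drop = FALSE], y[tr], config)
    evaluate_classifier(m, X[te, , drop = FALSE], y[te])
  })
  list(folds = reports,
       mean_accuracy = mean(vapply(reports, `[[`, numeric(1), "accuracy")),
       mean_auroc = mean(vapply(reports, `[[`, numeric(1), "auroc")))
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}
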