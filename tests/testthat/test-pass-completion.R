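test_that("receiver blocks carry the two nearest defenders, nearer first", {
  p <- normalize_play(generate_play(seed = 31))
  pass_i <- match(p$events$pass_forward, p$frames)
  # plant a receiver and three defenders at known offsets
  rj <- match("R01", p$roster$entity_id)
  p$x[pass_i, rj] <- 20; p$y[pass_i, rj] <- -10
  d <- list(D01 = c(20, -11), D02 = c(20, -13), D03 = c(25, -10))
  for (nm in names(d)) {
    j <- match(nm, p$roster$entity_id)
    p$x[pass_i, j] <- d[[nm]][1]; p$y[pass_i, j] <- d[[nm]][2]
  }
  # push the other defenders far away
  for (nm in c("D04", "D05", "D06", "D07")) {
    j <- match(nm, p$roster$entity_id)
    p$x[pass_i, j] <- 50; p$y[pass_i, j] <- -40
  }
  v <- build_feature_vector(p)
  expect_equal(unname(v[c("r1_d1x", "r1_d1y")]), c(20, -11))
  expect_equal(unname(v[c("r1_d1rx", "r1_d1ry")]), c(0, -1))
  expect_equal(unname(v[c("r1_d2x", "r1_d2y")]), c(20, -13))
  expect_equal(unname(v[c("r1_d2rx", "r1_d2ry")]), c(0, -3))
  # equidistant defenders: tie broken by entity id ascending
  j2 <- match("D02", p$roster$entity_id)
  p$x[pass_i, j2] <- 20; p$y[pass_i, j2] <- -9 # now D01 and D02 both 1 yard away
  v2 <- build_feature_vector(p)
  expect_equal(unname(v2[c("r1_d1x", "r1_d1y")]), c(20, -11)) # D01 < D02
  expect_equal(unname(v2[c("r1_d2x", "r1_d2y")]), c(20, -9))
})

test_that("the feature vector is invariant to pre-normalisation field translation", {
  p <- generate_play(seed = 32)
  v1 <- build_feature_vector(normalize_play(p))
  q <- p
  shift <- 4
  q$x <- q$x + shift # slide the whole play down-field
  q$meta$line_of_scrimmage_x <- q$meta$line_of_scrimmage_x + shift
  v2 <- build_feature_vector(normalize_play(q))
  keep <- setdiff(names(v1), "field_position") # field position is absolute
  expect_equal(v1[keep], v2[keep], tolerance = 1e-9)
})

test_that("receiver-block permutations compose, invert and cover all 120 orders", {
  p <- normalize_play(generate_play(seed = 33))
  v <- build_feature_vector(p)
  expect_identical(permute_receivers(v, perm = 1:5), v)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  w <- permute_receivers(v, perm = perm)
  inv <- order(perm)
  expect_identical(permute_receivers(w, perm = inv), v)
  # seeded random permutations over 1,000 draws cover all 120 orders
  X <- matrix(rep(v, 1000), nrow = 1000, byrow = TRUE)
  colnames(X) <- names(v)
  set.seed(1)
  seen <- character(0)
  Xp <- permute_receivers(X, seed = 2024)
  for (i in seq_len(nrow(Xp))) {
    first <- vapply(1:5, function(k) Xp[i, (k - 1) * 13 + 1], numeric(1))
    seen <- union(seen, paste(match(first, vapply(1:5, function(k) v[(k - 1) * 13 + 1], numeric(1))), collapse = ""))
  }
  expect_length(seen, 120)
})

test_that("predicted probability is the exact sigmoid of the raw score", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(50), 1, tolerance = 1e-12)
  set.seed(2)
  z <- rnorm(1000, 0, 3)
  expect_lt(max(abs(logit(sigmoid(z)) - z)), 1e-9)
  # through a trained model
  ds <- fx_get("pass_ds_small", function() build_pass_dataset(fx_coll20()))
  skip_if(length(unique(ds$y)) < 2)
  m <- fx_get("clf_tiny", function() {
    train_classifier(ds$X, ds$y, classifier_config("nn", augment = FALSE, seed = 1,
                                                   epochs = 5, batch_size = 8))
  })
  p <- predict_proba(m, ds$X)
  f <- predict_proba(m, ds$X, type = "logit")
  expect_equal(p, sigmoid(f), tolerance = 1e-12)
  mod <- abs(f) < 10 # the inverse is float-representable for moderate scores
  expect_lt(max(abs(logit(p[mod]) - f[mod])), 1e-9)
  expect_error(predict_proba(m, ds$X[, 1:10]), "mismatch")
})

test_that("training separates linearly separable data and is seed-deterministic", {
  set.seed(3)
  n <- 400
  X <- matrix(rnorm(n * 71), n, 71)
  y <- as.integer(X[, 1] + 0.5 * X[, 20] > 0)
  cfg <- classifier_config("nn", augment = FALSE, seed = 7, epochs = 60,
                           batch_size = 64)
  m1 <- train_classifier(X, y, cfg)
  rep1 <- evaluate_classifier(m1, X, y)
  expect_gt(rep1$accuracy, 0.97)
  m2 <- train_classifier(X, y, cfg)
  expect_identical(predict_proba(m1, X), predict_proba(m2, X))
  expect_error(train_classifier(X, rep(1L, n), cfg), "single class")
})

test_that("the ROC/AUROC implementation matches brute-force oracles", {
  # hand-computed 4-sample case: scores .9/.8 positive-ish, .4/.1
  p <- c(0.9, 0.8, 0.4, 0.1)
  y <- c(1, 0, 1, 0)
  rep <- evaluate_classifier(p, y = y)
  # thresholds sweep: TPR/FPR pairs (0,0) (.5,0) (.5,.5) (1,.5) (1,1) -> AUC .75
  expect_equal(rep$auroc, 0.75)
  expect_equal(rep$accuracy, 0.5) # at 0.5: predicts 1,1,0,0 vs 1,0,1,0
  expect_true(all(diff(rep$roc_points$fpr) >= 0))
  expect_true(all(diff(rep$roc_points$tpr) >= 0))
  # concordance oracle on 100 random samples
  set.seed(4)
  p <- runif(100)
  y <- rbinom(100, 1, 0.5)
  rep2 <- evaluate_classifier(p, y = y)
  expect_equal(rep2$auroc, fx_auroc_concordance(p, y), tolerance = 1e-12)
  # perfect separation
  rep3 <- evaluate_classifier(c(rep(0.9, 5), rep(0.1, 5)), y = c(rep(1, 5), rep(0, 5)))
  expect_equal(rep3$auroc, 1)
  expect_equal(rep3$accuracy, 1)
  expect_error(evaluate_classifier(numeric(0), y = integer(0)), "empty")
})

test_that("AUROC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  p <- runif(300)
  y <- rbinom(300, 1, plogis(3 * (p - 0.5)))
  skip_if(length(unique(y)) < 2)
  ours <- evaluate_classifier(p, y = y)$auroc
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("order-invariance score is zero for a receiver-blind model and non-negative", {
  ds <- fx_get("pass_ds_small", function() build_pass_dataset(fx_coll20()))
  m <- fx_get("clf_tiny", function() {
    train_classifier(ds$X, ds$y, classifier_config("nn", augment = FALSE, seed = 1,
                                                   epochs = 5, batch_size = 8))
  })
  s <- order_invariance_score(m, ds$X[1:3, , drop = FALSE])
  expect_gte(s, 0)
  # a model that ignores receiver blocks: zero out their weights
  blind <- m
  blind$fit$net$params$layers[[1]]$W[, 1:65] <- 0
  expect_equal(order_invariance_score(blind, ds$X[1:3, , drop = FALSE]), 0)
})

test_that("stratified folds balance classes", {
  stratified_folds <- getFromNamespace("stratified_folds", "ghostr")
  set.seed(6)
  y <- rep(c(0L, 1L), c(70, 30))
  f <- stratified_folds(y, 7, seed = 2)
  for (k in 1:7) {
    expect_equal(sum(f == k & y == 1), 30 / 7, tolerance = 0.35)
    expect_equal(sum(f == k), 100 / 7, tolerance = 0.35)
  }
})

test_that("stratified cross-validation reports per-fold metrics", {
  set.seed(8)
  n <- 140
  X <- matrix(rnorm(n * 71), n, 71)
  y <- as.integer(X[, 5] - X[, 30] > 0)
  cfg <- classifier_config("gbt", augment = FALSE, seed = 4, nrounds = 30,
                           cv_folds = 3L)
  cv <- cross_validate_classifier(X, y, cfg)
  expect_length(cv$folds, 3)
  expect_gt(cv$mean_accuracy, 0.7)
  expect_true(all(vapply(cv$folds, function(f) f$auroc, numeric(1)) > 0.5))
})
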