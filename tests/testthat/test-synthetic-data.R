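test_that("noise-free unit-gain pursuit collocates defender and receiver", {
  cfg <- synth_config(gain = 1, sigma = 0, routes = "hitch")
  p <- generate_play(cfg, seed = 3)
  snap_i <- match(p$events$ball_snap, p$frames)
  # man defender D01 chases receiver R01; with g = 1 the defender lands on
  # the receiver's previous position every frame (up to the speed cap)
  d <- cbind(p$x[, "D01"], p$y[, "D01"])
  r <- cbind(p$x[, "R01"], p$y[, "R01"])
  caught <- FALSE
  for (t in (snap_i + 1):length(p$frames)) {
    gap_prev <- sqrt(sum((r[t - 1, ] - d[t - 1, ])^2))
    gap_now <- sqrt(sum((r[t - 1, ] - d[t, ])^2))
    if (gap_prev <= 1.1) {
      expect_lt(gap_now, 1e-9) # within the cap: exact collocation
      caught <- TRUE
    }
  }
  expect_true(caught)
})

test_that("half-gain pursuit of a static target halves the gap each frame", {
  cfg <- synth_config(gain = 0.5, sigma = 0, routes = "hitch")
  p <- generate_play(cfg, seed = 4)
  # zone safety D06 relaxes toward its fixed anchor when no receiver is near;
  # construct the closed form directly from the stored script instead
  script <- p$script
  pos <- c(10, 10)
  target <- c(20, 10) # static target, gap 10 -> halves each step (cap not hit)
  gaps <- numeric(5)
  for (t in 1:5) {
    step <- 0.5 * (target - pos)
    if (sqrt(sum(step^2)) > 1.1) step <- step * 1.1 / sqrt(sum(step^2))
    pos <- pos + step
    gaps[t] <- sqrt(sum((target - pos)^2))
  }
  # the generator's own dynamics must match this closed form: replay D01 vs a
  # receiver pinned at its hitch endpoint once the receiver has stopped
  snap_i <- match(p$events$ball_snap, p$frames)
  r <- cbind(p$x[, "R01"], p$y[, "R01"])
  d <- cbind(p$x[, "D01"], p$y[, "D01"])
  stopped <- which(rowSums(abs(diff(r))) < 1e-12)
  stopped <- stopped[stopped > snap_i + 2]
  skip_if(length(stopped) < 4, "receiver never settles in this draw")
  t0 <- stopped[1]
  g0 <- sqrt(sum((r[t0, ] - d[t0, ])^2))
  g1 <- sqrt(sum((r[t0 + 1, ] - d[t0 + 1, ])^2))
  if (0.5 * g0 <= 1.1) expect_equal(g1, 0.5 * g0, tolerance = 1e-9)
})

test_that("the same seed produces byte-identical CSV output", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_tracking(generate_dataset(5, seed = 77), dir1)
  write_tracking(generate_dataset(5, seed = 77), dir2)
  for (f in list.files(dir1)) {
    expect_identical(readBin(file.path(dir1, f), "raw", 1e7),
                     readBin(file.path(dir2, f), "raw", 1e7))
  }
})

test_that("generated plays satisfy the tracking invariants and survive filtering", {
  coll <- fx_coll20()
  filt <- filter_plays(coll)
  expect_equal(length(filt$plays), length(coll$plays))
  for (p in coll$plays) {
    expect_true(all(p$x >= 0 & p$x <= 120))
    expect_true(all(p$y >= 0 & p$y <= 53.3))
    expect_true(all(p$s >= 0))
    expect_true(all(p$s <= 11 + 1e-9))
    expect_lt(p$events$ball_snap, p$events$pass_forward)
    dur <- (p$events$pass_forward - p$events$ball_snap + 1) / 10
    expect_gte(dur, 2); expect_lte(dur, 8.1)
  }
})

test_that("empirical completion rate matches the stored truth probabilities", {
  coll <- fx_get("coll2000", function() generate_dataset(2000, seed = 500))
  tp <- attr(coll, "truth_prob")
  lab <- attr(coll, "labels")
  # binomial sampling bound: 4 sd of the mean of 2000 Bernoullis
  expect_lt(abs(mean(lab) - mean(tp)), 4 * sqrt(0.25 / 2000))
  # degenerate truth: zero weights reduce to the bias
  cfg0 <- synth_config(completion_weights = c(separation = 0, pressure = 0, depth = 0),
                       completion_bias = 0.3)
  c0 <- generate_dataset(400, cfg0, seed = 9)
  expect_lt(abs(mean(attr(c0, "labels")) - sigmoid(0.3)), 0.1)
})

test_that("injected role switches swap duties at the requested frame", {
  cfg <- synth_config(gain = 0.6, sigma = 0, routes = "hitch")
  p <- generate_play(cfg, seed = 21)
  snap <- p$events$ball_snap
  pass <- p$events$pass_forward
  t_sw <- snap + ((pass - snap) %/% 2)
  sw <- inject_role_switch(p, t_sw, pair = c(1L, 3L), seed = 1)
  i_sw <- match(t_sw, p$frames)
  # truth sequence records the swap exactly at the switch frame
  expect_equal(sw$role_truth[i_sw - 1, 1:5], 1:5)
  expect_equal(sw$role_truth[i_sw, c(1, 3)], c(3L, 1L))
  # before the switch the defense is unchanged; after, D01 closes on R03
  dids <- c("D01", "D02", "D03", "D04", "D05", "D06", "D07")
  expect_equal(sw$x[1:(i_sw - 1), dids], p$x[1:(i_sw - 1), dids], tolerance = 1e-12)
  gap_before <- sqrt((p$x[i_sw, "D01"] - p$x[i_sw, "R03"])^2 +
                       (p$y[i_sw, "D01"] - p$y[i_sw, "R03"])^2)
  L <- length(p$frames)
  gap_after <- sqrt((sw$x[L, "D01"] - sw$x[L, "R03"])^2 +
                      (sw$y[L, "D01"] - sw$y[L, "R03"])^2)
  expect_lt(gap_after, gap_before)
  # out-of-window switch errors; a switch at the snap is a relabelling
  expect_error(inject_role_switch(p, pass + 5L), "outside")
})
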