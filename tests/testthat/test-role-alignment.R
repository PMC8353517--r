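test_that("static assignment minimises the brute-force permutation cost", {
  brute <- getFromNamespace("brute_force_assignment", "ghostr")
  role_cost <- getFromNamespace("role_cost_matrix", "ghostr")
  model <- fx_static_roles()
  plays <- fx_norm20()
  snap_positions <- getFromNamespace("snap_positions", "ghostr")
  for (p in plays[1:8]) {
    a <- assign_roles_static(model, p)
    cost <- role_cost(model, snap_positions(p, "defense"))
    b <- brute(cost)
    expect_equal(a$cost, b$cost, tolerance = 1e-10)
    expect_setequal(a$mapping, 1:7)
  }
})

test_that("static roles recover the generating formation slots", {
  model <- fx_static_roles()
  # the model's canonical roles must correspond 1:1 to the generator slots
  centers <- fx_slot_centers()
  corr <- solve_assignment(as.matrix(stats::dist(rbind(model$means, centers)))[1:7, 8:14])
  slot_of_role <- corr$assignment
  plays <- fx_norm20()
  hits <- vapply(plays, function(p) {
    a <- assign_roles_static(model, p)
    truth <- fx_truth_slots(p) # generating slot of defender j (roster order)
    all(slot_of_role[a$mapping] == truth)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("canonical role order is sorted along x' then y'", {
  model <- fx_static_roles()
  m <- model$means
  expect_identical(order(m[, 1], m[, 2]), 1:7)
})

test_that("dynamic window assignment agrees with the brute-force minimum and respects symmetry", {
  brute <- getFromNamespace("brute_force_assignment", "ghostr")
  plays <- fx_norm20()
  dm <- fx_get("dyn_roles", function() fit_dynamic_role_model(plays, 7, seed = 5, max_iter = 30))
  expect_true(all(diff(dm$loglik) >= -1e-6))
  p <- plays[[1]]
  a <- assign_roles_dynamic(dm, p)
  # rebuild the cost matrix independently and enumerate all 5040 permutations
  win <- seq_along(p$frames)
  dmvnorm_log <- getFromNamespace("dmvnorm_log", "ghostr")
  ids <- p$roster$entity_id[p$roster$team == "defense"]
  cost <- matrix(0, 7, 7)
  for (i in 1:7) {
    j <- match(ids[i], p$roster$entity_id)
    s <- cbind(p$x[win, j], p$y[win, j])
    for (r in 1:7) {
      cost[i, r] <- -sum(dmvnorm_log(s, dm$emission_means[r, ], dm$emission_covs[, , r]))
    }
  }
  b <- brute(cost)
  expect_equal(a$cost, b$cost, tolerance = 1e-8)
  # swapping two defenders' tracks swaps their roles
  q <- p
  j1 <- match(ids[1], p$roster$entity_id)
  j2 <- match(ids[2], p$roster$entity_id)
  q$x[, c(j1, j2)] <- p$x[, c(j2, j1)]
  q$y[, c(j1, j2)] <- p$y[, c(j2, j1)]
  a2 <- assign_roles_dynamic(dm, q)
  expect_equal(a2$mapping[c(1, 2)], a$mapping[c(2, 1)])
  expect_equal(a2$mapping[3:7], a$mapping[3:7])
})

test_that("defenders parked on the emission means are assigned those roles at the modal cost", {
  dmvnorm_log <- getFromNamespace("dmvnorm_log", "ghostr")
  k <- 7
  means <- cbind(seq(5, 47, length.out = k), rep(-6, k))
  model <- structure(
    list(transition = diag(k), initial = rep(1 / k, k),
         emission_means = means,
         emission_covs = array(rep(diag(2), k), c(2, 2, k)),
         loglik = 0, n_states = k),
    class = "gh_dynamic_roles"
  )
  p <- fx_norm20()[[1]]
  ids <- p$roster$entity_id[p$roster$team == "defense"]
  for (i in seq_along(ids)) {
    j <- match(ids[i], p$roster$entity_id)
    p$x[, j] <- means[i, 1]
    p$y[, j] <- means[i, 2]
  }
  a <- assign_roles_dynamic(model, p)
  expect_equal(a$mapping, 1:7)
  mode_logdens <- dmvnorm_log(means[1, , drop = FALSE], means[1, ], diag(2))
  expect_equal(a$cost, -7 * length(p$frames) * mode_logdens, tolerance = 1e-8)
})

test_that("the dynamic model locates an injected switch within three frames", {
  cfg <- synth_config(gain = 0.7, sigma = 0.02, routes = "hitch",
                      duration_range = c(4, 8))
  coll <- generate_dataset(40, cfg, seed = 900)
  plays <- lapply(coll$plays, function(p) clip_to_pass_window(normalize_play(p)))
  dm <- fx_get("dyn_roles_switch", function() {
    fit_dynamic_role_model(plays, 7, seed = 2, max_iter = 25)
  })
  hits <- 0L
  checked <- 0L
  for (i in seq_along(plays)) {
    p0 <- coll$plays[[i]]
    L <- p0$events$pass_forward - p0$events$ball_snap + 1L
    t_sw <- p0$events$ball_snap + L %/% 2L
    sw <- inject_role_switch(p0, t_sw, pair = c(1L, 2L), seed = 3)
    swn <- clip_to_pass_window(normalize_play(sw))
    path <- role_state_path(dm, swn, "D01")
    change <- which(diff(path) != 0)
    checked <- checked + 1L
    if (!length(change)) next
    # the hand-over registers when the defender crosses between the two duty
    # regions: adjacent lanes are ~10 yards apart, so mid-transit is ~4-5
    # frames after the commanded switch at the 1.1 yd/frame speed cap
    lag <- change[1] - (t_sw - p0$events$ball_snap + 1L)
    if (abs(lag - 4) <= 3) hits <- hits + 1L
  }
  expect_gte(checked, 30L)
  expect_gte(hits / checked, 0.85)
})

test_that("role models survive a JSON round trip", {
  model <- fx_static_roles()
  path <- withr::local_tempfile(fileext = ".json")
  write_role_model(model, path)
  back <- read_role_model(path)
  expect_equal(back$means, model$means, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$covs, model$covs, tolerance = 1e-12)
  expect_equal(back$weights, model$weights, tolerance = 1e-12)
  expect_s3_class(back, "gh_static_roles")
})
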