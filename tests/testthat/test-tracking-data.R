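test_that("writing then reading the CSV dialect preserves plays", {
  coll <- fx_coll20()
  dir <- withr::local_tempdir()
  write_tracking(coll, dir)
  back <- read_tracking(list.files(dir, pattern = "^week", full.names = TRUE),
                        file.path(dir, "plays.csv"), file.path(dir, "games.csv"))
  expect_length(back$plays, length(coll$plays))
  key <- function(p) paste(p$game_id, p$play_id)
  idx <- match(vapply(coll$plays, key, ""), vapply(back$plays, key, ""))
  expect_false(anyNA(idx))
  for (i in seq_along(coll$plays)) {
    a <- coll$plays[[i]]
    b <- back$plays[[idx[i]]]
    cols <- a$roster$entity_id
    expect_lt(max(abs(a$x - b$x[, cols])), 1e-9)
    expect_lt(max(abs(a$y - b$y[, cols])), 1e-9)
    expect_equal(a$events$ball_snap, b$events$ball_snap)
    expect_equal(a$events$pass_forward, b$events$pass_forward)
    expect_equal(a$meta$down, b$meta$down)
    expect_equal(a$meta$yards_to_go, b$meta$yards_to_go)
    expect_equal(a$meta$pass_outcome, b$meta$pass_outcome)
    expect_equal(a$week, b$week)
  }
})

test_that("rows with out-of-bounds coordinates are rejected with diagnostics", {
  coll <- play_collection(list(generate_play(seed = 5)))
  dir <- withr::local_tempdir()
  write_tracking(coll, dir)
  path <- list.files(dir, pattern = "^week", full.names = TRUE)[1]
  d <- data.table::fread(path)
  d$x[3] <- 500 # off the field
  data.table::fwrite(d, path)
  back <- read_tracking(path, file.path(dir, "plays.csv"), file.path(dir, "games.csv"))
  expect_equal(nrow(attr(back, "bad_rows")), 1L)
})

test_that("filtering keeps only clean 7-defender/6-offense pass plays", {
  coll <- fx_coll20()
  # corrupt three plays: drop a defender, add a sack event, remove pass_forward
  bad <- coll
  bad$plays[[1]]$roster <- bad$plays[[1]]$roster[-1, ]
  bad$plays[[1]]$x <- bad$plays[[1]]$x[, -1]
  bad$plays[[1]]$y <- bad$plays[[1]]$y[, -1]
  bad$plays[[2]]$events$qb_sack <- bad$plays[[2]]$events$ball_snap + 2L
  bad$plays[[3]]$events$pass_forward <- NULL
  filt <- filter_plays(bad)
  counts <- attr(filt, "filter_counts")
  expect_equal(unname(counts), c(20L, 17L))
  # idempotence
  again <- filter_plays(filt)
  expect_equal(unname(attr(again, "filter_counts")), c(17L, 17L))
  expect_lte(length(again$plays), length(filt$plays))
})

test_that("normalisation places the scrimmage line at y' = 0 with offense at positive y'", {
  p <- generate_play(seed = 11)
  los <- p$meta$line_of_scrimmage_x
  np <- normalize_play(p)
  snap_i <- match(np$events$ball_snap, np$frames)
  # a point exactly on the scrimmage line maps to y' = 0
  probe <- p
  j <- match("D01", probe$roster$entity_id)
  probe$x[snap_i, j] <- los
  nprobe <- normalize_play(probe)
  expect_equal(unname(nprobe$y[snap_i, j]), 0, tolerance = 1e-12)
  # QB 5 yards behind scrimmage maps to y' = +5
  adv <- if (p$meta$play_direction == "right") 1 else -1
  probe2 <- p
  qj <- match("QB01", probe2$roster$entity_id)
  probe2$x[snap_i, qj] <- los - adv * 5
  nprobe2 <- normalize_play(probe2)
  expect_equal(unname(nprobe2$y[snap_i, qj]), 5, tolerance = 1e-12)
  # offense advances toward negative y': receivers end deeper (more negative)
  rj <- match("R01", np$roster$entity_id)
  expect_lt(np$y[length(np$frames), rj], np$y[snap_i, rj] + 1e-9)
})

test_that("normalisation is a rigid transform with an exact inverse", {
  p <- generate_play(seed = 12)
  np <- normalize_play(p)
  t_idx <- 10L
  d_orig <- dist(cbind(p$x[t_idx, ], p$y[t_idx, ]))
  d_norm <- dist(cbind(np$x[t_idx, ], np$y[t_idx, ]))
  expect_lt(max(abs(d_orig - d_norm)), 1e-9)
  back <- denormalize_play(np)
  expect_lt(max(abs(back$x - p$x)), 1e-9)
  expect_lt(max(abs(back$y - p$y)), 1e-9)
})

test_that("mirroring the field leaves the normalized play unchanged", {
  p <- generate_play(seed = 13)
  m <- p
  m$x <- 120 - p$x
  m$y <- 53.3 - p$y
  m$meta$play_direction <- if (p$meta$play_direction == "right") "left" else "right"
  m$meta$line_of_scrimmage_x <- 120 - p$meta$line_of_scrimmage_x
  np <- normalize_play(p)
  nm <- normalize_play(m)
  expect_lt(max(abs(np$x - nm$x)), 1e-9)
  expect_lt(max(abs(np$y - nm$y)), 1e-9)
})

test_that("clipping retains the inclusive snap-to-pass window and is idempotent", {
  p <- generate_play(seed = 14)
  cp <- clip_to_pass_window(p)
  snap <- p$events$ball_snap
  pass <- p$events$pass_forward
  expect_equal(length(cp$frames), pass - snap + 1L)
  expect_equal(cp$frames[1], snap)
  expect_equal(cp$frames[length(cp$frames)], pass)
  expect_identical(clip_to_pass_window(cp)$frames, cp$frames)
  # corrupt ordering errors out
  bad <- p
  bad$events$pass_forward <- bad$events$ball_snap - 1L
  expect_error(clip_to_pass_window(bad), "precedes")
})

test_that("splitting modes behave as documented", {
  coll <- generate_dataset(34, seed = 55) # two plays per week over 17 weeks
  by_week <- split_collection(coll, "by_week", seed = 1)
  weeks <- vapply(by_week$plays, `[[`, integer(1), "week")
  expect_true(all(by_week$split[weeks >= 15] == "test"))
  expect_true(all(by_week$split[weeks <= 14] %in% c("train", "validation")))
  r1 <- split_collection(coll, "random_70_30", seed = 9)
  r2 <- split_collection(coll, "random_70_30", seed = 9)
  expect_identical(r1$split, r2$split)
  expect_equal(sum(r1$split == "test"), round(0.3 * 34))
  expect_error(split_collection(coll, "bogus"))
})
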