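#' Synthetic play generator configuration
#'
#' Controls the scripted-play generator that emulates the Big Data Bowl
#' tracking dialect: 7 defenders, 6 offensive players (QB + 5 receivers) and
#' a ball at 10 Hz, with route-running receivers, reactive scripted defense
#' and a known logistic completion-probability ground truth.
#'
#' Defaults encode the study conditions the rest of the package is tested
#' under: snap-to-pass windows of 2-8 s with mean 3.6 s, man coverage on the
#' five receivers with two deep zone safeties, first-order pursuit defense
#' (next step = `gain` times the gap to the target plus Gaussian noise) and
#' an 11 yd/s speed cap.
#'
#' @param coverage `"man"` (5 man defenders + 2 zone safeties) or `"zone"`
#'   (all 7 defenders anchored).
#' @param gain pursuit gain g in (0, 1]: fraction of the defender-target gap
#'   closed per frame. A range `c(lo, hi)` samples one gain per play.
#' @param sigma reaction noise, yards per frame, added to each defender step.
#' @param zone_gain pursuit gain toward zone anchors.
#' @param zone_radius radius (yards) within which a zone defender reacts to
#'   the nearest receiver.
#' @param duration_range snap-to-pass duration bounds in seconds; durations
#'   are `2 + min(Gamma(shape=2, scale=0.8), range)` truncated to the bounds,
#'   giving a 3.6 s mean.
#' @param pre_snap_frames frames recorded before the snap.
#' @param routes route-template names receivers draw from.
#' @param completion_weights named weights of the logistic ground truth over
#'   (max receiver separation from nearest defender, QB pressure distance,
#'   depth of the deepest receiver), all in yards at the pass frame.
#' @param completion_bias intercept of the logistic ground truth.
#' @param max_speed speed cap in yards/s.
#' @param role_switch_prob probability that a play contains a mid-play swap
#'   of two man assignments (0 by default; see [inject_role_switch()]).
#' @return a `gh_synth_config` list.
#' @export
synth_config <- function(coverage = c("man", "zone"),
                         gain = c(0.08, 0.4),
                         sigma = 0.12,
                         zone_gain = 0.15,
                         zone_radius = 10,
                         duration_range = c(2, 8),
                         pre_snap_frames = 5L,
                         routes = c("go", "hitch", "crossing", "flat"),
                         completion_weights = c(separation = 2.0,
                                                pressure = 0.15,
                                                depth = -0.5),
                         completion_bias = 6.4,
                         max_speed = 11,
                         role_switch_prob = 0) {
  coverage <- match.arg(coverage)
  stopifnot(all(gain > 0), all(gain <= 1), sigma >= 0, max_speed > 0)
  structure(
    list(coverage = coverage, gain = gain, sigma = sigma,
         zone_gain = zone_gain, zone_radius = zone_radius,
         duration_range = duration_range, pre_snap_frames = as.integer(pre_snap_frames),
         routes = routes, completion_weights = completion_weights,
         completion_bias = completion_bias, max_speed = max_speed,
         role_switch_prob = role_switch_prob),
    class = "gh_synth_config"
  )
}

# Route templates: waypoints as (depth beyond scrimmage, lateral offset from
# the receiver's lane), in yards, plus a cruise speed in yards/s.
route_template <- function(name) {
  switch(name,
    go = list(waypoints = rbind(c(2, 0), c(22, 0)), speed = 9),
    hitch = list(waypoints = rbind(c(6, 0), c(5, 0.5)), speed = 7.5),
    crossing = list(waypoints = rbind(c(3, 0), c(6, 18)), speed = 8),
    flat = list(waypoints = rbind(c(1.5, 0), c(2, -9)), speed = 7),
    stop("unknown route: ", name, call. = FALSE)
  )
}

# Receiver lanes across the field width, outermost to innermost.
receiver_lanes <- function() c(6, 16.5, 26.65, 36.8, 47.3)

#' Generate one synthetic play
#'
#' Simulates a snap-to-pass window in field coordinates: receivers follow
#' route templates, man defenders run first-order pursuit of their assigned
#' receiver, zone defenders hold anchors with local reaction, and the ball
#' stays with the QB until `pass_forward`. The completion ground truth is
#' computed from the geometry at the pass frame and the outcome drawn from
#' it. The coverage script, per-frame ground-truth role assignment and truth
#' probability are stored on the play (`$script`, `$role_truth`,
#' `$truth_prob`).
#'
#' @param config a [synth_config()].
#' @param seed integer seed; the play is a deterministic function of
#'   (config, seed).
#' @param week,game_id,play_id identifiers written into the dialect.
#' @return a `gh_play` in field coordinates.
#' @export
generate_play <- function(config = synth_config(), seed = 1L, week = 1L,
                          game_id = "1000", play_id = NULL) {
  stopifnot(inherits(config, "gh_synth_config"))
  set.seed(seed)
  if (is.null(play_id)) play_id <- as.character(seed)

  direction <- sample(c("left", "right"), 1L)
  adv <- if (direction == "right") 1 else -1
  los <- sample(30:90, 1L)
  dur <- config$duration_range[1] +
    min(stats::rgamma(1L, shape = 2, scale = 0.8),
        config$duration_range[2] - config$duration_range[1])
  n_play <- max(2L, as.integer(round(dur * 10)))
  ps <- config$pre_snap_frames
  n_f <- ps + n_play
  dt <- 0.1

  lanes <- receiver_lanes() + stats::runif(5, -1.5, 1.5)
  route_names <- sample(config$routes, 5L, replace = TRUE)
  qb_xy <- c(los - adv * 5, FIELD_WIDTH / 2 + stats::runif(1, -1, 1))
  rec_start <- cbind(los - adv * 0.7, lanes)

  # defender snap spots: 5 press corners opposite each lane, 2 deep safeties
  def_start <- rbind(
    cbind(los + adv * 6, lanes),
    c(los + adv * 13, 17.5),
    c(los + adv * 13, 35.8)
  ) + matrix(stats::rnorm(14, 0, 0.8), 7, 2)
  man_assign <- if (config$coverage == "man") 1:5 else integer(0)
  gain <- if (length(config$gain) == 2L) stats::runif(1, config$gain[1], config$gain[2]) else config$gain
  zone_anchors <- rbind(
    cbind(los + adv * 7, receiver_lanes()),
    c(los + adv * 14, 17.5),
    c(los + adv * 14, 35.8)
  )
  switch_frame <- NA_integer_
  switch_pair <- NULL
  if (config$coverage == "man" && stats::runif(1) < config$role_switch_prob) {
    switch_frame <- ps + sample(seq(6L, max(7L, n_play - 5L)), 1L)
    switch_pair <- sample(1:5, 2L)
  }
  script <- list(
    coverage = config$coverage, gain = gain, sigma = config$sigma,
    zone_gain = config$zone_gain, zone_radius = config$zone_radius,
    man_assign = man_assign, zone_anchors = zone_anchors,
    switch_frame = switch_frame, switch_pair = switch_pair,
    def_start = def_start, max_speed = config$max_speed
  )

  # --- offense kinematics (receivers chase route waypoints) ---
  rec_xy <- array(0, c(n_f, 5, 2))
  for (r in 1:5) {
    tmpl <- route_template(route_names[r])
    wp <- cbind(los + adv * tmpl$waypoints[, 1], lanes[r] + tmpl$waypoints[, 2])
    wp[, 2] <- pmin(pmax(wp[, 2], 1), FIELD_WIDTH - 1)
    pos <- rec_start[r, ]
    wi <- 1L
    spd <- min(tmpl$speed, config$max_speed)
    for (t in seq_len(n_f)) {
      rec_xy[t, r, ] <- pos
      if (t <= ps) next
      gap <- wp[wi, ] - pos
      dist <- sqrt(sum(gap^2))
      if (dist < 0.4 && wi < nrow(wp)) {
        wi <- wi + 1L
        gap <- wp[wi, ] - pos
        dist <- sqrt(sum(gap^2))
      }
      if (dist > 1e-9) {
        step <- min(spd * dt, dist)
        pos <- pos + gap / dist * step
      }
      pos <- clamp_field(pos)
    }
  }
  # QB takes a ~3-yard drop away from the line at 1.75 yd/s, then sets
  qb_path <- matrix(rep(qb_xy, each = n_f), n_f, 2)
  drop_mag <- pmin(cumsum(c(rep(0, ps), rep(1.75 * dt, n_play))), 3)
  qb_path[, 1] <- qb_xy[1] - adv * drop_mag

  # --- defense kinematics (scripted pursuit) ---
  def_xy <- simulate_defense(script, rec_xy, ps, n_f, dt)

  ball_path <- qb_path

  roster <- data.frame(
    entity_id = c(sprintf("D%02d", 1:7), "QB01", sprintf("R%02d", 1:5), "BALL"),
    team = c(rep("defense", 7), rep("offense", 6), "ball"),
    position = c("CB", "CB", "CB", "CB", "CB", "FS", "SS", "QB",
                 rep("WR", 5), ""),
    stringsAsFactors = FALSE
  )
  x <- cbind(def_xy[, , 1], qb_path[, 1], rec_xy[, , 1], ball_path[, 1])
  y <- cbind(def_xy[, , 2], qb_path[, 2], rec_xy[, , 2], ball_path[, 2])
  colnames(x) <- colnames(y) <- roster$entity_id
  disp <- rbind(matrix(0, 1, ncol(x)), sqrt(diff(x)^2 + diff(y)^2))
  s <- disp / dt
  o <- (atan2(diff(rbind(y[1, , drop = FALSE], y)),
              diff(rbind(x[1, , drop = FALSE], x))) * 180 / pi) %% 360

  frames <- seq_len(n_f)
  events <- list(ball_snap = ps + 1L, pass_forward = n_f)
  meta <- list(
    down = sample(1:4, 1L, prob = c(0.45, 0.3, 0.2, 0.05)),
    yards_to_go = sample(1:15, 1L),
    line_of_scrimmage_x = los,
    play_direction = direction,
    absolute_field_position = if (direction == "right") (FIELD_LENGTH - 10) - los else los - 10
  )

  play <- new_play(play_id, game_id, week, frames, roster, x, y, s, o, events, meta)
  play$script <- script
  play$route_names <- route_names
  play$role_truth <- role_truth_matrix(script, n_f)
  play$usable <- TRUE
  play$has_pass <- TRUE

  # completion ground truth from pass-frame geometry, then the outcome draw
  play$truth_prob <- completion_truth_probability(play, config)
  play$meta$pass_outcome <- if (stats::runif(1) < play$truth_prob) "complete" else {
    if (stats::runif(1) < 0.07) "intercepted" else "incomplete"
  }
  play
}

clamp_field <- function(pos) {
  c(min(max(pos[1], 0.5), FIELD_LENGTH - 0.5), min(max(pos[2], 0.5), FIELD_WIDTH - 0.5))
}

# Scripted defense: first-order pursuit toward a per-frame target.
simulate_defense <- function(script, rec_xy, ps, n_f, dt) {
  def_xy <- array(0, c(n_f, 7, 2))
  pos <- script$def_start
  assign <- rep(NA_integer_, 7)
  if (script$coverage == "man") assign[1:5] <- script$man_assign
  for (t in seq_len(n_f)) {
    def_xy[t, , ] <- pos
    if (t >= n_f) break
    if (t >= ps + 1L) {
      if (!is.na(script$switch_frame) && t == script$switch_frame) {
        assign[script$switch_pair] <- assign[rev(script$switch_pair)]
      }
      for (j in 1:7) {
        if (!is.na(assign[j])) {
          target <- rec_xy[t, assign[j], ]
          g <- script$gain
        } else {
          anchor <- script$zone_anchors[j, ]
          d2 <- colSums((t(rec_xy[t, , ]) - anchor)^2)
          nearest <- which.min(d2)
          target <- if (d2[nearest] < script$zone_radius^2) {
            anchor + 0.5 * (rec_xy[t, nearest, ] - anchor)
          } else {
            anchor
          }
          g <- script$zone_gain
        }
        step <- g * (target - pos[j, ]) + stats::rnorm(2, 0, script$sigma)
        nrm <- sqrt(sum(step^2))
        cap <- script$max_speed * dt
        if (nrm > cap) step <- step * cap / nrm
        pos[j, ] <- clamp_field(pos[j, ] + step)
      }
    }
  }
  def_xy
}

# Ground-truth defender -> duty assignment per frame (duty index: receiver
# 1..5 for man duties, 6/7 for the two zone duties).
role_truth_matrix <- function(script, n_f) {
  truth <- matrix(NA_integer_, n_f, 7)
  assign <- c(if (script$coverage == "man") script$man_assign else rep(NA_integer_, 5),
              NA_integer_, NA_integer_)
  duties <- ifelse(is.na(assign), seq_len(7), assign)
  for (t in seq_len(n_f)) {
    if (!is.na(script$switch_frame) && t == script$switch_frame) {
      duties[script$switch_pair] <- duties[rev(script$switch_pair)]
    }
    truth[t, ] <- duties
  }
  truth
}

# Interpretable geometry features at the pass frame, in yards.
completion_truth_features <- function(play) {
  pass_i <- match(play$events[["pass_forward"]], play$frames)
  dids <- defense_ids(play)
  rids <- receiver_ids(play)
  dpos <- cbind(play$x[pass_i, dids], play$y[pass_i, dids])
  rpos <- cbind(play$x[pass_i, rids], play$y[pass_i, rids])
  qb <- c(play$x[pass_i, qb_id(play)], play$y[pass_i, qb_id(play)])
  sep <- apply(rpos, 1L, function(r) sqrt(min(colSums((t(dpos) - r)^2))))
  pressure <- sqrt(min(colSums((t(dpos) - qb)^2)))
  los <- play$meta$line_of_scrimmage_x
  adv <- if (identical(play$meta$play_direction, "right")) 1 else -1
  depth <- max(adv * (rpos[, 1] - los))
  c(separation = max(sep), pressure = pressure, depth = depth)
}

#' Ground-truth completion probability of a play
#'
#' Evaluates the generator's logistic ground truth (weights over max receiver
#' separation, QB pressure distance and depth of the deepest receiver) at the
#' pass frame.
#'
#' @param play a generated `gh_play` in field coordinates.
#' @param config the [synth_config()] holding weights and bias.
#' @return probability in (0, 1).
#' @export
completion_truth_probability <- function(play, config = synth_config()) {
  f <- completion_truth_features(play)
  w <- config$completion_weights[names(f)]
  sigmoid(sum(w * f) + config$completion_bias)
}

#' Generate a synthetic play collection
#'
#' Draws `n_plays` independent plays; play i uses a child seed derived from
#' `seed`, so the collection is a deterministic function of (config, seed).
#' Weeks are assigned round-robin over 1-17 so week-based splitting is
#' exercised. Outcome labels are Bernoulli draws from each play's stored
#' ground-truth completion probability.
#'
#' @param n_plays number of plays.
#' @param config a [synth_config()].
#' @param seed integer master seed.
#' @return a `gh_collection`; per-play truth probabilities are in
#'   `attr(, "truth_prob")` and labels (1 = complete) in `attr(, "labels")`.
#' @export
generate_dataset <- function(n_plays, config = synth_config(), seed = 1L) {
  seeds <- derive_seeds(seed, n_plays)
  plays <- vector("list", n_plays)
  for (i in seq_len(n_plays)) {
    wk <- ((i - 1L) %% 17L) + 1L
    plays[[i]] <- generate_play(config, seed = seeds[i], week = wk,
                                game_id = sprintf("%d", 1000L + wk),
                                play_id = sprintf("%d", i))
  }
  coll <- play_collection(plays)
  attr(coll, "truth_prob") <- vapply(plays, function(p) p$truth_prob, numeric(1))
  attr(coll, "labels") <- as.integer(
    vapply(plays, function(p) identical(p$meta$pass_outcome, "complete"), logical(1))
  )
  coll
}

#' Swap two man-coverage assignments mid-play
#'
#' Re-simulates the play's scripted defense with the two given defenders
#' exchanging their coverage duties at `t_switch` (frame index on the play's
#' grid). The offense, metadata and RNG draws for the noise are re-derived
#' from the play's stored script; the ground-truth role sequence is updated.
#'
#' @param play a generated man-coverage `gh_play` in field coordinates.
#' @param t_switch frame id at which the swap happens; must lie inside the
#'   snap-to-pass window.
#' @param pair integer pair of man-defender indices (1-5) to swap.
#' @param seed seed for the re-simulated reaction noise.
#' @return the play with re-simulated defense and updated `$role_truth`.
#' @export
inject_role_switch <- function(play, t_switch, pair = c(1L, 2L), seed = 1L) {
  stopifnot(!is.null(play$script), identical(play$script$coverage, "man"))
  snap <- play$events[["ball_snap"]]
  pass <- play$events[["pass_forward"]]
  if (t_switch < snap || t_switch > pass) {
    stop_play(play, "t_switch outside the snap-to-pass window")
  }
  script <- play$script
  script$switch_frame <- match(t_switch, play$frames)
  script$switch_pair <- as.integer(pair)
  n_f <- length(play$frames)
  rids <- receiver_ids(play)
  rec_xy <- array(0, c(n_f, 5, 2))
  rec_xy[, , 1] <- play$x[, rids]
  rec_xy[, , 2] <- play$y[, rids]
  ps <- match(snap, play$frames) - 1L
  set.seed(seed)
  def_xy <- simulate_defense(script, rec_xy, ps, n_f, 0.1)
  dids <- defense_ids(play)
  play$x[, dids] <- def_xy[, , 1]
  play$y[, dids] <- def_xy[, , 2]
  disp <- rbind(matrix(0, 1, 7), sqrt(diff(def_xy[, , 1])^2 + diff(def_xy[, , 2])^2))
  play$s[, dids] <- disp / 0.1
  play$script <- script
  play$role_truth <- role_truth_matrix(script, n_f)
  play
}
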