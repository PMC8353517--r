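# Per-frame model input: 7 defender positions in role order, QB position,
# 5 receiver positions, ball position, then (yards_to_go, down, absolute
# field position) — 31 features.
GHOST_STATE_LEN <- 31L

ghost_def_cols <- function(r) c(2L * r - 1L, 2L * r) # role r's (x, y) columns

# Rescale 2 x B displacement columns whose norm exceeds the per-frame cap.
cap_step <- function(d, cap) {
  nrm <- sqrt(colSums(d^2))
  over <- nrm > cap
  if (any(over)) d[, over] <- d[, over, drop = FALSE] * rep(cap / nrm[over], each = 2)
  d
}

#' Ghosting configuration
#'
#' Training hyperparameters for the per-role recurrent policies: two LSTM
#' layers of `hidden` units with a 2-d linear head predicting the next-step
#' displacement, trained with Adam.
#'
#' @param hidden LSTM units per layer (128 in the reference architecture;
#'   smaller values train faster on small fixtures).
#' @param n_layers recurrent layers.
#' @param lr Adam learning rate.
#' @param pretrain_epochs teacher-forced pretraining epochs.
#' @param dagger_iterations,dagger_epochs rollout-aggregation iterations and
#'   refit epochs per iteration for single-policy training.
#' @param joint_iterations,joint_epochs same for joint training.
#' @param window_len,window_stride training-window split (25-frame windows,
#'   stride 15, i.e. 10-frame overlap).
#' @param batch_windows windows per gradient batch.
#' @param max_step physical cap (yards per 0.1 s frame) applied to expert
#'   corrections and rolled-out policy steps; 1.1 matches the 11 yd/s speed
#'   cap of the tracking data.
#' @param seed master seed.
#' @return a `gh_ghost_config`.
#' @export
ghost_config <- function(hidden = 128L, n_layers = 2L, lr = 2e-3,
                         pretrain_epochs = 30L, dagger_iterations = 5L,
                         dagger_epochs = 4L, joint_iterations = 2L,
                         joint_epochs = 4L, window_len = 25L,
                         window_stride = 15L, batch_windows = 32L,
                         max_step = 1.1, seed = 1L) {
  structure(
    list(hidden = as.integer(hidden), n_layers = as.integer(n_layers), lr = lr,
         pretrain_epochs = as.integer(pretrain_epochs),
         dagger_iterations = as.integer(dagger_iterations),
         dagger_epochs = as.integer(dagger_epochs),
         joint_iterations = as.integer(joint_iterations),
         joint_epochs = as.integer(joint_epochs),
         window_len = as.integer(window_len),
         window_stride = as.integer(window_stride),
         batch_windows = as.integer(batch_windows),
         max_step = max_step, seed = as.integer(seed)),
    class = "gh_ghost_config"
  )
}

#' Prepare plays for ghost training
#'
#' Normalizes and clips each play and attaches the static role ordering of
#' its defenders (and, optionally, receivers) so feature-vector slots have a
#' consistent tactical meaning across plays.
#'
#' @param plays list of `gh_play`s or a `gh_collection`.
#' @param static_roles a fitted defense `gh_static_roles` model.
#' @param receiver_roles optional receiver `gh_static_roles` model.
#' @return list of prepared plays.
#' @export
prepare_ghost_plays <- function(plays, static_roles, receiver_roles = NULL) {
  plays <- as_play_list(plays)
  lapply(plays, function(p) {
    p <- clip_to_pass_window(normalize_play(p))
    a <- assign_roles_static(static_roles, p)
    p$defender_role_ids <- a$entity_ids[match(seq_len(static_roles$k), a$mapping)]
    if (!is.null(receiver_roles)) {
      ar <- assign_roles_static(receiver_roles, p)
      p$receiver_role_ids <- ar$entity_ids[match(seq_len(receiver_roles$k), ar$mapping)]
    } else {
      p$receiver_role_ids <- receiver_ids(p)
    }
    p
  })
}

# Full-play state matrix (n_frames x 31) under a given defender role order.
ghost_state_matrix <- function(play, def_ids = play$defender_role_ids,
                               rec_ids = play$receiver_role_ids) {
  if (is.null(def_ids)) stop_play(play, "play has no defender role order; run prepare_ghost_plays")
  dj <- match(def_ids, play$roster$entity_id)
  rj <- match(rec_ids %||% receiver_ids(play), play$roster$entity_id)
  qj <- match(qb_id(play), play$roster$entity_id)
  bj <- match(ball_id(play), play$roster$entity_id)
  n_f <- length(play$frames)
  S <- matrix(0, n_f, GHOST_STATE_LEN)
  for (r in 1:7) S[, ghost_def_cols(r)] <- cbind(play$x[, dj[r]], play$y[, dj[r]])
  S[, 15:16] <- cbind(play$x[, qj], play$y[, qj])
  for (k in 1:5) S[, 17L + 2L * (k - 1L) + 0:1] <- cbind(play$x[, rj[k]], play$y[, rj[k]])
  S[, 27:28] <- cbind(play$x[, bj], play$y[, bj])
  S[, 29] <- play$meta$yards_to_go
  S[, 30] <- play$meta$down
  S[, 31] <- play$meta$absolute_field_position
  S
}

#' Split plays into overlapping training windows
#'
#' Windows of `window_len` frames at stride `window_stride` (10-frame
#' overlap with the defaults); a trailing remainder shorter than the window
#' length is kept as a final shorter window. Each window records the play
#' index, inclusive frame-index range and its defender role order.
#'
#' @param plays prepared plays (see [prepare_ghost_plays()]).
#' @param window_len,window_stride window geometry.
#' @return list of window descriptors.
#' @export
make_training_windows <- function(plays, window_len = 25L, window_stride = 15L) {
  out <- list()
  for (i in seq_along(plays)) {
    L <- length(plays[[i]]$frames)
    bounds <- window_bounds(L, window_len, window_stride)
    for (b in bounds) {
      out[[length(out) + 1L]] <- list(
        play = i, start = b[1], end = b[2],
        def_ids = plays[[i]]$defender_role_ids
      )
    }
  }
  out
}

# Inclusive 1-based (start, end) pairs: full windows while they fit, then one
# trailing shorter window reaching the end.
window_bounds <- function(L, len = 25L, stride = 15L) {
  bounds <- list()
  s <- 1L
  repeat {
    e <- min(s + len - 1L, L)
    bounds[[length(bounds) + 1L]] <- c(s, e)
    if (e >= L) break
    s <- s + stride
  }
  bounds
}

# Stack windows into padded tensors: raw states (31 x B x Tmax), per-role
# displacement targets (2 x B x Tmax) and a (B x Tmax) validity mask.
# Inputs run over frames start..end-1.
window_tensors <- function(plays, windows) {
  B <- length(windows)
  lens <- vapply(windows, function(w) w$end - w$start, integer(1)) # input steps
  Tmax <- max(lens)
  raw <- array(0, c(GHOST_STATE_LEN, B, Tmax))
  nxt <- array(0, c(GHOST_STATE_LEN, B, Tmax)) # state at t+1 (for targets)
  mask <- matrix(0, B, Tmax)
  for (b in seq_len(B)) {
    w <- windows[[b]]
    S <- ghost_state_matrix(plays[[w$play]], def_ids = w$def_ids)
    idx <- w$start:(w$end - 1L)
    raw[, b, seq_along(idx)] <- t(S[idx, , drop = FALSE])
    nxt[, b, seq_along(idx)] <- t(S[idx + 1L, , drop = FALSE])
    mask[b, seq_along(idx)] <- 1
  }
  targets <- lapply(1:7, function(r) {
    nxt[ghost_def_cols(r), , , drop = FALSE] - raw[ghost_def_cols(r), , , drop = FALSE]
  })
  list(raw = raw, targets = targets, mask = mask, lens = lens)
}

# Columns of the state holding (x, y) pairs of entities other than role r.
ghost_pos_pair_starts <- c(seq(1L, 13L, by = 2L), 15L, seq(17L, 25L, by = 2L), 27L)

# Role-centred policy input: every other entity's position becomes an offset
# from role r's own position; the own position stays absolute. This is an
# affine re-parametrisation of the same positional state that makes pursuit
# relations directly visible to the policy.
policy_input <- function(xraw, role) {
  own <- xraw[ghost_def_cols(role), , drop = FALSE]
  out <- xraw
  for (s in ghost_pos_pair_starts) {
    if (s == ghost_def_cols(role)[1L]) next
    out[s:(s + 1L), ] <- xraw[s:(s + 1L), , drop = FALSE] - own
  }
  out
}

# Per-role input standardisation moments over the teacher-forced windows.
ghost_norm_from_tensors <- function(tensors) {
  B <- dim(tensors$raw)[2]
  Tmax <- dim(tensors$raw)[3]
  lapply(1:7, function(r) {
    m <- matrix(0, GHOST_STATE_LEN, sum(tensors$mask))
    k <- 0L
    for (t in seq_len(Tmax)) {
      act <- which(tensors$mask[, t] > 0)
      if (!length(act)) next
      xin <- policy_input(matrix(tensors$raw[, , t], GHOST_STATE_LEN, B)[, act, drop = FALSE], r)
      m[, k + seq_along(act)] <- xin
      k <- k + length(act)
    }
    mu <- rowMeans(m)
    sd <- apply(m, 1L, stats::sd)
    sd[sd < 1e-6] <- 1
    list(mu = mu, sd = sd)
  })
}

#' Construct an untrained ghost model
#'
#' Seven per-role recurrent policies plus the role models. Policies are
#' created with seeded weights and trained by [pretrain_policies()],
#' [dagger_train_single()], [joint_train()] or [alternate_optimize()].
#'
#' @param static_roles fitted defense `gh_static_roles`.
#' @param receiver_roles optional receiver role model.
#' @param config a [ghost_config()].
#' @return a `gh_ghost_model`.
#' @export
ghost_model <- function(static_roles, receiver_roles = NULL,
                        config = ghost_config()) {
  policies <- lapply(1:7, function(r) {
    lstm_init(GHOST_STATE_LEN, hidden = config$hidden,
              n_layers = config$n_layers, out_dim = 2L,
              seed = config$seed + r)
  })
  structure(
    list(policies = policies, static_roles = static_roles,
         receiver_roles = receiver_roles, dynamic_roles = NULL,
         config = config, norm = NULL,
         manifest = list(phases = character(0), seeds = config$seed,
                         losses = list())),
    class = "gh_ghost_model"
  )
}

#' @export
print.gh_ghost_model <- function(x, ...) {
  cat(sprintf("<gh_ghost_model> 7 policies (%d x %d LSTM), phases: %s\n",
              x$config$n_layers, x$config$hidden,
              if (length(x$manifest$phases)) paste(x$manifest$phases, collapse = ",") else "untrained"))
  invisible(x)
}

# Teacher-forced batches for one role: role-centred standardized inputs.
chunk_batches <- function(tensors, role, max_b, norm) {
  B <- dim(tensors$raw)[2]
  Tmax <- dim(tensors$raw)[3]
  nr <- norm[[role]]
  X <- array(0, c(GHOST_STATE_LEN, B, Tmax))
  for (t in seq_len(Tmax)) {
    xin <- policy_input(matrix(tensors$raw[, , t], GHOST_STATE_LEN, B), role)
    X[, , t] <- (xin - nr$mu) / nr$sd
  }
  starts <- seq(1L, B, by = max_b)
  lapply(starts, function(s) {
    take <- s:min(s + max_b - 1L, B)
    list(X = X[, take, , drop = FALSE],
         target = tensors$targets[[role]][, take, , drop = FALSE],
         mask = tensors$mask[take, , drop = FALSE])
  })
}

#' Teacher-forced pretraining of all policies
#'
#' Trains each role's policy to predict the next-step displacement of its
#' defender from the ground-truth state sequence (perfect information, no
#' interaction). Also fits the feature standardisation used by all later
#' phases.
#'
#' @param model a `gh_ghost_model`.
#' @param plays prepared plays.
#' @param windows training windows from [make_training_windows()].
#' @param roles roles to train (default all 7).
#' @return the trained model with per-epoch losses in the manifest.
#' @export
pretrain_policies <- function(model, plays, windows, roles = 1:7) {
  if (!length(windows)) stop("no training windows", call. = FALSE)
  cfg <- model$config
  tensors <- window_tensors(plays, windows)
  if (is.null(model$norm)) model$norm <- ghost_norm_from_tensors(tensors)
  # staged learning-rate schedule: bulk of the epochs at the base rate, then
  # two refinement stages for a precise one-step map
  stages <- pretrain_stages(cfg$pretrain_epochs, cfg$lr)
  for (r in roles) {
    batches <- chunk_batches(tensors, r, cfg$batch_windows, model$norm)
    for (si in seq_along(stages)) {
      st <- stages[[si]]
      model$policies[[r]] <- lstm_fit(model$policies[[r]], batches,
                                      epochs = st$epochs, lr = st$lr,
                                      seed = cfg$seed + 17L * r + si)
    }
    model$manifest$losses[[paste0("pretrain_role", r)]] <-
      utils::tail(model$policies[[r]]$loss_trace, cfg$pretrain_epochs)
  }
  model$manifest$phases <- union(model$manifest$phases, "pretrain")
  model
}

pretrain_stages <- function(epochs, lr) {
  e1 <- max(1L, round(0.6 * epochs))
  e2 <- max(0L, round(0.25 * epochs))
  e3 <- max(0L, epochs - e1 - e2)
  st <- list(list(epochs = e1, lr = lr))
  if (e2 > 0L) st <- c(st, list(list(epochs = e2, lr = lr / 4)))
  if (e3 > 0L) st <- c(st, list(list(epochs = e3, lr = lr / 10)))
  st
}

# Batched policy rollout over windows. rolled_roles get their own predicted
# positions fed back; everything else stays ground truth. Returns per-role
# visited standardized states, expert displacement targets, and predicted
# positions.
rollout_windows <- function(model, tensors, rolled_roles) {
  cfg <- model$config
  B <- dim(tensors$raw)[2]
  Tmax <- dim(tensors$raw)[3]
  keys <- as.character(rolled_roles)
  states <- lapply(rolled_roles, function(r) lstm_zero_state(model$policies[[r]], B))
  names(states) <- keys
  cur <- lapply(rolled_roles, function(r) matrix(tensors$raw[ghost_def_cols(r), , 1], 2, B))
  names(cur) <- keys
  X_visited <- lapply(rolled_roles, function(r) array(0, c(GHOST_STATE_LEN, B, Tmax)))
  names(X_visited) <- keys
  exp_target <- lapply(rolled_roles, function(r) array(0, c(2, B, Tmax)))
  names(exp_target) <- keys
  pred_pos <- lapply(rolled_roles, function(r) array(0, c(2, B, Tmax)))
  names(pred_pos) <- keys
  for (t in seq_len(Tmax)) {
    xraw <- matrix(tensors$raw[, , t], GHOST_STATE_LEN, B)
    for (key in keys) xraw[ghost_def_cols(as.integer(key)), ] <- cur[[key]]
    for (r in rolled_roles) {
      key <- as.character(r)
      nr <- model$norm[[r]]
      xstd <- (policy_input(xraw, r) - nr$mu) / nr$sd
      X_visited[[key]][, , t] <- xstd
      truth_next <- matrix(tensors$raw[ghost_def_cols(r), , t], 2, B) +
        matrix(tensors$targets[[r]][, , t], 2, B)
      # expert correction: step from the predicted position toward the true
      # next position, capped at the physical per-frame speed limit
      exp_target[[key]][, , t] <- cap_step(truth_next - cur[[key]], cfg$max_step)
      out <- lstm_step(model$policies[[r]], model$policies[[r]]$params,
                       xstd, states[[key]])
      states[[key]] <- out$state
      cur[[key]] <- cur[[key]] + cap_step(out$y, cfg$max_step)
      pred_pos[[key]][, , t] <- cur[[key]]
    }
  }
  list(X = X_visited, targets = exp_target, pred_pos = pred_pos,
       mask = tensors$mask)
}

#' Single-policy rollout training with dataset aggregation
#'
#' For the chosen role, repeatedly rolls the policy out over the training
#' windows with its own predicted positions substituted into the input
#' (everyone else keeps ground truth), records the visited states with the
#' expert correction (displacement from the predicted position to the true
#' next position) and refits the policy on the aggregate of the
#' teacher-forced data and all collected rollout data.
#'
#' @param model a pretrained `gh_ghost_model`.
#' @param role role index 1-7.
#' @param plays prepared plays.
#' @param windows training windows.
#' @return the model; the manifest records aggregate sizes and losses per
#'   iteration.
#' @export
dagger_train_single <- function(model, role, plays, windows) {
  if (!(role %in% 1:7)) stop("role out of range", call. = FALSE)
  if (is.null(model$norm)) stop("pretrain before DAgger", call. = FALSE)
  cfg <- model$config
  tensors <- window_tensors(plays, windows)
  aggregate <- chunk_batches(tensors, role, cfg$batch_windows, model$norm)
  agg_sizes <- sum(tensors$mask)
  for (it in seq_len(cfg$dagger_iterations)) {
    ro <- rollout_windows(model, tensors, rolled_roles = role)
    new_batches <- split_rollout_batches(ro, role, cfg$batch_windows)
    aggregate <- c(aggregate, new_batches)
    agg_sizes <- c(agg_sizes, utils::tail(agg_sizes, 1) + sum(ro$mask))
    model$policies[[role]] <- lstm_fit(model$policies[[role]], aggregate,
                                       epochs = cfg$dagger_epochs, lr = cfg$lr / 2,
                                       seed = cfg$seed + 1000L * role + it)
  }
  model$manifest$phases <- union(model$manifest$phases, "dagger")
  model$manifest$losses[[paste0("dagger_role", role)]] <-
    utils::tail(model$policies[[role]]$loss_trace,
                cfg$dagger_iterations * cfg$dagger_epochs)
  model$manifest$dagger_aggregate_sizes <- agg_sizes
  model
}

split_rollout_batches <- function(ro, role, max_b) {
  key <- as.character(role)
  B <- dim(ro$X[[key]])[2]
  starts <- seq(1L, B, by = max_b)
  lapply(starts, function(s) {
    take <- s:min(s + max_b - 1L, B)
    list(X = ro$X[[key]][, take, , drop = FALSE],
         target = ro$targets[[key]][, take, , drop = FALSE],
         mask = ro$mask[take, , drop = FALSE])
  })
}

#' Joint rollout training of all policies
#'
#' Rolls out all seven policies together: every defender's input position is
#' imputed from its own policy, so each policy trains against states that
#' simulate the complete ghosted defense (offense and ball stay ground
#' truth). Aggregation and refitting as in [dagger_train_single()], applied
#' to every role.
#'
#' @param model a `gh_ghost_model` (pretrained, typically DAgger-trained).
#' @param plays prepared plays.
#' @param windows training windows.
#' @return the model.
#' @export
joint_train <- function(model, plays, windows) {
  if (is.null(model$norm)) stop("pretrain before joint training", call. = FALSE)
  cfg <- model$config
  tensors <- window_tensors(plays, windows)
  aggregates <- lapply(1:7, function(r) chunk_batches(tensors, r, cfg$batch_windows, model$norm))
  for (it in seq_len(cfg$joint_iterations)) {
    ro <- rollout_windows(model, tensors, rolled_roles = 1:7)
    for (r in 1:7) {
      aggregates[[r]] <- c(aggregates[[r]], split_rollout_batches(ro, r, cfg$batch_windows))
      model$policies[[r]] <- lstm_fit(model$policies[[r]], aggregates[[r]],
                                      epochs = cfg$joint_epochs, lr = cfg$lr / 2,
                                      seed = cfg$seed + 7000L + 31L * r + it)
    }
  }
  model$manifest$phases <- union(model$manifest$phases, "joint")
  model
}

#' Roll out ghost trajectories for plays
#'
#' Starting from the true defender positions at the snap, each per-role
#' policy autoregressively produces that defender's position every 0.1 s up
#' to the pass frame; offense, ball and metadata inputs are the observed
#' ones. Returns copies of the plays with the rolled defenders' coordinates
#' replaced.
#'
#' @param model a trained `gh_ghost_model`.
#' @param plays prepared play or list of prepared plays.
#' @param roles roles to ghost (default all 7; others keep observed tracks).
#' @return a ghost play, or list of ghost plays.
#' @export
rollout <- function(model, plays, roles = 1:7) {
  single <- inherits(plays, "gh_play")
  if (single) plays <- list(plays)
  if (is.null(model$norm)) stop("model is untrained", call. = FALSE)
  windows <- lapply(seq_along(plays), function(i) {
    list(play = i, start = 1L, end = length(plays[[i]]$frames),
         def_ids = plays[[i]]$defender_role_ids)
  })
  tensors <- window_tensors(plays, windows)
  ro <- rollout_windows(model, tensors, rolled_roles = roles)
  ghosts <- plays
  for (i in seq_along(plays)) {
    p <- ghosts[[i]]
    L <- length(p$frames)
    for (r in roles) {
      id <- p$defender_role_ids[r]
      j <- match(id, p$roster$entity_id)
      path <- t(matrix(ro$pred_pos[[as.character(r)]][, i, seq_len(L - 1L)], 2, L - 1L))
      p$x[2:L, j] <- path[, 1]
      p$y[2:L, j] <- path[, 2]
      disp <- sqrt(diff(p$x[, j])^2 + diff(p$y[, j])^2)
      p$s[, j] <- c(p$s[1, j], disp / 0.1)
    }
    p$ghosted_roles <- roles
    ghosts[[i]] <- p
  }
  if (single) ghosts[[1L]] else ghosts
}

#' Window-level per-role rollout error
#'
#' Splits plays into training-length windows, assigns window roles either
#' statically (snap-formation assignment stored on the play) or dynamically
#' (Hungarian matching under the model's hidden Markov role model), rolls
#' all policies out within each window from the true start positions, and
#' reports the mean absolute error per role against the defender occupying
#' that role in that window. This is the coordination metric: a dynamic
#' assignment that relabels mid-play switches correctly yields consistent
#' targets and lower per-role error.
#'
#' @param model a trained `gh_ghost_model`.
#' @param plays prepared plays.
#' @param assignment `"static"` or `"dynamic"` (requires a fitted
#'   `model$dynamic_roles`).
#' @return list with `per_role` (named 7-vector, yards) and `overall`.
#' @export
window_rollout_mae <- function(model, plays, assignment = c("static", "dynamic")) {
  assignment <- match.arg(assignment)
  cfg <- model$config
  windows <- make_training_windows(plays, cfg$window_len, cfg$window_stride)
  if (assignment == "dynamic") {
    if (is.null(model$dynamic_roles)) stop("model has no dynamic role model", call. = FALSE)
    windows <- lapply(windows, function(w) {
      a <- assign_roles_dynamic(model$dynamic_roles, plays[[w$play]],
                                frame_idx = w$start:w$end)
      w$def_ids <- a$entity_ids[match(1:7, a$mapping)]
      w
    })
  }
  tensors <- window_tensors(plays, windows)
  ro <- rollout_windows(model, tensors, rolled_roles = 1:7)
  per_role <- vapply(1:7, function(r) {
    key <- as.character(r)
    truth <- tensors$raw[ghost_def_cols(r), , , drop = FALSE] +
      tensors$targets[[r]]
    err <- sqrt(colSums((ro$pred_pos[[key]] - truth)^2, dims = 1))
    sum(err * tensors$mask) / sum(tensors$mask)
  }, numeric(1))
  names(per_role) <- paste0("role", 1:7)
  list(per_role = per_role, overall = mean(per_role))
}

#' Alternating policy / role-assignment optimisation
#'
#' The coordination loop: train the policies with the role assignment fixed,
#' then fix the policies, refit the dynamic (hidden Markov) role model on
#' the defender trajectories and re-assign window roles by Hungarian
#' matching; repeat until the validation joint-rollout mean absolute error
#' stops improving by more than `tol` for a full cycle. The best-validation
#' model is returned.
#'
#' @param model an untrained `gh_ghost_model`.
#' @param plays prepared plays.
#' @param val_plays prepared validation plays for the stopping rule.
#' @param max_cycles upper bound on alternation cycles.
#' @param tol minimum MAE improvement counted as progress (yards).
#' @param phases which training phases to run inside each cycle
#'   (`"pretrain"` always runs in cycle 1).
#' @return the best-validation `gh_ghost_model`; the manifest records the
#'   per-cycle validation MAE.
#' @export
alternate_optimize <- function(model, plays, val_plays, max_cycles = 3L,
                               tol = 1e-3, phases = c("pretrain", "joint")) {
  cfg <- model$config
  windows <- make_training_windows(plays, cfg$window_len, cfg$window_stride)
  val_mae_trace <- numeric(0)
  best <- NULL
  for (cycle in seq_len(max_cycles)) {
    if (cycle == 1L) {
      model <- pretrain_policies(model, plays, windows)
    } else {
      # refit policies on the re-assigned windows with the same budget
      tensors <- window_tensors(plays, windows)
      stages <- pretrain_stages(cfg$pretrain_epochs, cfg$lr / 2)
      for (r in 1:7) {
        batches <- chunk_batches(tensors, r, cfg$batch_windows, model$norm)
        for (si in seq_along(stages)) {
          model$policies[[r]] <- lstm_fit(model$policies[[r]], batches,
                                          epochs = stages[[si]]$epochs,
                                          lr = stages[[si]]$lr,
                                          seed = cfg$seed + 300L * cycle + 11L * si + r)
        }
      }
    }
    if ("joint" %in% phases) model <- joint_train(model, plays, windows)
    mae <- window_rollout_mae(
      model, val_plays,
      assignment = if (is.null(model$dynamic_roles)) "static" else "dynamic"
    )$overall
    val_mae_trace <- c(val_mae_trace, mae)
    if (is.null(best) || mae < best$mae - 0) best <- list(model = model, mae = mae)
    improved <- cycle == 1L || (val_mae_trace[cycle - 1L] - mae) > tol
    if (!improved || cycle == max_cycles) break
    # role-model update: fix policies, refit the HMM, re-assign windows
    model$dynamic_roles <- fit_dynamic_role_model(plays, n_states = 7L,
                                                  seed = cfg$seed + cycle)
    windows <- lapply(windows, function(w) {
      a <- assign_roles_dynamic(model$dynamic_roles, plays[[w$play]],
                                frame_idx = w$start:w$end)
      w$def_ids <- a$entity_ids[match(1:7, a$mapping)]
      w
    })
  }
  best$model$manifest$val_mae_trace <- val_mae_trace
  best$model$manifest$phases <- union(best$model$manifest$phases, "alternating")
  best$model
}
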