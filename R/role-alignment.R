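#' Fit the static role model from snap formations
#'
#' Fits a Gaussian mixture over the snap-frame positions of one side of the
#' ball across plays, giving one mixture component ("role") per lineup slot.
#' Role labels are canonicalized by sorting the component means left-to-right
#' along x', then by y', so role indices are stable across refits.
#'
#' @param plays list of normalized `gh_play`s (or a `gh_collection`).
#' @param n_roles number of roles (7 for the defense, 5 for receivers).
#' @param side `"defense"` or `"receivers"`.
#' @param seed seed for the EM initialisation.
#' @param n_init number of independent EM runs (seeded restarts); the run
#'   with the highest final log-likelihood is kept, guarding against local
#'   optima that merge neighbouring lineup slots.
#' @param ... passed to the EM fitter (`max_iter`, `tol`, `reg`).
#' @return a `gh_static_roles` model with `means`, `covs`, `weights`,
#'   `loglik` trace.
#' @export
fit_static_role_model <- function(plays, n_roles = 7L, side = c("defense", "receivers"),
                                  seed = 1L, n_init = 5L, ...) {
  side <- match.arg(side)
  plays <- as_play_list(plays)
  if (length(plays) < n_roles) {
    stop("need at least as many plays as roles", call. = FALSE)
  }
  X <- do.call(rbind, lapply(plays, snap_positions, side = side))
  fits <- lapply(derive_seeds(seed, n_init), function(s) fit_gmm(X, n_roles, seed = s, ...))
  fit <- fits[[which.max(vapply(fits, function(f) utils::tail(f$loglik, 1), numeric(1)))]]
  ord <- order(fit$means[, 1], fit$means[, 2])
  fit$means <- fit$means[ord, , drop = FALSE]
  fit$covs <- fit$covs[, , ord, drop = FALSE]
  fit$weights <- fit$weights[ord]
  structure(c(fit, list(side = side)), class = "gh_static_roles")
}

as_play_list <- function(plays) {
  if (inherits(plays, "gh_collection")) plays$plays else plays
}

snap_positions <- function(play, side = "defense") {
  if (!isTRUE(play$normalized)) stop_play(play, "play must be normalized")
  snap_i <- event_index(play, "ball_snap")
  if (is.na(snap_i)) stop_play(play, "no ball_snap event")
  ids <- if (side == "defense") defense_ids(play) else receiver_ids(play)
  cbind(play$x[snap_i, ids], play$y[snap_i, ids])
}

#' Assign static roles to one play
#'
#' Builds the cost matrix `cost[i, j] =` negative log density of player i's
#' snap position under role j (mixture weights ignored: the assignment is a
#' bijection, so every role is used exactly once) and solves it with the
#' Hungarian algorithm.
#'
#' @param model a `gh_static_roles` model.
#' @param play a normalized `gh_play`.
#' @return a `gh_role_assignment`: `mapping[i]` is the role of the i-th
#'   player (in roster order for the model's side), plus the total `cost`
#'   and the player `entity_ids`.
#' @export
assign_roles_static <- function(model, play) {
  X <- snap_positions(play, model$side)
  ids <- if (model$side == "defense") defense_ids(play) else receiver_ids(play)
  if (nrow(X) != model$k) {
    stop_play(play, sprintf("expected %d players for side %s", model$k, model$side))
  }
  cost <- role_cost_matrix(model, X)
  sol <- solve_assignment(cost)
  structure(
    list(play_id = play$play_id, mapping = sol$assignment, cost = sol$cost,
         entity_ids = ids),
    class = "gh_role_assignment"
  )
}

role_cost_matrix <- function(model, X) {
  k <- model$k
  cost <- matrix(0, nrow(X), k)
  for (j in seq_len(k)) {
    det2 <- det(model$covs[, , j])
    if (!is.finite(det2) || det2 <= 1e-12) {
      stop("singular role covariance; refit with stronger regularization",
           call. = FALSE)
    }
    cost[, j] <- -dmvnorm_log(X, model$means[j, ], model$covs[, , j])
  }
  cost
}

#' Fit the dynamic role model (hidden Markov model)
#'
#' Baum-Welch fit of a Gaussian-emission HMM over per-frame (x', y') defender
#' positions, one observation sequence per defender trajectory per play
#' (snap-to-pass window). Emission states play the part of time-varying
#' roles. States are canonicalized like the static roles (emission means
#' sorted along x', then y').
#'
#' @param plays list of normalized, clipped `gh_play`s (or a collection).
#' @param n_states number of hidden states; defaults to 7, one per role.
#' @param seed seed for the initialisation.
#' @param ... passed to the Baum-Welch fitter.
#' @return a `gh_dynamic_roles` model.
#' @export
fit_dynamic_role_model <- function(plays, n_states = 7L, seed = 1L, ...) {
  plays <- as_play_list(plays)
  seqs <- unlist(lapply(plays, defender_sequences), recursive = FALSE)
  fit <- fit_hmm(seqs, n_states, seed = seed, ...)
  ord <- order(fit$emission_means[, 1], fit$emission_means[, 2])
  fit$emission_means <- fit$emission_means[ord, , drop = FALSE]
  fit$emission_covs <- fit$emission_covs[, , ord, drop = FALSE]
  fit$transition <- fit$transition[ord, ord, drop = FALSE]
  fit$initial <- fit$initial[ord]
  structure(fit, class = "gh_dynamic_roles")
}

defender_sequences <- function(play) {
  if (!isTRUE(play$normalized)) stop_play(play, "play must be normalized")
  win <- pass_window_indices(play)
  lapply(defense_ids(play), function(id) {
    j <- match(id, play$roster$entity_id)
    cbind(play$x[win, j], play$y[win, j])
  })
}

pass_window_indices <- function(play) {
  snap_i <- event_index(play, "ball_snap")
  pass_i <- event_index(play, "pass_forward")
  if (is.na(snap_i) || is.na(pass_i)) stop_play(play, "missing snap/pass events")
  snap_i:pass_i
}

#' Assign dynamic roles over a window
#'
#' For each defender trajectory in the window, computes the emission
#' log-likelihood of the trajectory under each hidden state and solves the
#' resulting negative-log-likelihood cost matrix with the Hungarian
#' algorithm, yielding a per-window bijection defenders -> roles.
#'
#' @param model a `gh_dynamic_roles` model.
#' @param play a normalized `gh_play`.
#' @param frame_idx integer indices (on the play's frame grid) of the window;
#'   defaults to the full snap-to-pass window.
#' @return a `gh_role_assignment`.
#' @export
assign_roles_dynamic <- function(model, play, frame_idx = NULL) {
  if (is.null(frame_idx)) frame_idx <- pass_window_indices(play)
  ids <- defense_ids(play)
  k <- model$n_states
  if (length(ids) != k) {
    stop_play(play, sprintf("dynamic assignment needs %d defenders", k))
  }
  cost <- matrix(0, length(ids), k)
  for (i in seq_along(ids)) {
    j <- match(ids[i], play$roster$entity_id)
    s <- cbind(play$x[frame_idx, j], play$y[frame_idx, j])
    for (r in seq_len(k)) {
      cost[i, r] <- -sum(dmvnorm_log(s, model$emission_means[r, ],
                                     model$emission_covs[, , r]))
    }
  }
  if (!all(is.finite(cost))) {
    stop("degenerate emission density in dynamic assignment", call. = FALSE)
  }
  sol <- solve_assignment(cost)
  structure(
    list(play_id = play$play_id, mapping = sol$assignment, cost = sol$cost,
         entity_ids = ids, frame_idx = frame_idx),
    class = "gh_role_assignment"
  )
}

#' Most likely role path of one defender trajectory
#'
#' Viterbi decoding of a defender's (x', y') sequence under the dynamic role
#' model; used to locate mid-play role switches.
#'
#' @param model a `gh_dynamic_roles` model.
#' @param play a normalized `gh_play`.
#' @param entity_id defender entity id.
#' @return integer state path over the snap-to-pass window.
#' @export
role_state_path <- function(model, play, entity_id) {
  win <- pass_window_indices(play)
  j <- match(entity_id, play$roster$entity_id)
  s <- cbind(play$x[win, j], play$y[win, j])
  hmm_viterbi(model, s)
}

#' Persist a role model as JSON
#'
#' @param model a `gh_static_roles` or `gh_dynamic_roles` model.
#' @param path output path.
#' @export
write_role_model <- function(model, path) {
  obj <- unclass(model)
  obj$.class <- class(model)[1L]
  for (nm in c("covs", "emission_covs")) {
    if (!is.null(obj[[nm]])) {
      obj[[nm]] <- lapply(seq_len(dim(obj[[nm]])[3]), function(j) obj[[nm]][, , j])
    }
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a role model written by [write_role_model()]
#'
#' @param path JSON path.
#' @return the role model.
#' @export
read_role_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$.class
  obj$.class <- NULL
  for (nm in c("covs", "emission_covs")) {
    if (!is.null(obj[[nm]])) {
      mats <- obj[[nm]]
      if (is.array(mats) && length(dim(mats)) == 3L) {
        # jsonlite may simplify to (k x d x d); restore (d x d x k)
        obj[[nm]] <- aperm(mats, c(2, 3, 1))
      } else {
        arr <- array(0, c(nrow(mats[[1]]), ncol(mats[[1]]), length(mats)))
        for (j in seq_along(mats)) arr[, , j] <- mats[[j]]
        obj[[nm]] <- arr
      }
    }
  }
  for (nm in c("means", "emission_means", "transition")) {
    if (!is.null(obj[[nm]])) obj[[nm]] <- as.matrix(obj[[nm]])
  }
  structure(obj, class = cls)
}
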