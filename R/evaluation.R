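#' Rollout error profile between an observed and a ghosted play
#'
#' Mean absolute position error (Euclidean distance, yards) between each
#' defender's observed and ghosted track: per 0.1 s timestep averaged over
#' defenders, and per role averaged over timesteps.
#'
#' @param true_play,ghost_play `gh_play`s on the same frame grid with the
#'   same defender role order.
#' @param roles roles to score (default all 7).
#' @return a `gh_rollout_errors` list: `per_timestep` (vector over the
#'   window), `per_role` (named vector), `overall_mae`.
#' @export
rollout_mae <- function(true_play, ghost_play, roles = 1:7) {
  if (!identical(true_play$frames, ghost_play$frames)) {
    stop("plays are on different time grids", call. = FALSE)
  }
  ids <- true_play$defender_role_ids %||% defense_ids(true_play)
  gids <- ghost_play$defender_role_ids %||% defense_ids(ghost_play)
  if (!identical(ids, gids)) stop("role alignment differs between plays", call. = FALSE)
  err <- sapply(roles, function(r) {
    j <- match(ids[r], true_play$roster$entity_id)
    sqrt((true_play$x[, j] - ghost_play$x[, j])^2 +
           (true_play$y[, j] - ghost_play$y[, j])^2)
  })
  err <- matrix(err, nrow = length(true_play$frames))
  per_timestep <- rowMeans(err)
  per_role <- colMeans(err)
  names(per_role) <- paste0("role", roles)
  structure(
    list(per_timestep = per_timestep, per_role = per_role,
         overall_mae = mean(err), time_s = (seq_along(per_timestep) - 1L) / 10),
    class = "gh_rollout_errors"
  )
}

# Average per-timestep error curve over plays of different lengths (mean of
# the curves available at each timestep).
aggregate_error_curves <- function(profiles) {
  L <- max(vapply(profiles, function(p) length(p$per_timestep), integer(1)))
  acc <- matrix(NA_real_, length(profiles), L)
  for (i in seq_along(profiles)) {
    v <- profiles[[i]]$per_timestep
    acc[i, seq_along(v)] <- v
  }
  colMeans(acc, na.rm = TRUE)
}

#' Completion-probability comparison of ghosted vs observed defense
#'
#' For each play, evaluates the trained pass-completion classifier on the
#' formation built from (a) the observed defense and (b) the ghost defense
#' (same offense), at the pass frame; reports the per-play probability
#' pairs, their Pearson correlation, and the per-timestep mean completion
#' probability curves obtained by evaluating the pass-frame feature builder
#' at every frame of the window.
#'
#' If the probability pairs have zero variance (e.g. ghosts identical to the
#' truth), the correlation is reported as a flagged `NA` rather than an
#' error (`r_defined = FALSE`).
#'
#' @param true_plays,ghost_plays matched lists of prepared plays (ghosts
#'   from [rollout()]); order defines the pairing.
#' @param classifier a trained `gh_classifier`.
#' @return a `gh_ghost_comparison` list: `pairs` (data.frame true/ghost),
#'   `pearson_r`, `r_defined`, `curve_true`, `curve_ghost` (per-timestep
#'   means).
#' @export
compare_completion <- function(true_plays, ghost_plays, classifier) {
  stopifnot(length(true_plays) == length(ghost_plays))
  p_true <- vapply(true_plays, play_completion_prob, numeric(1), classifier = classifier)
  p_ghost <- vapply(ghost_plays, play_completion_prob, numeric(1), classifier = classifier)
  r_defined <- stats::sd(p_true) > 1e-12 && stats::sd(p_ghost) > 1e-12
  r <- if (r_defined) stats::cor(p_true, p_ghost) else NA_real_
  curves_t <- lapply(true_plays, play_completion_curve, classifier = classifier)
  curves_g <- lapply(ghost_plays, play_completion_curve, classifier = classifier)
  structure(
    list(pairs = data.frame(true = p_true, ghost = p_ghost),
         pearson_r = r, r_defined = r_defined,
         curve_true = aggregate_curves(curves_t),
         curve_ghost = aggregate_curves(curves_g)),
    class = "gh_ghost_comparison"
  )
}

play_completion_prob <- function(play, classifier) {
  predict_proba(classifier, build_feature_vector(play))
}

play_completion_curve <- function(play, classifier) {
  X <- t(vapply(seq_along(play$frames), function(t) build_feature_vector(play, frame_idx = t),
                numeric(PASS_FEATURE_LEN)))
  predict_proba(classifier, X)
}

aggregate_curves <- function(curves) {
  L <- max(lengths(curves))
  acc <- matrix(NA_real_, length(curves), L)
  for (i in seq_along(curves)) acc[i, seq_along(curves[[i]])] <- curves[[i]]
  colMeans(acc, na.rm = TRUE)
}

#' Base-graphics plot of a rollout error curve
#'
#' @param profile output of [rollout_mae()] or a numeric per-timestep curve.
#' @param ... passed to [plot()].
#' @export
plot_rollout_error <- function(profile, ...) {
  v <- if (inherits(profile, "gh_rollout_errors")) profile$per_timestep else profile
  graphics::plot((seq_along(v) - 1) / 10, v, type = "l", xlab = "time since snap (s)",
                 ylab = "mean absolute error (yards)", ...)
}
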