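# Shared fixtures, built once per test run and cached.
.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# Small default-config collection (20 plays).
fx_coll20 <- function() fx_get("coll20", function() generate_dataset(20, seed = 101))

# Normalized + clipped versions of the same plays.
fx_norm20 <- function() fx_get("norm20", function() {
  lapply(fx_coll20()$plays, function(p) clip_to_pass_window(normalize_play(p)))
})

# Static role model over a 150-play season (defaults).
fx_static_roles <- function() fx_get("static_roles", function() {
  coll <- generate_dataset(150, seed = 202)
  plays <- lapply(coll$plays, function(p) clip_to_pass_window(normalize_play(p)))
  fit_static_role_model(plays, n_roles = 7L, seed = 3)
})

# Canonical generator slot centers in normalized coordinates: five press
# corners 6 yards past the line at the receiver lanes, two safeties at 13.
# In normalized coordinates the defense side is negative y'.
fx_slot_centers <- function() {
  lanes <- c(6, 16.5, 26.65, 36.8, 47.3)
  rbind(cbind(lanes, -6), cbind(c(17.5, 35.8), -13))
}

# Ground-truth role bijection of a play's defenders in normalized space:
# defender j was generated at slot j in FIELD y order; left-directed plays
# mirror the width axis, which (for the symmetric lanes) maps corner slot j
# to slot 6-j and swaps the two safety slots.
fx_truth_slots <- function(play) {
  if (identical(play$meta$play_direction, "right")) c(1:5, 6, 7) else c(5:1, 7, 6)
}

# Brute-force AUROC via pairwise concordance.
fx_auroc_concordance <- function(p, y) {
  pos <- p[y == 1]
  neg <- p[y != 1]
  mean(outer(pos, neg, ">")) + 0.5 * mean(outer(pos, neg, "=="))
}

# Numerical gradient of scalar function f at x (vector), central differences.
fx_num_grad <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (k in seq_along(x)) {
    xp <- x; xp[k] <- x[k] + eps
    xm <- x; xm[k] <- x[k] - eps
    g[k] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Rate at which static GMM+Hungarian assignment recovers the generating
# formation bijection over plays (slot correspondence fixed by matching the
# model's canonical role means to the generator's slot centers).
fx_static_recovery_rate <- function(model, plays) {
  centers <- fx_slot_centers()
  corr <- solve_assignment(as.matrix(stats::dist(rbind(model$means, centers)))[1:7, 8:14])
  slot_of_role <- corr$assignment
  hits <- vapply(plays, function(p) {
    a <- assign_roles_static(model, p)
    all(slot_of_role[a$mapping] == fx_truth_slots(p))
  }, logical(1))
  mean(hits)
}
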