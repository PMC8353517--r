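#' @section Play representation:
#' A play is stored column-aligned on a common frame grid: `frames` is the
#' vector of frame ids, and `x`, `y`, `s`, `o` are (n_frames x n_entities)
#' matrices whose columns follow `roster$entity_id`. Gaps (an entity missing
#' from a frame) are NA. Events map event names to frame ids.
#' @name ghostr-play
#' @keywords internal
NULL

new_play <- function(play_id, game_id, week, frames, roster, x, y, s, o,
                     events, meta, normalized = FALSE, transform = NULL) {
  structure(
    list(
      play_id = play_id, game_id = game_id, week = week,
      frames = as.integer(frames), roster = roster,
      x = x, y = y, s = s, o = o,
      events = events, meta = meta,
      normalized = normalized, transform = transform
    ),
    class = "gh_play"
  )
}

#' @export
print.gh_play <- function(x, ...) {
  cat(sprintf(
    "<gh_play %s/%s> %d frames, %d defenders, %d offense, %s coords\n",
    x$game_id, x$play_id, length(x$frames),
    sum(x$roster$team == "defense"), sum(x$roster$team == "offense"),
    if (x$normalized) "normalized" else "field"
  ))
  invisible(x)
}

#' Build a play collection
#'
#' @param plays list of plays.
#' @param split optional character vector of split labels per play.
#' @return a `gh_collection`.
#' @export
play_collection <- function(plays, split = NULL) {
  structure(
    list(plays = plays, split = split, split_mode = NULL, split_seed = NULL),
    class = "gh_collection"
  )
}

#' @export
print.gh_collection <- function(x, ...) {
  cat(sprintf("<gh_collection> %d plays", length(x$plays)))
  if (!is.null(x$split)) cat(" | split:", paste(names(table(x$split)), table(x$split), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' @export
length.gh_collection <- function(x) length(x$plays)

defense_ids <- function(play) play$roster$entity_id[play$roster$team == "defense"]
offense_ids <- function(play) play$roster$entity_id[play$roster$team == "offense"]
qb_id <- function(play) {
  ids <- play$roster$entity_id[play$roster$team == "offense" & play$roster$position == "QB"]
  if (length(ids) != 1L) stop_play(play, "expected exactly one quarterback")
  ids
}
receiver_ids <- function(play) setdiff(offense_ids(play), qb_id(play))
ball_id <- function(play) play$roster$entity_id[play$roster$team == "ball"]

entity_xy <- function(play, id, frame_idx = NULL) {
  j <- match(id, play$roster$entity_id)
  if (is.null(frame_idx)) {
    cbind(play$x[, j], play$y[, j])
  } else {
    c(play$x[frame_idx, j], play$y[frame_idx, j])
  }
}

event_index <- function(play, name) {
  f <- play$events[[name]]
  if (is.null(f) || is.na(f)) return(NA_integer_)
  match(f, play$frames)
}

#' Read tracking data in the Big Data Bowl 2021 CSV dialect
#'
#' Parses one or more `weekN.csv` tracking files plus the `plays.csv`
#' (per-play metadata) and optional `games.csv` (week lookup) companions into
#' a play collection. Entities are time-aligned on `frameId`; entities absent
#' from a frame are recorded as NA gaps. Rows with missing or non-numeric
#' coordinates are rejected with row-level diagnostics (attribute
#' `"bad_rows"`). Plays without a `ball_snap` event are retained but flagged
#' unusable (`play$usable == FALSE`).
#'
#' @param csv_paths character vector of tracking CSV paths.
#' @param plays_path path to `plays.csv` with columns gameId, playId, down,
#'   yardsToGo, absoluteYardlineNumber, passResult.
#' @param games_path optional path to `games.csv` with gameId, week.
#' @return a `gh_collection`.
#' @export
read_tracking <- function(csv_paths, plays_path, games_path = NULL) {
  need <- c("x", "y", "s", "o", "event", "nflId", "frameId", "playId",
            "gameId", "team", "position", "playDirection")
  tr <- data.table::rbindlist(
    lapply(csv_paths, data.table::fread),
    use.names = TRUE, fill = TRUE
  )
  missing_cols <- setdiff(need, names(tr))
  if (length(missing_cols)) {
    stop("tracking files missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- !is.finite(tr$x) | !is.finite(tr$y) | tr$x < 0 | tr$x > FIELD_LENGTH |
    tr$y < 0 | tr$y > FIELD_WIDTH
  bad_rows <- NULL
  if (any(bad)) {
    bad_rows <- data.table::as.data.table(tr[bad, c("gameId", "playId", "frameId", "nflId")])
    bad_rows$reason <- "coordinate missing or out of field bounds"
    tr <- tr[!bad, ]
  }
  pm <- data.table::fread(plays_path)
  weeks <- NULL
  if (!is.null(games_path)) weeks <- data.table::fread(games_path)

  keys <- unique(tr[, c("gameId", "playId")])
  plays <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    g <- keys$gameId[i]
    p <- keys$playId[i]
    rows <- tr[tr$gameId == g & tr$playId == p, ]
    meta_row <- pm[pm$gameId == g & pm$playId == p, ]
    week <- if (!is.null(weeks)) weeks$week[match(g, weeks$gameId)] else NA_integer_
    plays[[i]] <- build_play_from_rows(rows, meta_row, week)
  }
  coll <- play_collection(plays)
  attr(coll, "bad_rows") <- bad_rows
  coll
}

build_play_from_rows <- function(rows, meta_row, week) {
  rows <- rows[order(rows$frameId, rows$nflId), ]
  frames <- sort(unique(rows$frameId))
  ball <- rows$team == "football"
  qb_team <- unique(rows$team[!ball & rows$position == "QB"])
  teams <- setdiff(unique(rows$team), "football")
  off_team <- if (length(qb_team) == 1L) qb_team else teams[1L]
  def_team <- setdiff(teams, off_team)
  ent <- unique(rows[, c("nflId", "team", "position")])
  ent$entity_id <- as.character(ent$nflId)
  ent$side <- ifelse(ent$team == "football", "ball",
                     ifelse(ent$team == off_team, "offense", "defense"))
  # roster order: defense, offense (QB first), ball — stable by entity id
  ord <- order(match(ent$side, c("defense", "offense", "ball")),
               ent$position != "QB", ent$entity_id)
  ent <- ent[ord, ]
  roster <- data.frame(
    entity_id = ent$entity_id, team = ent$side, position = ent$position,
    stringsAsFactors = FALSE
  )
  n_f <- length(frames)
  n_e <- nrow(roster)
  mk <- function() matrix(NA_real_, n_f, n_e, dimnames = list(NULL, roster$entity_id))
  x <- mk(); y <- mk(); s <- mk(); o <- mk()
  fi <- match(rows$frameId, frames)
  ei <- match(as.character(rows$nflId), roster$entity_id)
  idx <- cbind(fi, ei)
  x[idx] <- rows$x
  y[idx] <- rows$y
  s[idx] <- rows$s
  o[idx] <- rows$o
  ev_rows <- rows[!is.na(rows$event) & rows$event != "" & rows$event != "None", ]
  events <- list()
  for (e in unique(ev_rows$event)) {
    events[[e]] <- min(ev_rows$frameId[ev_rows$event == e])
  }
  outcome <- NA_character_
  meta <- list()
  if (nrow(meta_row)) {
    outcome <- switch(as.character(meta_row$passResult[1L]),
                      C = "complete", I = "incomplete", IN = "intercepted",
                      NA_character_)
    meta <- list(
      down = meta_row$down[1L],
      yards_to_go = meta_row$yardsToGo[1L],
      line_of_scrimmage_x = meta_row$absoluteYardlineNumber[1L],
      play_direction = rows$playDirection[1L],
      pass_outcome = outcome
    )
    meta$absolute_field_position <- if (identical(meta$play_direction, "right")) {
      (FIELD_LENGTH - 10) - meta$line_of_scrimmage_x
    } else {
      meta$line_of_scrimmage_x - 10
    }
  }
  play <- new_play(
    play_id = as.character(rows$playId[1L]), game_id = as.character(rows$gameId[1L]),
    week = week, frames = frames, roster = roster,
    x = x, y = y, s = s, o = o, events = events, meta = meta
  )
  play$usable <- !is.null(events[["ball_snap"]])
  play$has_pass <- !is.null(events[["pass_forward"]])
  play
}

#' Filter a collection to modelable pass plays
#'
#' Keeps plays with exactly 7 tracked defenders and 6 tracked offensive
#' players (QB + 5 receivers), both a `ball_snap` and a `pass_forward` event
#' in the right order, no sack and no handoff, and no frame gaps for any
#' rostered entity inside the snap-to-pass window. Idempotent; records
#' before/after counts in attribute `"filter_counts"`.
#'
#' @param collection a `gh_collection`.
#' @return the filtered collection.
#' @export
filter_plays <- function(collection) {
  keep <- vapply(collection$plays, play_passes_filter, logical(1))
  out <- play_collection(collection$plays[keep],
                         split = collection$split[keep])
  out$split_mode <- collection$split_mode
  out$split_seed <- collection$split_seed
  attr(out, "filter_counts") <- c(before = length(collection$plays),
                                  after = sum(keep))
  out
}

play_passes_filter <- function(play) {
  ev <- play$events
  if (is.null(ev[["ball_snap"]]) || is.null(ev[["pass_forward"]])) return(FALSE)
  if (ev[["pass_forward"]] < ev[["ball_snap"]]) return(FALSE)
  if (!is.null(ev[["qb_sack"]]) || !is.null(ev[["handoff"]])) return(FALSE)
  if (sum(play$roster$team == "defense") != 7L) return(FALSE)
  if (sum(play$roster$team == "offense") != 6L) return(FALSE)
  if (sum(play$roster$team == "offense" & play$roster$position == "QB") != 1L) return(FALSE)
  win <- which(play$frames >= ev[["ball_snap"]] & play$frames <= ev[["pass_forward"]])
  if (!length(win)) return(FALSE)
  players <- play$roster$team != "ball"
  !anyNA(play$x[win, players]) && !anyNA(play$y[win, players])
}

#' Normalise a play to scrimmage-line coordinates
#'
#' Applies the rigid transform that places the line of scrimmage on the new
#' x'-axis (y' = 0), with the offensive backfield at positive y' and the
#' offense advancing toward negative y'. Left- and right-directed plays map
#' to one canonical handedness (the offense's right sideline always lands at
#' x' = 0). The transform and its inverse are stored on the play; applying
#' [denormalize_play()] recovers the original coordinates.
#'
#' @param play a `gh_play` with `line_of_scrimmage_x` and `play_direction`.
#' @return the normalized play.
#' @export
normalize_play <- function(play) {
  if (isTRUE(play$normalized)) return(play)
  los <- play$meta$line_of_scrimmage_x
  dir <- play$meta$play_direction
  if (is.null(los) || is.null(dir) || is.na(los) || is.na(dir)) {
    stop_play(play, "missing line_of_scrimmage_x or play_direction; cannot normalize")
  }
  # Both maps are pure rotations (det +1):
  #   right: (x, y) -> (y, los - x)          offense backfield x < los -> y' > 0
  #   left:  (x, y) -> (W - y, x - los)      offense backfield x > los -> y' > 0
  if (identical(dir, "right")) {
    A <- matrix(c(0, -1, 1, 0), 2, 2)       # columns: image of e_x, e_y
    b <- c(0, los)
    dtheta <- -90
  } else if (identical(dir, "left")) {
    A <- matrix(c(0, 1, -1, 0), 2, 2)
    b <- c(FIELD_WIDTH, -los)
    dtheta <- 90
  } else {
    stop_play(play, sprintf("unknown play_direction '%s'", dir))
  }
  new_x <- A[1, 1] * play$x + A[1, 2] * play$y + b[1]
  new_y <- A[2, 1] * play$x + A[2, 2] * play$y + b[2]
  play$x <- new_x
  play$y <- new_y
  play$o <- (play$o + dtheta) %% 360
  play$normalized <- TRUE
  play$transform <- list(A = A, b = b, dtheta = dtheta)
  play
}

#' Undo play normalisation
#'
#' @param play a normalized `gh_play`.
#' @return the play in original field coordinates.
#' @export
denormalize_play <- function(play) {
  if (!isTRUE(play$normalized)) return(play)
  tr <- play$transform
  Ai <- solve(tr$A)
  ox <- Ai[1, 1] * (play$x - tr$b[1]) + Ai[1, 2] * (play$y - tr$b[2])
  oy <- Ai[2, 1] * (play$x - tr$b[1]) + Ai[2, 2] * (play$y - tr$b[2])
  play$x <- ox
  play$y <- oy
  play$o <- (play$o - tr$dtheta) %% 360
  play$normalized <- FALSE
  play$transform <- NULL
  play
}

#' Clip a play to the snap-to-pass window
#'
#' Removes frames strictly outside the inclusive `[ball_snap, pass_forward]`
#' interval. Idempotent.
#'
#' @param play a `gh_play` with both events.
#' @return the clipped play.
#' @export
clip_to_pass_window <- function(play) {
  snap <- play$events[["ball_snap"]]
  pass <- play$events[["pass_forward"]]
  if (is.null(snap) || is.null(pass)) {
    stop_play(play, "clip_to_pass_window needs both ball_snap and pass_forward events")
  }
  if (pass < snap) stop_play(play, "pass_forward precedes ball_snap (corrupt play)")
  keep <- play$frames >= snap & play$frames <= pass
  play$frames <- play$frames[keep]
  play$x <- play$x[keep, , drop = FALSE]
  play$y <- play$y[keep, , drop = FALSE]
  play$s <- play$s[keep, , drop = FALSE]
  play$o <- play$o[keep, , drop = FALSE]
  play$events <- play$events[
    vapply(play$events, function(f) f >= snap && f <= pass, logical(1))
  ]
  play
}

#' Assign train/validation/test splits
#'
#' `by_week` places weeks 1-14 in train/validation and weeks 15-17 in test;
#' `random_70_30` draws a seeded 70/30 train/test partition. The mode and
#' seed are recorded on the collection.
#'
#' @param collection a `gh_collection`.
#' @param mode `"by_week"` (default) or `"random_70_30"`.
#' @param seed seed for the random mode.
#' @param val_frac within the `by_week` train block, fraction held out as
#'   validation (seeded).
#' @return the collection with `$split` set.
#' @export
split_collection <- function(collection, mode = c("by_week", "random_70_30"),
                             seed = 1L, val_frac = 0.15) {
  mode <- match.arg(mode)
  n <- length(collection$plays)
  split <- character(n)
  if (mode == "by_week") {
    weeks <- vapply(collection$plays, function(p) as.integer(p$week %||% NA_integer_), integer(1))
    if (anyNA(weeks)) stop("by_week split requires a week for every play", call. = FALSE)
    split[weeks >= 15L] <- "test"
    trainish <- which(weeks <= 14L)
    set.seed(seed)
    n_val <- floor(length(trainish) * val_frac)
    val <- if (n_val > 0) sample(trainish, n_val) else integer(0)
    split[setdiff(trainish, val)] <- "train"
    split[val] <- "validation"
  } else {
    set.seed(seed)
    n_test <- round(0.3 * n)
    test <- sample.int(n, n_test)
    split[test] <- "test"
    split[setdiff(seq_len(n), test)] <- "train"
  }
  collection$split <- split
  collection$split_mode <- mode
  collection$split_seed <- seed
  collection
}

#' Subset a collection by split label
#'
#' @param collection a split `gh_collection`.
#' @param label one or more of `"train"`, `"validation"`, `"test"`.
#' @return a `gh_collection` with the matching plays.
#' @export
collection_subset <- function(collection, label) {
  stopifnot(!is.null(collection$split))
  keep <- collection$split %in% label
  out <- play_collection(collection$plays[keep], split = collection$split[keep])
  out$split_mode <- collection$split_mode
  out$split_seed <- collection$split_seed
  out
}

#' Write a collection in the Big Data Bowl 2021 CSV dialect
#'
#' Writes one `weekN.csv` tracking file per week plus `plays.csv` and
#' `games.csv` into `dir`. Coordinates are written with enough digits to
#' round-trip through [read_tracking()] (absolute error below 1e-9).
#'
#' @param collection a `gh_collection` in field coordinates.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_tracking <- function(collection, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows_by_week <- list()
  plays_meta <- list()
  games <- list()
  for (play in collection$plays) {
    if (isTRUE(play$normalized)) play <- denormalize_play(play)
    n_f <- length(play$frames)
    n_e <- nrow(play$roster)
    ev <- rep("", n_f)
    for (e in names(play$events)) {
      i <- match(play$events[[e]], play$frames)
      if (!is.na(i)) ev[i] <- e
    }
    team_lab <- c(defense = "away", offense = "home", ball = "football")[play$roster$team]
    d <- data.frame(
      x = as.vector(play$x), y = as.vector(play$y),
      s = as.vector(play$s), o = as.vector(play$o),
      event = rep(ev, times = n_e),
      nflId = rep(play$roster$entity_id, each = n_f),
      frameId = rep(play$frames, times = n_e),
      playId = play$play_id, gameId = play$game_id,
      team = rep(team_lab, each = n_f),
      position = rep(play$roster$position, each = n_f),
      playDirection = play$meta$play_direction %||% "right",
      stringsAsFactors = FALSE
    )
    d <- d[!is.na(d$x), ]
    wk <- as.character(play$week %||% 1L)
    rows_by_week[[wk]] <- c(rows_by_week[[wk]], list(d))
    plays_meta[[length(plays_meta) + 1L]] <- data.frame(
      gameId = play$game_id, playId = play$play_id,
      down = play$meta$down %||% NA_integer_,
      yardsToGo = play$meta$yards_to_go %||% NA_integer_,
      absoluteYardlineNumber = play$meta$line_of_scrimmage_x %||% NA_real_,
      passResult = switch(play$meta$pass_outcome %||% "none",
                          complete = "C", incomplete = "I", intercepted = "IN", ""),
      stringsAsFactors = FALSE
    )
    games[[length(games) + 1L]] <- data.frame(
      gameId = play$game_id, week = play$week %||% 1L, stringsAsFactors = FALSE
    )
  }
  paths <- character(0)
  for (wk in names(rows_by_week)) {
    d <- do.call(rbind, rows_by_week[[wk]])
    for (col in c("x", "y", "s", "o")) d[[col]] <- sprintf("%.10f", d[[col]])
    path <- file.path(dir, sprintf("week%s.csv", wk))
    data.table::fwrite(d, path)
    paths <- c(paths, path)
  }
  pm <- unique(do.call(rbind, plays_meta))
  gm <- unique(do.call(rbind, games))
  data.table::fwrite(pm, file.path(dir, "plays.csv"))
  data.table::fwrite(gm, file.path(dir, "games.csv"))
  invisible(c(paths, file.path(dir, c("plays.csv", "games.csv"))))
}

#' Write a play manifest
#'
#' JSON listing play id, split label and filter disposition for a collection.
#'
#' @param collection a `gh_collection` (pre-filter).
#' @param path output JSON path.
#' @return invisibly, the manifest list.
#' @export
write_play_manifest <- function(collection, path) {
  keep <- vapply(collection$plays, play_passes_filter, logical(1))
  manifest <- lapply(seq_along(collection$plays), function(i) {
    p <- collection$plays[[i]]
    list(
      game_id = p$game_id, play_id = p$play_id, week = p$week,
      split = if (!is.null(collection$split)) collection$split[i] else NA,
      retained = keep[i]
    )
  })
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
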