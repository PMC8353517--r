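#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Solves the linear assignment problem for a square cost matrix: finds the
#' bijection rows -> columns minimising the total cost. Used to match players
#' to tactical roles, where entry (i, j) is the negative log-density of player
#' i's track under role j. Implementation is the O(n^3) shortest augmenting
#' path method with dual potentials.
#'
#' @param cost square numeric matrix; `cost[i, j]` is the cost of assigning
#'   row i to column j. Must be finite.
#' @return list with `assignment` (integer vector; `assignment[i]` is the
#'   column assigned to row i) and `cost` (the minimised total).
#' @examples
#' solve_assignment(matrix(c(1, 2, 2, 1), 2, byrow = TRUE))
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost) || nrow(cost) != ncol(cost)) {
    stop("cost must be a square matrix", call. = FALSE)
  }
  if (!all(is.finite(cost))) stop("cost entries must be finite", call. = FALSE)
  n <- nrow(cost)
  # Index shift: position k holds column k-1; column 0 is the virtual root.
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1) # p[j+1]: row currently assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j + 1L]] <- j
  list(assignment = assignment, cost = sum(cost[cbind(seq_len(n), assignment)]))
}

# Exhaustive assignment minimum; oracle-grade, n <= 8.
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- permutations_all(n)
  costs <- apply(perms, 1L, function(p) sum(cost[cbind(seq_len(n), p)]))
  best <- which.min(costs)
  list(assignment = perms[best, ], cost = costs[best])
}

# All permutations of 1..n as rows (n! x n), lexicographic.
permutations_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}
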