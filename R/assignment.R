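#' Optimal one-to-one assignment (Hungarian algorithm)
#'
#' Solves the square linear assignment problem: pick one column per row,
#' each column used once, optimising the summed matrix entries. Used to map
#' the nine fitted clusters bijectively onto the nine size codes from the
#' training contingency table. O(n^3) shortest augmenting path
#' implementation with row/column potentials.
#'
#' @param mat Square numeric matrix; `mat[i, j]` is the cost (or, with
#'   `maximize = TRUE`, the gain) of assigning row `i` to column `j`.
#' @param maximize Maximise instead of minimise.
#' @return List with `assignment` (integer vector: column chosen for each
#'   row) and `value` (the optimal total).
#' @examples
#' solve_assignment(matrix(c(5, 0, 1, 0, 6, 0, 1, 0, 4), 3, byrow = TRUE),
#'                  maximize = TRUE)
#' @export
solve_assignment <- function(mat, maximize = FALSE) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (ncol(mat) != n || n == 0) {
    isz_error("assignment matrix must be square and non-empty",
              "implant_cardinality_error")
  }
  if (anyNA(mat)) isz_error("assignment matrix contains NA", "implant_value_error")
  cost <- if (maximize) max(mat) - mat else mat
  big <- sum(abs(cost)) + 1
  # columns are shifted by +1: index 1 is the virtual root column
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1)      # column potentials (incl. virtual)
  p <- integer(n + 1)      # p[j]: row matched to column j - 1 (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(big, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- big
      j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assignment <- integer(n)
  for (j in 2:(n + 1)) assignment[p[j]] <- j - 1L
  list(assignment = assignment,
       value = sum(mat[cbind(seq_len(n), assignment)]))
}

# Maximum-agreement bijection with deterministic tie-breaking: among all
# assignments attaining the optimal agreement, pick the one whose column
# sequence (rows in order) is lexicographically smallest. Columns are
# assumed ordered by ascending label code.
assign_max_lexicographic <- function(mat) {
  n <- nrow(mat)
  best <- solve_assignment(mat, maximize = TRUE)$value
  avail <- seq_len(n)
  chosen <- integer(n)
  fixed <- 0
  for (i in seq_len(n)) {
    for (j in avail) {
      rest <- setdiff(avail, j)
      tail_best <- if (length(rest)) {
        solve_assignment(mat[(i + 1):n, rest, drop = FALSE], maximize = TRUE)$value
      } else 0
      if (fixed + mat[i, j] + tail_best >= best - 1e-9) {
        chosen[i] <- j
        fixed <- fixed + mat[i, j]
        avail <- rest
        break
      }
    }
  }
  chosen
}
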