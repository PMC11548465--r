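# Linear assignment by the Hungarian algorithm (shortest augmenting path
# with potentials, O(n^3)). No assignment solver ships with the installed
# R stack, so the solver is implemented here and checked against an
# exhaustive permutation oracle in the tests.

# a: n x m cost matrix with n <= m, all entries finite.
# Returns integer vector of length n: column assigned to each row.
hungarian_lt <- function(a) {
  n <- nrow(a); m <- ncol(a)
  u <- numeric(n)
  v <- numeric(m + 1L)     # index 1 is the virtual column 0
  p <- integer(m + 1L)     # p[j + 1]: row assigned to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      js <- which(!used[-1L])
      cur <- a[i0, js] - u[i0] - v[js + 1L]
      better <- cur < minv[js]
      if (any(better)) {
        minv[js[better]] <- cur[better]
        way[js[better] + 1L] <- j0
      }
      k <- which.min(minv[js])   # first minimum: lowest column index wins
      j1 <- js[k]
      delta <- minv[j1]
      uj <- which(used)
      rows <- p[uj]
      u[rows] <- u[rows] + delta
      v[uj] <- v[uj] - delta
      minv[js] <- minv[js] - delta
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
  assign_col <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) assign_col[p[j + 1L]] <- j
  assign_col
}

#' Solve a linear assignment problem
#'
#' Minimum-total-cost one-to-one assignment of rows to columns (Hungarian
#' algorithm). When the matrix is rectangular, `min(n, m)` pairs are
#' assigned. Ties in total cost are broken deterministically in favour of
#' lower row, then lower column indices.
#'
#' @param cost numeric cost matrix (finite entries)
#' @return An integer vector `assignment` of length `nrow(cost)`: the column
#'   assigned to each row, `NA` for unassigned rows.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  if (!all(is.finite(cost))) stop_validation("assignment costs must be finite")
  # infinitesimal lexicographic preference for (low row, low col) among ties
  eps <- (max(abs(cost)) + 1) * 1e-9
  pert <- cost + eps * (outer(seq_len(n), seq_len(m),
                              function(i, j) i / n + j / (n * m + m)))
  if (n <= m) {
    hungarian_lt(pert)
  } else {
    byrow <- hungarian_lt(t(pert))
    out <- rep(NA_integer_, n)
    out[byrow] <- seq_len(m)
    out
  }
}

#' Gated association of tracks to detections
#'
#' Solves the assignment on the cost matrix (gated-out pairs replaced by a
#' large sentinel), then removes assigned pairs whose true cost exceeds the
#' gate. Rows conventionally index tracks and columns detections.
#'
#' @param cost numeric cost matrix (rows x cols); entries above `gate` are
#'   never matched
#' @param gate maximum acceptable cost (inclusive)
#' @return A list with `matches` (k x 2 integer matrix of row, col indices),
#'   `unmatched_rows` and `unmatched_cols` (integer vectors).
#' @export
associate <- function(cost, gate) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) {
    return(list(matches = matrix(integer(), ncol = 2L,
                                 dimnames = list(NULL, c("row", "col"))),
                unmatched_rows = seq_len(n), unmatched_cols = seq_len(m)))
  }
  big <- max(gate, max(cost[is.finite(cost)], 0)) * 2 + 10
  gated <- cost
  gated[!is.finite(gated) | gated > gate] <- big
  assign_col <- solve_assignment(gated)
  rows <- which(!is.na(assign_col))
  cols <- assign_col[rows]
  keep <- cost[cbind(rows, cols)] <= gate
  matches <- cbind(row = rows[keep], col = cols[keep])
  list(matches = matches,
       unmatched_rows = setdiff(seq_len(n), matches[, 1]),
       unmatched_cols = setdiff(seq_len(m), matches[, 2]))
}
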