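# Linear assignment (Hungarian / shortest augmenting path with potentials),
# O(n^3). Used for frame-to-frame detection linking and for matching
# predicted tracks to ground truth in the fidelity metric. Rectangular
# problems are handled by the row <= column orientation; forbidden pairs are
# encoded as a large finite cost and filtered by the caller.

BIG_COST <- 1e9

#' Solve the linear assignment problem
#'
#' Minimises the total cost of a one-to-one assignment of rows to columns.
#' Works on rectangular matrices (each row matched when nrow <= ncol,
#' otherwise each column).
#'
#' @param cost numeric cost matrix; use values >= 1e9 for forbidden pairs.
#' @return integer vector `match` of length nrow(cost): the column assigned
#'   to each row (NA when the row is unmatched or only forbidden pairs were
#'   available).
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  transposed <- FALSE
  if (n > m) { cost <- t(cost); transposed <- TRUE; tmp <- n; n <- m; m <- tmp }
  # Jonker-Volgenant style shortest augmenting path with dual potentials
  u <- numeric(n + 1L); v <- numeric(m + 1L)
  p <- integer(m + 1L)        # p[j] = row matched to column j (0 = none)
  for (i in seq_len(n)) {
    p[m + 1L] <- i
    j0 <- m + 1L
    minv <- rep(Inf, m); used <- rep(FALSE, m + 1L)
    way <- integer(m)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(m + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- if (j1 > m) i else p[j1]
      j0 <- j1
      if (j0 > m) break
    }
  }
  match_row <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j] > 0L) match_row[p[j]] <- j
  out <- if (transposed) {
    res <- rep(NA_integer_, m)  # original rows = m after transpose
    for (i in seq_len(n)) if (!is.na(match_row[i])) res[match_row[i]] <- i
    res
  } else match_row
  # strip forbidden matches
  if (!transposed) {
    bad <- !is.na(out) & cost[cbind(seq_len(n), out)] >= BIG_COST
  } else {
    bad <- !is.na(out) & t(cost)[cbind(seq_along(out), out)] >= BIG_COST
  }
  out[bad] <- NA_integer_
  out
}
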