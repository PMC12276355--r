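# Optimal bipartite assignment (Hungarian / shortest augmenting path with
# potentials). Used by the track linker; no solver for this is available
# among the package's dependencies, so it is implemented here and checked
# against brute-force enumeration in the tests.

#' Minimal-cost bipartite assignment
#'
#' Solves min sum cost[i, match(i)] over one-to-one matchings of rows to
#' columns. Requires nrow(cost) <= ncol(cost); every row is matched.
#'
#' @param cost numeric matrix (finite entries; use a large value to
#'   discourage a pairing).
#' @return integer vector: column matched to each row.
#' @export
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0) return(integer(0))
  if (n > m) stop("cost matrix needs nrow <= ncol")
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1)          # p[j+1]: row assigned to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match_col <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) match_col[p[j + 1]] <- j
  match_col
}
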