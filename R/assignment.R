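# Minimum-cost bipartite assignment (Hungarian algorithm, O(n^3) shortest
# augmenting path formulation). Used by the association cascade and the
# CLEAR-MOT matcher; no weighted-assignment solver ships with base R.

#' Solve a minimum-cost assignment problem
#'
#' Finds the one-to-one row-to-column assignment minimizing total cost.
#' `Inf` entries mark forbidden pairs; rows (or columns) whose only options
#' are forbidden stay unassigned. With unequal dimensions the smaller side
#' is fully assigned where feasible.
#'
#' @param cost Numeric cost matrix; `Inf` allowed, `NA` not.
#' @return Integer vector of length `nrow(cost)`: for each row the assigned
#'   column index, or `NA` if unassigned. Deterministic, ties broken by
#'   lowest index.
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost)) cost <- as.matrix(cost)
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0L || nc == 0L) return(rep(NA_integer_, nr))
  if (any(is.na(cost) & !is.infinite(cost))) stop("NA in cost matrix")
  finite <- cost[is.finite(cost)]
  big <- if (length(finite)) max(abs(finite)) * (max(nr, nc) + 1) + 1 else 1
  n <- max(nr, nc)
  a <- matrix(big, n, n)
  a[seq_len(nr), seq_len(nc)] <- pmin(cost, big)
  # shortest augmenting path with potentials; p[j] = row assigned to col j
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0L
    minv <- rep(Inf, n + 1); used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- a[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
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
  out <- rep(NA_integer_, nr)
  for (j in seq_len(n)) {
    i <- p[j + 1L]
    if (i >= 1L && i <= nr && j <= nc && is.finite(cost[i, j]))
      out[i] <- j
  }
  out
}
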