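# Optimal one-to-one assignment (Hungarian algorithm, shortest augmenting
# path formulation, O(n^3)). Used for detection-to-truth matching and
# frame-to-frame track association; gated pairs are excluded via a large
# finite cost so the solver stays numerically exact.

BIG_COST <- 1e9

# Solve min-cost perfect matching on an n x n cost matrix.
# Returns an integer vector `match` with match[row] = assigned column.
hungarian_square <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)      # p[col+1] = row assigned to col (0 = none)
  way <- integer(n + 1)
  a <- rbind(cbind(cost, 0), 0)  # 1-based padding convenience
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j + 1] <- minv[j + 1] - delta
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
  match <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) match[p[j + 1]] <- j
  match
}

# Min-cost assignment with explicit unassignment penalties: rows and
# columns may stay unmatched at cost `unmatch_row[i]` / `unmatch_col[j]`
# (dummy nodes), so an association is chosen only when it beats leaving
# both ends unmatched. `D` may contain BIG_COST for forbidden pairs.
assign_with_unmatch <- function(D, unmatch_row, unmatch_col) {
  nr <- nrow(D); nc <- ncol(D)
  if (nr == 0 || nc == 0)
    return(tibble::tibble(row = integer(), col = integer(),
                          cost = numeric()))
  n <- nr + nc
  C <- matrix(BIG_COST, n, n)
  C[seq_len(nr), seq_len(nc)] <- D
  for (i in seq_len(nr)) C[i, nc + i] <- unmatch_row[i]
  for (j in seq_len(nc)) C[nr + j, j] <- unmatch_col[j]
  C[(nr + 1):n, (nc + 1):n] <- 0
  m <- hungarian_square(C)
  rows <- seq_len(nr)
  cols <- m[seq_len(nr)]
  ok <- cols <= nc & C[cbind(rows, cols)] < BIG_COST
  tibble::tibble(row = rows[ok], col = cols[ok],
                 cost = D[cbind(rows[ok], cols[ok])])
}

# Gated rectangular assignment: rows and columns may stay unmatched when no
# partner lies within `gate`. Returns a tibble (row, col, cost) of matched
# pairs with cost <= gate.
hungarian_match <- function(D, gate = Inf) {
  nr <- nrow(D); nc <- ncol(D)
  if (nr == 0 || nc == 0)
    return(tibble::tibble(row = integer(), col = integer(),
                          cost = numeric()))
  n <- max(nr, nc)
  C <- matrix(BIG_COST, n, n)
  C[seq_len(nr), seq_len(nc)] <- ifelse(D <= gate, D, BIG_COST)
  m <- hungarian_square(C)
  rows <- seq_len(nr)
  cols <- m[seq_len(nr)]
  ok <- cols <= nc & C[cbind(rows, cols)] < BIG_COST
  tibble::tibble(row = rows[ok], col = cols[ok],
                 cost = D[cbind(rows[ok], cols[ok])])
}
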