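# Linear assignment by shortest augmenting paths (Jonker-Volgenant style,
# O(n^2 m)). Solves min sum cost[i, assign[i]] for an n x m cost matrix with
# n <= m (caller pads if necessary). Deterministic: rows are augmented in
# order and column scans run left to right, so among equal-cost optima the
# one favoring earlier rows/columns is produced.
# Returns an integer vector a with a[i] = assigned column of row i.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n)            # row potentials
  v <- numeric(m + 1)        # column potentials, v[j+1] for column j (j=0 dummy)
  p <- integer(m + 1)        # p[j+1] = row assigned to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i                # dummy column 0 holds the row being inserted
    j0 <- 0
    minv <- rep(INF, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF; j1 <- 0
      cur <- cost[i0, ] - u[i0] - v[2:(m + 1)]
      upd <- !used[2:(m + 1)] & cur < minv
      minv[upd] <- cur[upd]
      way[which(upd) + 1] <- j0
      free_cols <- which(!used[2:(m + 1)])
      j1 <- free_cols[which.min(minv[free_cols])]
      delta <- minv[j1]
      for (j in 0:m) {
        if (used[j + 1]) {
          if (p[j + 1] > 0) u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  a <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) a[p[j + 1]] <- j
  a
}
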