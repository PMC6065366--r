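# Independent oracles used to validate the detection and tracking paths.
# These deliberately share no code with the package implementation.

# Exhaustive template-matching droplet finder: normalized cross-correlation
# of a disk template against the image at every admissible integer center
# and every candidate radius; returns the top `k` non-overlapping peaks.
oracle_detect <- function(img, radii, k = 1) {
  nr <- nrow(img); nc <- ncol(img)
  best <- data.frame(x = numeric(), y = numeric(), r = numeric(), ncc = numeric())
  cand <- list()
  for (r in radii) {
    half <- ceiling(r) + 2
    tmpl_d <- outer((-half:half)^2, (-half:half)^2, `+`) <= r^2
    tv <- as.numeric(tmpl_d)
    for (yc in (half + 1):(nr - half)) {
      for (xc in (half + 1):(nc - half)) {
        patch <- img[(yc - half):(yc + half), (xc - half):(xc + half)]
        pv <- as.numeric(patch)
        if (stats::sd(pv) == 0) next
        cand[[length(cand) + 1]] <- c(xc - 1, yc - 1, r,
                                      suppressWarnings(stats::cor(pv, tv)))
      }
    }
  }
  if (length(cand) == 0) return(best)
  m <- do.call(rbind, cand)
  m <- m[order(-m[, 4]), , drop = FALSE]
  for (i in seq_len(nrow(m))) {
    if (nrow(best) >= k) break
    if (nrow(best) == 0 ||
        all((best$x - m[i, 1])^2 + (best$y - m[i, 2])^2 >
            (best$r + m[i, 3])^2)) {
      best <- rbind(best, data.frame(x = m[i, 1], y = m[i, 2],
                                     r = m[i, 3], ncc = m[i, 4]))
    }
  }
  best
}

perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  p <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, p + (p >= i))
  }))
}

# Brute-force minimum-total-squared-displacement linking for movies with the
# same small number of droplets in every frame (no gaps): enumerates every
# per-frame permutation sequence.
oracle_link_cost <- function(frames_xy) {
  n <- nrow(frames_xy[[1]])
  stopifnot(all(vapply(frames_xy, nrow, 1L) == n), n <= 4)
  pm <- perms(n)
  total_best <- Inf
  # order[i] = permutation applied to frame i (mapping track -> row)
  rec <- function(fi, assign_prev, cost) {
    if (fi > length(frames_xy)) {
      if (cost < total_best) total_best <<- cost
      return(invisible())
    }
    for (pi in seq_len(nrow(pm))) {
      a <- pm[pi, ]
      step <- sum((frames_xy[[fi]]$x[a] - frames_xy[[fi - 1]]$x[assign_prev])^2 +
                    (frames_xy[[fi]]$y[a] - frames_xy[[fi - 1]]$y[assign_prev])^2)
      if (cost + step < total_best) rec(fi + 1, a, cost + step)
    }
  }
  rec(2, seq_len(n), 0)
  total_best
}

# total squared displacement of a linked trajectory table
link_cost <- function(traj) {
  sum(unlist(lapply(split(traj, traj$droplet_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 2) return(0)
    diff(tr$x)^2 + diff(tr$y)^2
  })))
}

# lattice points with dx^2 + dy^2 <= r^2 (used to cross-check disk masks)
lattice_disk_count <- function(r) {
  g <- expand.grid(dx = -ceiling(r):ceiling(r), dy = -ceiling(r):ceiling(r))
  sum(g$dx^2 + g$dy^2 <= r^2)
}
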