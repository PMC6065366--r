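#' Link per-frame droplet detections into trajectories
#'
#' Frame-to-frame linking with optimal (Hungarian) assignment minimizing the
#' total squared displacement among candidate pairs within `max_disp` per
#' frame step. Trajectories unmatched in a frame persist for up to `memory`
#' frames (their last position is used for matching across the gap, with the
#' displacement budget scaled by the gap length); unmatched detections start
#' new trajectories. Ties are resolved deterministically in favor of the
#' smaller trajectory id.
#'
#' @param detections data.frame with columns `frame` (integer, 0-based or any
#'   increasing integers), `x`, `y` and optionally `r` plus extras. Typically
#'   the row-bound output of [detect_droplets()] over frames.
#' @param max_disp Maximum displacement per frame step, px, > 0.
#' @param memory Number of frames a vanished droplet may be bridged over.
#' @return The input data.frame with a `droplet_id` column added, sorted by
#'   (`droplet_id`, `frame`).
#' @export
link_trajectories <- function(detections, max_disp = 5, memory = 2) {
  stopifnot(is.data.frame(detections),
            all(c("frame", "x", "y") %in% names(detections)))
  if (max_disp <= 0) stop("max_disp must be > 0")
  if (memory < 0) stop("memory must be >= 0")
  det <- detections
  det$droplet_id <- NA_integer_
  if (nrow(det) == 0) return(det)
  frames <- sort(unique(det$frame))
  BIG <- 1e12
  # active tracks: id, x, y, last frame seen
  act <- data.frame(id = integer(), x = numeric(), y = numeric(), last = numeric())
  next_id <- 1L
  for (f in frames) {
    rows <- which(det$frame == f)
    act <- act[f - act$last <= memory + 1, , drop = FALSE]
    nA <- nrow(act); nD <- length(rows)
    assigned <- rep(NA_integer_, nD)
    if (nA > 0 && nD > 0) {
      dx <- outer(act$x, det$x[rows], `-`)
      dy <- outer(act$y, det$y[rows], `-`)
      cost <- dx^2 + dy^2
      lim <- (max_disp * (f - act$last))^2
      cost[cost > matrix(lim, nA, nD)] <- BIG
      # pad with dummy columns so every track may stay unmatched
      cm <- cbind(cost, matrix(BIG / 2, nA, nA))
      a <- solve_assignment(cm)
      for (i in seq_len(nA)) {
        if (a[i] <= nD && cost[i, a[i]] < BIG) assigned[a[i]] <- i
      }
    }
    for (j in seq_len(nD)) {
      if (!is.na(assigned[j])) {
        id <- act$id[assigned[j]]
      } else {
        id <- next_id; next_id <- next_id + 1L
        act <- rbind(act, data.frame(id = id, x = 0, y = 0, last = f))
      }
      det$droplet_id[rows[j]] <- id
      k <- which(act$id == id)
      act$x[k] <- det$x[rows[j]]; act$y[k] <- det$y[rows[j]]; act$last[k] <- f
    }
    act <- act[order(act$id), , drop = FALSE]
  }
  det <- det[order(det$droplet_id, det$frame), , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Annotate fusion events among linked trajectories
#'
#' A fusion is recorded when a trajectory ends at frame t in contact with a
#' second droplet (center distance smaller than the sum of radii) and a
#' trajectory present at the next frame has radius^3 matching the two
#' parents' summed radius^3 within `volume_tol` (relative), i.e. droplet
#' volume is conserved across the merge.
#'
#' @param trajectories Output of [link_trajectories()]; must contain `r`.
#' @param volume_tol Relative tolerance on the child volume.
#' @return data.frame with columns `frame` (frame of the merged child),
#'   `parent1` (the continuing or larger parent), `parent2` (the vanishing
#'   parent), `child`.
#' @export
annotate_fusions <- function(trajectories, volume_tol = 0.1) {
  stopifnot(all(c("droplet_id", "frame", "x", "y", "r") %in% names(trajectories)))
  tr <- trajectories
  events <- list()
  last_frame <- tapply(tr$frame, tr$droplet_id, max)
  all_frames <- sort(unique(tr$frame))
  for (id in names(last_frame)) {
    t_end <- last_frame[[id]]
    nxt <- all_frames[all_frames > t_end]
    if (length(nxt) == 0) next
    t1 <- nxt[1]
    e <- tr[tr$droplet_id == as.integer(id) & tr$frame == t_end, ]
    # candidate children present at t1 and in contact with the ending parent
    ch <- tr[tr$frame == t1, ]
    if (nrow(ch) == 0) next
    dist_e <- sqrt((ch$x - e$x)^2 + (ch$y - e$y)^2)
    ch <- ch[dist_e < ch$r + e$r, , drop = FALSE]
    for (ci in seq_len(nrow(ch))) {
      child <- ch[ci, ]
      # second parent: any droplet at t_end (other than the ending one)
      # in contact with the child position
      p2 <- tr[tr$frame == t_end & tr$droplet_id != as.integer(id), , drop = FALSE]
      if (nrow(p2) == 0) next
      dist_c <- sqrt((p2$x - child$x)^2 + (p2$y - child$y)^2)
      p2 <- p2[dist_c < p2$r + child$r, , drop = FALSE]
      for (pi in seq_len(nrow(p2))) {
        expect_v <- e$r^3 + p2$r[pi]^3
        if (abs(child$r^3 - expect_v) <= volume_tol * expect_v) {
          events[[length(events) + 1]] <- data.frame(
            frame = t1, parent1 = p2$droplet_id[pi],
            parent2 = as.integer(id), child = child$droplet_id)
        }
      }
    }
  }
  if (length(events) == 0)
    return(data.frame(frame = numeric(), parent1 = integer(),
                      parent2 = integer(), child = integer()))
  ev <- unique(do.call(rbind, events))
  rownames(ev) <- NULL
  ev
}
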