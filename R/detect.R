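#' Detect circular droplets with a circular Hough transform
#'
#' Edge pixels (Sobel gradient magnitude above a relative threshold) vote for
#' circle centers at every candidate radius; votes are normalized by the
#' circle circumference so one threshold is meaningful across the radius
#' range. Peaks above `vote_threshold` are accepted greedily in descending
#' score with centers at least `min_separation` apart, the accepted center is
#' refined to subpixel precision by the centroid of the accumulator peak
#' neighborhood, and the radius by a vote-weighted mean over adjacent radii.
#'
#' Accuracy is limited for droplets of diameter at or below 10 px (about
#' 1 um at the default 0.1 um/px scale); no radius-accuracy guarantee is made
#' below that floor.
#'
#' @param frame Numeric matrix (intensities, finite and >= 0).
#' @param r_min,r_max Radius search range, px, `1 <= r_min <= r_max` and
#'   `r_max < min(dim(frame))/2`.
#' @param edge_threshold Edge map threshold as a fraction of the maximum
#'   Sobel gradient magnitude.
#' @param vote_threshold Minimum normalized accumulator score (roughly the
#'   supported fraction of the circle perimeter) for a candidate.
#' @param min_separation Minimum center-to-center distance between accepted
#'   detections, px. Default `r_min`.
#' @param polarity `"both"`, `"bright"` (droplet brighter than surroundings),
#'   or `"dark"`.
#' @return data.frame with columns `x`, `y` (subpixel, 0-based), `r` (px),
#'   `score`, `integrated`, `mean_interior`, `pixel_count`, sorted by
#'   descending score with ties broken by (y, x).
#' @export
detect_droplets <- function(frame, r_min = 5, r_max = 25,
                            edge_threshold = 0.25, vote_threshold = 0.35,
                            min_separation = NULL, polarity = "both") {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  nr <- nrow(frame); nc <- ncol(frame)
  if (r_min > r_max) stop("r_min must be <= r_max")
  if (r_min < 1 || r_max >= min(nr, nc) / 2)
    stop("radius range must satisfy 1 <= r_min <= r_max < min(dim)/2")
  min_separation <- min_separation %||% r_min
  empty <- data.frame(x = numeric(), y = numeric(), r = numeric(),
                      score = numeric(), integrated = numeric(),
                      mean_interior = numeric(), pixel_count = integer())

  # an (effectively) constant frame has no edges; the relative tolerance
  # keeps this check invariant to intensity scaling
  if (diff(range(frame)) <= 1e-9 * max(abs(frame), 1e-300)) return(empty)
  g <- sobel_magnitude(frame)
  gmax <- max(g)
  if (gmax <= 0) return(empty)
  edge_idx <- which(g >= edge_threshold * gmax)
  if (length(edge_idx) == 0) return(empty)
  ey <- (edge_idx - 1) %% nr          # 0-based row
  ex <- (edge_idx - 1) %/% nr         # 0-based col

  radii <- seq(r_min, r_max)
  acc <- array(0, dim = c(nr, nc, length(radii)))
  for (k in seq_along(radii)) {
    r <- radii[k]
    off <- circle_offsets(r)
    cy <- rep(ey, times = nrow(off)) + rep(off$dy, each = length(ey))
    cx <- rep(ex, times = nrow(off)) + rep(off$dx, each = length(ey))
    ok <- cy >= 0 & cy < nr & cx >= 0 & cx < nc
    bins <- cx[ok] * nr + cy[ok] + 1
    acc[, , k] <- matrix(tabulate(bins, nbins = nr * nc), nr, nc) / nrow(off)
  }

  cand <- which(acc >= vote_threshold)
  if (length(cand) == 0) return(empty)
  ci <- arrayInd(cand, dim(acc))
  sc <- acc[cand]
  ord <- order(-sc, ci[, 1], ci[, 2])
  ci <- ci[ord, , drop = FALSE]; sc <- sc[ord]

  picked <- list()
  px <- numeric(0); py <- numeric(0); pr <- numeric(0)
  for (i in seq_along(sc)) {
    y0 <- ci[i, 1] - 1; x0 <- ci[i, 2] - 1
    # a candidate is suppressed when its center lies closer to an accepted
    # center than the sum of the two radii (distinct droplets cannot be
    # closer than touching; this also removes the vote echoes a strong
    # circle casts at other radii) or within min_separation
    # (the 2 px margin absorbs the echo ring a circle of radius R casts at
    # distance R + r; centers of distinct droplets separated by >= 2 px of
    # background are never suppressed)
    r_cand <- radii[ci[i, 3]]
    if (length(px) > 0 &&
        any((px - x0)^2 + (py - y0)^2 < pmax(min_separation, pr + r_cand + 2)^2)) next
    ref <- refine_peak(acc, ci[i, 1], ci[i, 2], ci[i, 3], radii)
    px <- c(px, x0); py <- c(py, y0); pr <- c(pr, ref$r)
    picked[[length(picked) + 1]] <- data.frame(x = ref$x, y = ref$y, r = ref$r,
                                               score = sc[i])
  }
  det <- do.call(rbind, picked)

  meas <- lapply(seq_len(nrow(det)), function(i) {
    m <- measure_droplet(frame, det$x[i], det$y[i], det$r[i], erosion = 0)
    ann <- annulus_mean(frame, det$x[i], det$y[i], det$r[i], gap = 2, width = 3)
    data.frame(integrated = m$integrated, mean_interior = m$mean,
               pixel_count = m$pixel_count, annulus = ann)
  })
  det <- cbind(det, do.call(rbind, meas))
  if (polarity == "bright") det <- det[det$mean_interior > det$annulus, , drop = FALSE]
  if (polarity == "dark") det <- det[det$mean_interior < det$annulus, , drop = FALSE]
  det$annulus <- NULL
  det <- det[order(-det$score, det$y, det$x), , drop = FALSE]
  rownames(det) <- NULL
  det
}

sobel_kernel_x <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)

sobel_magnitude <- function(frame) {
  gx <- EBImage::filter2(frame, sobel_kernel_x, boundary = "replicate")
  gy <- EBImage::filter2(frame, t(sobel_kernel_x), boundary = "replicate")
  m <- sqrt(as.numeric(gx)^2 + as.numeric(gy)^2)
  matrix(m, nrow(frame), ncol(frame))
}

# Unique integer offsets on the circle of radius r.
circle_offsets <- function(r) {
  n <- max(16, ceiling(4 * pi * r))
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  off <- unique(data.frame(dx = round(r * cos(th)), dy = round(r * sin(th))))
  off
}

# Subpixel center (vote centroid over a 5x5 neighborhood at the peak radius)
# and radius (vote-weighted mean over adjacent radius planes at the peak).
refine_peak <- function(acc, i, j, k, radii) {
  nr <- dim(acc)[1]; nc <- dim(acc)[2]
  ii <- max(1, i - 2):min(nr, i + 2)
  jj <- max(1, j - 2):min(nc, j + 2)
  w <- acc[ii, jj, k]
  tot <- sum(w)
  y <- sum((ii - 1) * rowSums(w)) / tot
  x <- sum((jj - 1) * colSums(w)) / tot
  kk <- max(1, k - 1):min(length(radii), k + 1)
  wr <- acc[i, j, kk]
  r <- sum(radii[kk] * wr) / sum(wr)
  list(x = x, y = y, r = r)
}

annulus_mean <- function(frame, x, y, r, gap = 2, width = 3) {
  nr <- nrow(frame); nc <- ncol(frame)
  r1 <- r + gap; r2 <- r + gap + width
  rows <- max(1, floor(y - r2) + 1):min(nr, ceiling(y + r2) + 1)
  cols <- max(1, floor(x - r2) + 1):min(nc, ceiling(x + r2) + 1)
  d2 <- outer((rows - 1 - y)^2, (cols - 1 - x)^2, `+`)
  sel <- d2 > r1^2 & d2 <= r2^2
  if (!any(sel)) return(NA_real_)
  mean(frame[cbind(rep(rows, ncol(d2))[as.vector(sel)],
                   rep(cols, each = nrow(d2))[as.vector(sel)])])
}

#' Measure droplet intensity inside a detected circle
#'
#' Sums the pixels whose centers fall inside the (optionally eroded) circle:
#' mask = pixels with (dx^2 + dy^2) <= (r - erosion)^2.
#'
#' @param frame Numeric matrix.
#' @param x,y Center, 0-based pixel coordinates (pixel centers at integers).
#' @param r Radius, px.
#' @param erosion Radial erosion, px; `0 <= erosion < r`. Eroding excludes
#'   the blurred rim from intensity statistics.
#' @return List with `integrated` (sum over mask), `mean` and `pixel_count`.
#' @export
measure_droplet <- function(frame, x, y, r, erosion = 0) {
  stopifnot(is.matrix(frame), erosion >= 0)
  if (erosion >= r) stop("erosion must be < radius")
  nr <- nrow(frame); nc <- ncol(frame)
  if (x < 0 || x > nc - 1 || y < 0 || y > nr - 1)
    stop("detection center outside the frame")
  idx <- disk_mask_indices(x, y, r - erosion, nr, nc)
  if (length(idx) == 0)
    stop("eroded mask is empty: radius too small for this erosion")
  v <- frame[idx]
  list(integrated = sum(v), mean = mean(v), pixel_count = length(idx))
}
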