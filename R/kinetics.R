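#' Normalized diameter traces from linked trajectories
#'
#' For dissolution-style movies every trajectory present in the first frame
#' is normalized to its own initial diameter and the population mean is taken
#' over surviving droplets at each time point. Droplets falling below the
#' detection floor simply drop out of the average; the per-time survivor
#' count is reported so censoring bias stays visible.
#'
#' @param trajectories Output of [link_trajectories()] with an `r` column.
#' @param times Optional numeric vector mapping frame index to time
#'   (minutes); defaults to the frame indices themselves.
#' @param min_track_length Minimum number of observations for a trajectory to
#'   be included.
#' @param require_first_frame If `TRUE` (dissolution mode), only trajectories
#'   starting in the first frame qualify; set `FALSE` for assembly movies
#'   where droplets nucleate mid-movie (each is then normalized to its own
#'   first observation).
#' @return An object of class `kinetics_trace`: data.frame with columns
#'   `time`, `mean_norm_d` (population mean of d(t)/d(0)), `n` (survivor
#'   count), with the per-droplet matrix in attribute `per_droplet`.
#' @export
diameter_traces <- function(trajectories, times = NULL, min_track_length = 2,
                            require_first_frame = TRUE) {
  stopifnot(all(c("droplet_id", "frame", "r") %in% names(trajectories)))
  tr <- trajectories
  frames <- sort(unique(tr$frame))
  f0 <- frames[1]
  if (is.null(times)) times <- frames
  stopifnot(length(times) == length(frames))
  keep <- names(which(table(tr$droplet_id) >= min_track_length))
  if (require_first_frame) {
    starters <- unique(tr$droplet_id[tr$frame == f0])
    keep <- intersect(keep, as.character(starters))
  }
  if (length(keep) == 0) stop("no qualifying trajectories")
  ids <- sort(as.integer(keep))
  mat <- matrix(NA_real_, length(frames), length(ids),
                dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    sub <- tr[tr$droplet_id == ids[j], ]
    mat[match(sub$frame, frames), j] <- 2 * sub$r
    mat[, j] <- mat[, j] / mat[which(!is.na(mat[, j]))[1], j]
  }
  out <- data.frame(time = times,
                    mean_norm_d = rowMeans(mat, na.rm = TRUE),
                    n = rowSums(!is.na(mat)))
  out$mean_norm_d[out$n == 0] <- NA_real_
  class(out) <- c("kinetics_trace", "data.frame")
  attr(out, "per_droplet") <- mat
  out
}

#' Time to reach a fractional level of the initial value
#'
#' First crossing of `level` by a decaying population trace, linearly
#' interpolated between the bracketing samples. The conventional summary is
#' the half-time (`level = 0.5`): the time to disassemble 50% of droplet
#' diameter.
#'
#' @param trace A [diameter_traces()] result, or any data.frame with `time`
#'   and a value column (named `mean_norm_d` or given via `value_col`).
#' @param level Fraction of the initial value to reach.
#' @param value_col Name of the value column.
#' @return The crossing time (same units as `time`). If the trace never
#'   crosses, `NA` with attributes `reached = FALSE` and `last_value`.
#' @export
half_time <- function(trace, level = 0.5, value_col = "mean_norm_d") {
  stopifnot("time" %in% names(trace), value_col %in% names(trace))
  v <- trace[[value_col]]; t <- trace$time
  ok <- !is.na(v)
  v <- v[ok]; t <- t[ok]
  if (length(v) == 0) stop("empty trace")
  if (v[1] >= level) {
    idx <- which(v <= level)
    if (length(idx) == 0)
      return(structure(NA_real_, reached = FALSE, last_value = v[length(v)]))
    i <- idx[1]
    if (i == 1) return(structure(t[1], reached = TRUE))
    # linear interpolation between the bracketing samples
    frac <- (v[i - 1] - level) / (v[i - 1] - v[i])
    structure(t[i - 1] + frac * (t[i] - t[i - 1]), reached = TRUE)
  } else {
    structure(t[1], reached = TRUE)
  }
}

#' Transition temperature from a turbidity ramp
#'
#' On a cooling segment, the transition temperature is the temperature at
#' which absorbance first exceeds half of the segment's maximum, linearly
#' interpolated between the two bracketing samples. A logistic-fit mode
#' returns the fitted midpoint instead.
#'
#' @param ramp A [simulate_turbidity_ramp()] result or data.frame with
#'   columns `temperature` and `a600` (and optionally `segment`,
#'   `direction`).
#' @param method `"halfmax"` (default) or `"logistic"`.
#' @param segment Which segment to analyze; `NULL` analyzes every cooling
#'   segment and returns a named vector.
#' @param noise_floor Minimum segment maximum absorbance for a transition to
#'   be considered present.
#' @return Transition temperature(s) in deg C; `NA` with a message attribute
#'   when no transition is detected.
#' @export
transition_temperature <- function(ramp, method = c("halfmax", "logistic"),
                                   segment = NULL, noise_floor = 0.02) {
  method <- match.arg(method)
  stopifnot(all(c("temperature", "a600") %in% names(ramp)))
  if (!"segment" %in% names(ramp)) {
    ramp$segment <- 1
    ramp$direction <- if (ramp$temperature[1] > tail(ramp$temperature, 1))
      "cooling" else "heating"
  }
  segs <- unique(ramp$segment[ramp$direction == "cooling"])
  if (!is.null(segment)) segs <- intersect(segs, segment)
  if (length(segs) == 0) stop("no cooling segment to analyze")
  res <- vapply(segs, function(s) {
    seg <- ramp[ramp$segment == s, ]
    seg <- seg[order(-seg$temperature), ]   # cooling order: high -> low T
    amax <- max(seg$a600)
    if (amax <= noise_floor) return(NA_real_)
    half <- amax / 2
    idx <- which(seg$a600 >= half)
    if (length(idx) == 0) return(NA_real_)
    i <- idx[1]
    if (method == "logistic") {
      fit <- try(minpack.lm::nlsLM(
        a600 ~ amx / (1 + exp((temperature - tm) / st)), data = seg,
        start = list(amx = amax, tm = seg$temperature[i], st = 1),
        control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
      if (inherits(fit, "try-error")) return(NA_real_)
      return(unname(coef(fit)[["tm"]]))
    }
    if (i == 1) return(seg$temperature[1])
    a0 <- seg$a600[i - 1]; a1 <- seg$a600[i]
    frac <- (half - a0) / (a1 - a0)
    seg$temperature[i - 1] + frac * (seg$temperature[i] - seg$temperature[i - 1])
  }, numeric(1))
  names(res) <- paste0("segment", segs)
  if (all(is.na(res))) attr(res, "message") <- "no transition detected"
  if (length(res) == 1) res <- unname(res)
  res
}

#' Phase diagram from a grid of condition images
#'
#' Each (salt, concentration) condition image is segmented with
#' [detect_droplets()]; the condition is called phase-separated when at least
#' `min_droplets` droplets are found. The critical concentration per salt is
#' the geometric mean of the highest soluble and lowest separated
#' concentration in that column; columns with a separated cell below a
#' soluble one are flagged inconsistent and their estimate withheld.
#'
#' @param frames List of image matrices, one per condition row.
#' @param conditions data.frame with columns `salt` and `conc` matching
#'   `frames`.
#' @param detect_args List of arguments passed to [detect_droplets()].
#' @param min_droplets Minimum droplet count to call a condition separated.
#' @return List of class `phase_diagram` with `grid` (conditions plus
#'   `n_droplets`, `separated`) and `critical` (per salt: `c_low`, `c_high`,
#'   `c_crit`, `consistent`).
#' @export
phase_diagram <- function(frames, conditions,
                          detect_args = list(r_min = 4, r_max = 15),
                          min_droplets = 3) {
  stopifnot(length(frames) == nrow(conditions),
            all(c("salt", "conc") %in% names(conditions)))
  grid <- conditions
  grid$n_droplets <- vapply(frames, function(f)
    nrow(do.call(detect_droplets, c(list(frame = f), detect_args))), integer(1))
  grid$separated <- grid$n_droplets >= min_droplets
  crit <- lapply(split(grid, grid$salt), function(col) {
    col <- col[order(col$conc), ]
    if (nrow(col) < 2) stop("need at least 2 concentration levels per salt")
    sep <- col$separated
    consistent <- all(diff(sep) >= 0)   # single soluble -> separated switch
    c_low <- if (any(!sep)) max(col$conc[!sep]) else NA_real_
    c_high <- if (any(sep)) min(col$conc[sep]) else NA_real_
    c_crit <- if (consistent && !is.na(c_low) && !is.na(c_high))
      sqrt(c_low * c_high) else NA_real_
    data.frame(salt = col$salt[1], c_low = c_low, c_high = c_high,
               c_crit = c_crit, consistent = consistent)
  })
  crit <- do.call(rbind, crit)
  rownames(crit) <- NULL
  structure(list(grid = grid, critical = crit), class = "phase_diagram")
}
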