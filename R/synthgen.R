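#' Optics configuration for synthetic image rendering
#'
#' Imaging-model parameters shared by all synthetic generators. The default
#' pixel size of 0.1 um/px reproduces the scale at which a 1 um droplet spans
#' about 10 pixels, the regime the detection module is calibrated for.
#'
#' @param pixel_size Physical pixel size in micrometres per pixel. Must be > 0.
#' @param blur_sigma Standard deviation of the Gaussian point-spread function,
#'   in pixels. 0 disables blurring.
#' @param bit_depth Integer bit depth used when frames are written to TIFF.
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(pixel_size = 0.1, blur_sigma = 0, bit_depth = 16) {
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1, pixel_size > 0,
            is.numeric(blur_sigma), length(blur_sigma) == 1, blur_sigma >= 0,
            bit_depth %in% c(8, 12, 16, 32))
  structure(list(pixel_size = pixel_size, blur_sigma = blur_sigma,
                 bit_depth = as.integer(bit_depth)),
            class = "optics_config")
}

#' Noise configuration for synthetic image rendering
#'
#' @param gaussian_sd Standard deviation of additive Gaussian read noise, in
#'   intensity units. 0 disables it.
#' @param poisson If `TRUE`, pixel values are replaced by Poisson draws with
#'   the noiseless value as the mean (shot noise).
#' @param seed Integer seed making the noise reproducible; `NULL` leaves the
#'   caller's RNG stream untouched.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(gaussian_sd = 0, poisson = FALSE, seed = NULL) {
  stopifnot(is.numeric(gaussian_sd), gaussian_sd >= 0, is.logical(poisson))
  structure(list(gaussian_sd = gaussian_sd, poisson = poisson, seed = seed),
            class = "noise_config")
}

#' Ground-truth droplet scene
#'
#' A scene holds the exact geometry and intensities of every droplet in one
#' frame. Coordinates are 0-based with pixel centers at integers; `x` runs
#' along columns and `y` along rows; radii are in pixels.
#'
#' @param droplets `data.frame` with columns `x`, `y`, `r` and one or more
#'   intensity columns (default channel column name `"intensity"`).
#' @param background Named or unnamed numeric vector of background intensities,
#'   one per channel (recycled to all channels if length 1).
#' @param shape Frame shape `c(rows, cols)`.
#' @param allow_overlap Permit overlapping droplets (used mid-fusion). By
#'   default overlapping droplets are rejected.
#' @return An object of class `droplet_scene`.
#' @export
droplet_scene <- function(droplets, background = 0, shape = c(128L, 128L),
                          allow_overlap = FALSE) {
  stopifnot(is.data.frame(droplets) || is.null(droplets),
            length(shape) == 2, all(shape >= 1))
  shape <- as.integer(shape)
  if (is.null(droplets)) droplets <- data.frame(x = numeric(), y = numeric(),
                                                r = numeric(), intensity = numeric())
  if (nrow(droplets) > 0) {
    stopifnot(all(c("x", "y", "r") %in% names(droplets)))
    if (any(droplets$r <= 0)) stop("droplet radii must be > 0")
    if (!allow_overlap && nrow(droplets) > 1) {
      d <- as.matrix(stats::dist(droplets[, c("x", "y")]))
      rs <- outer(droplets$r, droplets$r, `+`)
      diag(d) <- Inf
      if (any(d < rs)) stop("droplets overlap; set allow_overlap = TRUE for fusing scenes")
    }
  }
  structure(list(droplets = droplets, background = background, shape = shape),
            class = "droplet_scene")
}

intensity_channels <- function(scene) {
  setdiff(names(scene$droplets), c("x", "y", "r", "id"))
}

#' Render a droplet scene into an image frame
#'
#' Draws uniform-interior disks on a flat background, convolves with a
#' Gaussian point-spread function, and applies read/shot noise. Given the
#' same scene, optics and noise seed the output is bit-identical.
#'
#' @param scene A [droplet_scene()].
#' @param optics An [optics_config()].
#' @param noise A [noise_config()].
#' @param channel Name of the intensity column of `scene$droplets` to render.
#' @return A numeric matrix of dimensions `scene$shape` with attributes
#'   `pixel_size` and `channel`.
#' @export
render_scene <- function(scene, optics = optics_config(),
                         noise = noise_config(), channel = "intensity") {
  stopifnot(inherits(scene, "droplet_scene"))
  dr <- scene$droplets
  nr <- scene$shape[1]; nc <- scene$shape[2]
  bg <- scene$background
  if (!is.null(names(bg)) && channel %in% names(bg)) bg <- bg[[channel]]
  else bg <- bg[[1]]
  if (bg < 0) stop("background intensity must be >= 0")
  img <- matrix(bg, nr, nc)
  if (nrow(dr) > 0) {
    if (!channel %in% names(dr)) stop("no intensity column '", channel, "' in scene")
    if (any(dr[[channel]] < 0)) stop("droplet intensities must be >= 0")
    out_of_frame <- dr$x - dr$r < -0.5 | dr$x + dr$r > nc - 0.5 |
      dr$y - dr$r < -0.5 | dr$y + dr$r > nr - 0.5
    if (any(out_of_frame)) stop("droplet extends outside the frame")
    for (i in seq_len(nrow(dr))) {
      m <- disk_mask_indices(dr$x[i], dr$y[i], dr$r[i], nr, nc)
      img[m] <- dr[[channel]][i]
    }
  }
  if (optics$blur_sigma > 0 && diff(range(img)) > 0) {
    img <- EBImage::gblur(img, sigma = optics$blur_sigma, boundary = "replicate")
    img <- matrix(as.numeric(img), nr, nc)
  }
  img <- with_seed(noise$seed, {
    out <- img
    if (noise$poisson) out <- matrix(rpois(length(out), lambda = pmax(out, 0)), nr, nc)
    if (noise$gaussian_sd > 0) out <- out + matrix(rnorm(length(out), 0, noise$gaussian_sd), nr, nc)
    out
  })
  attr(img, "pixel_size") <- optics$pixel_size
  attr(img, "channel") <- channel
  img
}

# Linear indices of pixels whose centers fall inside the disk
# (col0 - x)^2 + (row0 - y)^2 <= r^2, 0-based coordinates.
disk_mask_indices <- function(x, y, r, nr, nc) {
  rows <- max(1, floor(y - r) + 1):min(nr, ceiling(y + r) + 1)
  cols <- max(1, floor(x - r) + 1):min(nc, ceiling(x + r) + 1)
  dy2 <- (rows - 1 - y)^2
  dx2 <- (cols - 1 - x)^2
  inside <- outer(dy2, dx2, `+`) <= r^2
  idx <- which(inside, arr.ind = TRUE)
  (cols[idx[, 2]] - 1) * nr + rows[idx[, 1]]
}

#' Radius of the droplet formed by fusing two droplets
#'
#' Volume conservation for spherical droplets: the merged radius satisfies
#' r^3 = r1^3 + r2^3.
#'
#' @param r1,r2 Parent radii (same units).
#' @return Merged radius.
#' @export
fused_radius <- function(r1, r2) (r1^3 + r2^3)^(1 / 3)

#' Simulate a droplet dissolution or assembly time-lapse
#'
#' Dissolution emulates protease-triggered droplet disassembly: every droplet
#' diameter follows d(t) = d0 * exp(-k t) (or d0 * (1 - k t) in linear mode)
#' and the droplet disappears once its diameter falls below the optical
#' resolution floor. Assembly emulates triggered condensation: droplets
#' nucleate as a Poisson process in time, grow toward a plateau diameter, and
#' optionally fuse pairwise with conserved volume.
#'
#' @param mode `"dissolution"` or `"assembly"`.
#' @param params Named list of kinetic parameters. Dissolution: `k` (1/min,
#'   decay rate, required > 0 unless exactly 0 for a static control), `law`
#'   (`"exponential"` or `"linear"`). Assembly: `nucleation_rate` (droplets
#'   per minute), `growth_rate` (1/min), `plateau_diameter` (px), `fusion`
#'   (logical).
#' @param n_droplets Initial droplet count (dissolution) or expected cap on
#'   droplets (assembly placement attempts).
#' @param duration Total simulated time, minutes.
#' @param dt Frame interval, minutes. Must be > 0.
#' @param shape Frame shape `c(rows, cols)`.
#' @param init_diameter Mean initial (dissolution) or nucleation (assembly)
#'   diameter in px; individual diameters are lognormal with `diameter_cv`
#'   coefficient of variation.
#' @param diameter_cv Lognormal coefficient of variation of diameters.
#' @param intensity,background Interior and background intensities.
#' @param min_diameter Resolution floor (px): droplets below it are removed.
#' @param seed Integer seed.
#' @return An object of class `scene_series`: list with `frames` (list of
#'   [droplet_scene()]), `timestamps` (minutes), `ground_truth` (data.frame
#'   `frame`, `time`, `id`, `x`, `y`, `r`, `intensity`), `fusions`
#'   (data.frame `frame`, `parent1`, `parent2`, `child`), and `params`.
#' @export
simulate_timelapse <- function(mode = c("dissolution", "assembly"),
                               params = list(), n_droplets = 5,
                               duration = 60, dt = 2,
                               shape = c(128L, 128L),
                               init_diameter = 30, diameter_cv = 0.1,
                               intensity = 1, background = 0,
                               min_diameter = 3, seed = NULL) {
  mode <- match.arg(mode)
  if (dt <= 0) stop("dt must be > 0")
  times <- seq(0, duration, by = dt)
  with_seed(seed, {
    if (mode == "dissolution") {
      k <- params$k %||% 0.0347
      law <- params$law %||% "exponential"
      if (k < 0) stop("dissolution rate k must be >= 0")
      init <- place_droplets(n_droplets, shape, init_diameter, diameter_cv)
      gt <- list(); frames <- list()
      for (fi in seq_along(times)) {
        t <- times[fi]
        d <- if (law == "exponential") init$d0 * exp(-k * t) else init$d0 * pmax(0, 1 - k * t)
        alive <- d >= min_diameter
        df <- data.frame(id = init$id[alive], x = init$x[alive], y = init$y[alive],
                         r = d[alive] / 2, intensity = rep(intensity, sum(alive)))
        frames[[fi]] <- droplet_scene(df[, c("x", "y", "r", "intensity", "id")],
                                      background = background, shape = shape)
        if (any(alive))
          gt[[fi]] <- data.frame(frame = fi - 1L, time = t, id = init$id[alive],
                                 x = init$x[alive], y = init$y[alive],
                                 r = d[alive] / 2, intensity = intensity)
      }
      structure(list(frames = frames, timestamps = times,
                     ground_truth = do.call(rbind, gt),
                     fusions = data.frame(frame = integer(), parent1 = integer(),
                                          parent2 = integer(), child = integer()),
                     params = list(mode = mode, k = k, law = law,
                                   min_diameter = min_diameter)),
                class = "scene_series")
    } else {
      nuc_rate <- params$nucleation_rate %||% 0.5
      g <- params$growth_rate %||% 0.1
      plateau <- params$plateau_diameter %||% 25
      fuse <- params$fusion %||% TRUE
      if (nuc_rate <= 0 || g <= 0 || plateau <= 0)
        stop("assembly rates and plateau diameter must be > 0")
      state <- data.frame(id = integer(), x = numeric(), y = numeric(),
                          t0 = numeric(), d_nuc = numeric(), plat = numeric())
      next_id <- 1L
      gt <- list(); frames <- list(); fus <- list()
      for (fi in seq_along(times)) {
        t <- times[fi]
        if (fi > 1) {
          n_new <- rpois(1, nuc_rate * dt)
          for (j in seq_len(n_new)) {
            if (nrow(state) >= n_droplets) break
            cand <- try_place_one(state, shape, init_diameter, diameter_cv,
                                  plateau, t, g)
            if (!is.null(cand)) {
              cand$id <- next_id; next_id <- next_id + 1L
              cand$t0 <- t
              cand$plat <- plateau
              state <- rbind(state, cand)
            }
          }
        }
        d <- droplet_diam(state, t, g)
        # pairwise fusion: merge overlapping droplets, conserving volume
        # (both the instantaneous diameters and the plateaus combine as
        # cube roots of summed cubes); the child keeps the older parent's id
        if (fuse && nrow(state) > 1) {
          repeat {
            dd <- droplet_diam(state, t, g)
            dm <- as.matrix(stats::dist(state[, c("x", "y")]))
            diag(dm) <- Inf
            touching <- which(dm < outer(dd, dd, `+`) / 2, arr.ind = TRUE)
            if (nrow(touching) == 0) break
            i1 <- min(touching[1, ]); i2 <- max(touching[1, ])
            keep <- if (state$t0[i1] <= state$t0[i2]) i1 else i2
            drop <- setdiff(c(i1, i2), keep)
            d_new <- 2 * fused_radius(dd[i1] / 2, dd[i2] / 2)
            p_new <- 2 * fused_radius(state$plat[i1] / 2, state$plat[i2] / 2)
            w <- (dd / 2)^3
            state$x[keep] <- sum(state$x[c(i1, i2)] * w[c(i1, i2)]) / sum(w[c(i1, i2)])
            state$y[keep] <- sum(state$y[c(i1, i2)] * w[c(i1, i2)]) / sum(w[c(i1, i2)])
            # re-parameterize so the current diameter equals the fused value
            # and growth continues toward the fused plateau
            state$plat[keep] <- p_new
            state$d_nuc[keep] <- solve_dnuc(d_new, state$t0[keep], t, g, p_new)
            fus[[length(fus) + 1]] <- data.frame(frame = fi - 1L,
                                                 parent1 = state$id[keep],
                                                 parent2 = state$id[drop],
                                                 child = state$id[keep])
            state <- state[-drop, , drop = FALSE]
          }
          d <- droplet_diam(state, t, g)
        }
        df <- data.frame(x = state$x, y = state$y, r = d / 2,
                         intensity = rep(intensity, nrow(state)),
                         id = state$id)
        df <- df[df$r * 2 >= min_diameter, , drop = FALSE]
        frames[[fi]] <- droplet_scene(df, background = background, shape = shape,
                                      allow_overlap = TRUE)
        if (nrow(df) > 0)
          gt[[fi]] <- data.frame(frame = fi - 1L, time = t, id = df$id,
                                 x = df$x, y = df$y, r = df$r, intensity = intensity)
      }
      structure(list(frames = frames, timestamps = times,
                     ground_truth = do.call(rbind, gt),
                     fusions = if (length(fus)) do.call(rbind, fus)
                               else data.frame(frame = integer(), parent1 = integer(),
                                               parent2 = integer(), child = integer()),
                     params = list(mode = mode, nucleation_rate = nuc_rate,
                                   growth_rate = g, plateau_diameter = plateau,
                                   fusion = fuse, min_diameter = min_diameter)),
                class = "scene_series")
    }
  })
}

droplet_diam <- function(state, t, g) {
  if (nrow(state) == 0) return(numeric())
  state$d_nuc + (state$plat - state$d_nuc) * (1 - exp(-g * pmax(0, t - state$t0)))
}

# diameter at nucleation that makes the growth law pass through diameter d_now
# at time t (inverted saturating-growth law); exact because d_now never
# exceeds the fused plateau
solve_dnuc <- function(d_now, t0, t, g, plateau) {
  e <- exp(-g * max(0, t - t0))
  (d_now - plateau * (1 - e)) / e
}

place_droplets <- function(n, shape, init_diameter, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  d0 <- rlnorm(n, meanlog = log(init_diameter) - sdlog^2 / 2, sdlog = sdlog)
  xs <- numeric(0); ys <- numeric(0); ds <- numeric(0)
  for (i in seq_len(n)) {
    for (attempt in 1:200) {
      margin <- d0[i] / 2 + 2
      x <- runif(1, margin, shape[2] - 1 - margin)
      y <- runif(1, margin, shape[1] - 1 - margin)
      if (length(xs) == 0 ||
          all(sqrt((xs - x)^2 + (ys - y)^2) > (ds + d0[i]) / 2 + 2)) {
        xs <- c(xs, x); ys <- c(ys, y); ds <- c(ds, d0[i])
        break
      }
    }
  }
  list(id = seq_along(xs), x = xs, y = ys, d0 = ds)
}

# nucleate without overlap against the droplets' current sizes; growth may
# later bring neighbors into contact, which is what drives fusion
try_place_one <- function(state, shape, init_diameter, cv, plateau, t, g) {
  sdlog <- sqrt(log(1 + cv^2))
  d <- rlnorm(1, meanlog = log(init_diameter) - sdlog^2 / 2, sdlog = sdlog)
  d_now <- droplet_diam(state, t, g)
  for (attempt in 1:50) {
    margin <- plateau / 2 + 2
    x <- runif(1, margin, shape[2] - 1 - margin)
    y <- runif(1, margin, shape[1] - 1 - margin)
    if (nrow(state) == 0 ||
        all(sqrt((state$x - x)^2 + (state$y - y)^2) > (d_now + d) / 2 + 1))
      return(data.frame(id = NA_integer_, x = x, y = y, t0 = NA_real_, d_nuc = d))
  }
  NULL
}

#' Simulate a normalized FRAP recovery trace
#'
#' Produces a fluorescence-recovery-after-photobleaching trace following the
#' single-exponential recovery model f(t) = A * (1 - exp(-t / tau)), with
#' prebleach samples at `prebleach_level` at negative times and optional
#' additive Gaussian noise. The generating parameters are attached as ground
#' truth.
#'
#' @param A Mobile (plateau) fraction, 0 < A <= 1.
#' @param tau Recovery timescale in seconds, > 0.
#' @param prebleach_level Intensity of the prebleach samples.
#' @param prebleach_n Number of prebleach samples (at times -n*dt .. -dt).
#' @param sampling_dt Sampling interval, seconds.
#' @param duration Post-bleach duration, seconds. A duration shorter than
#'   `tau` triggers a warning (the fit would be poorly constrained).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return An object of class `frap_trace`: data.frame with columns `time`
#'   (s; bleach at 0) and `intensity`, with attribute `ground_truth`.
#' @export
simulate_frap_trace <- function(A = 0.9, tau = 36, prebleach_level = 1,
                                prebleach_n = 5, sampling_dt = 0.5,
                                duration = 300, noise_sd = 0, seed = NULL) {
  if (tau <= 0) stop("tau must be > 0")
  if (A <= 0 || A > 1) stop("A must satisfy 0 < A <= 1")
  if (duration < tau) warning("duration < tau: recovery fit will be poorly constrained")
  t_pre <- -rev(seq_len(prebleach_n)) * sampling_dt
  t_post <- seq(0, duration, by = sampling_dt)
  f <- c(rep(prebleach_level, prebleach_n), A * (1 - exp(-t_post / tau)))
  times <- c(t_pre, t_post)
  f <- with_seed(seed, {
    if (noise_sd > 0) f + rnorm(length(f), 0, noise_sd) else f
  })
  out <- data.frame(time = times, intensity = f)
  class(out) <- c("frap_trace", "data.frame")
  attr(out, "ground_truth") <- list(A = A, tau = tau,
                                    prebleach_level = prebleach_level,
                                    noise_sd = noise_sd)
  out
}

#' Simulate a turbidity temperature ramp
#'
#' Absorbance at 600 nm versus temperature for a UCST system: clear above the
#' transition, turbid below, following the logistic
#' A(T) = a_max / (1 + exp((T - t_mid) / steepness)). The ramp is sampled
#' every `step` degrees along the protocol of cooling at constant rate;
#' concatenated cool/heat/cool cycles are supported by passing more than two
#' breakpoints.
#'
#' @param t_mid Transition midpoint, deg C.
#' @param steepness Logistic width, deg C, > 0. Values near 0 approach a step.
#' @param a_max Plateau absorbance.
#' @param ramp Temperature breakpoints; default `c(60, 4)` is a single cooling
#'   ramp. `c(60, 4, 60, 4)` gives a cool/heat/cool cycle.
#' @param step Sampling interval, deg C (0.5 by default).
#' @param noise_sd Additive Gaussian noise standard deviation (0 = noise-free).
#' @param seed Integer seed.
#' @return An object of class `turbidity_ramp`: data.frame with columns
#'   `temperature`, `a600`, `segment`, `direction`.
#' @export
simulate_turbidity_ramp <- function(t_mid = 40, steepness = 1, a_max = 1,
                                    ramp = c(60, 4), step = 0.5,
                                    noise_sd = 0, seed = NULL) {
  if (steepness <= 0) stop("steepness must be > 0")
  if (length(ramp) < 2) stop("ramp needs at least two breakpoints")
  if (ramp[1] <= ramp[2]) stop("ramp must start with a cooling segment (start > end)")
  segs <- list()
  for (s in seq_len(length(ramp) - 1)) {
    from <- ramp[s]; to <- ramp[s + 1]
    temps <- seq(from, to, by = if (to < from) -step else step)
    if (s > 1) temps <- temps[-1]  # breakpoint shared with previous segment
    segs[[s]] <- data.frame(temperature = temps,
                            segment = s,
                            direction = if (to < from) "cooling" else "heating")
  }
  out <- do.call(rbind, segs)
  out$a600 <- a_max / (1 + exp((out$temperature - t_mid) / steepness))
  out$a600 <- with_seed(seed, {
    if (noise_sd > 0) pmax(0, out$a600 + rnorm(nrow(out), 0, noise_sd)) else out$a600
  })
  out <- out[, c("temperature", "a600", "segment", "direction")]
  class(out) <- c("turbidity_ramp", "data.frame")
  attr(out, "ground_truth") <- list(t_mid = t_mid, steepness = steepness,
                                    a_max = a_max)
  out
}

#' Default binodal: critical concentration as a function of salt
#'
#' The phase boundary used by [simulate_phase_grid()]: passes through 1 uM at
#' 150 mM NaCl and rises with salt (salt screens the electrostatic
#' interactions that drive condensation, so more protein is needed to demix).
#'
#' @param salt_mM NaCl concentration, mM.
#' @return Critical protein concentration, uM.
#' @export
default_binodal <- function(salt_mM) exp((salt_mM - 150) / 100)

#' Simulate a salt x protein-concentration phase-diagram grid
#'
#' For each (salt, concentration) condition, a frame is rendered with
#' droplets when the condition lies above the binodal (concentration strictly
#' greater than the critical concentration at that salt) and as a uniform
#' background frame otherwise. Ground truth is returned per condition.
#'
#' @param binodal Function salt (mM) -> critical concentration (uM).
#' @param salt_values NaCl levels, mM.
#' @param conc_values Protein concentration levels, uM (must be >= 0).
#' @param optics An [optics_config()].
#' @param noise A [noise_config()] applied to every frame (its `seed`, if any,
#'   is offset per condition so frames differ).
#' @param shape Frame shape.
#' @param n_droplets Droplets rendered per phase-separated condition.
#' @param droplet_radius Mean droplet radius, px.
#' @param intensity,background Interior and background intensities.
#' @param seed Integer seed for droplet placement.
#' @return List with `conditions` (data.frame `salt`, `conc`, `separated`)
#'   and `frames` (list of matrices, same order).
#' @export
simulate_phase_grid <- function(binodal = default_binodal,
                                salt_values = c(100, 150, 200),
                                conc_values = c(0.25, 0.5, 1, 2, 4),
                                optics = optics_config(blur_sigma = 1),
                                noise = noise_config(),
                                shape = c(128L, 128L), n_droplets = 8,
                                droplet_radius = 8, intensity = 100,
                                background = 10, seed = NULL) {
  if (length(salt_values) == 0 || length(conc_values) == 0)
    stop("salt and concentration grids must be non-empty")
  if (any(conc_values < 0)) stop("concentrations must be >= 0")
  grid <- expand.grid(conc = conc_values, salt = salt_values)[, c("salt", "conc")]
  grid$separated <- grid$conc > binodal(grid$salt)
  frames <- vector("list", nrow(grid))
  with_seed(seed, {
    for (i in seq_len(nrow(grid))) {
      ns <- noise
      if (!is.null(ns$seed)) ns$seed <- ns$seed + i
      if (grid$separated[i]) {
        pl <- place_droplets(n_droplets, shape, 2 * droplet_radius, 0.15)
        sc <- droplet_scene(data.frame(x = pl$x, y = pl$y, r = pl$d0 / 2,
                                       intensity = intensity),
                            background = background, shape = shape)
      } else {
        sc <- droplet_scene(NULL, background = background, shape = shape)
      }
      frames[[i]] <- render_scene(sc, optics, ns)
    }
  })
  list(conditions = grid, frames = frames)
}
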