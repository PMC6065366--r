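test_that("rendering reproduces exact disk geometry on a flat background", {
  # zero droplets: constant frame
  sc0 <- droplet_scene(NULL, background = 10, shape = c(32, 32))
  img0 <- render_scene(sc0)
  expect_true(all(img0 == 10))

  # unblurred disk: binary values and exact lattice pixel count
  sc <- droplet_scene(data.frame(x = 64, y = 64, r = 10, intensity = 1),
                      background = 0, shape = c(128, 128))
  img <- render_scene(sc)
  expect_setequal(unique(as.numeric(img)), c(0, 1))
  expect_identical(sum(img == 1), lattice_disk_count(10))

  # r = 3 disk at integer center: integrated intensity = 5 * 29
  sc3 <- droplet_scene(data.frame(x = 16, y = 16, r = 3, intensity = 5),
                       background = 0, shape = c(32, 32))
  img3 <- render_scene(sc3)
  expect_equal(lattice_disk_count(3), 29)
  expect_equal(sum(img3), 5 * 29)
})

test_that("rendering rejects invalid scenes and preserves flux under blur", {
  expect_error(droplet_scene(data.frame(x = 10, y = 10, r = 0, intensity = 1)),
               "radii")
  sc_out <- droplet_scene(data.frame(x = 2, y = 2, r = 10, intensity = 1),
                          background = 0, shape = c(32, 32))
  expect_error(render_scene(sc_out), "outside")
  sc_neg <- droplet_scene(data.frame(x = 16, y = 16, r = 3, intensity = -1),
                          background = 0, shape = c(32, 32))
  expect_error(render_scene(sc_neg), ">= 0")
  expect_error(droplet_scene(data.frame(x = c(10, 14), y = c(10, 10), r = c(4, 4),
                                        intensity = 1), shape = c(32, 32)),
               "overlap")
  # Gaussian blur redistributes but conserves integrated intensity
  sc <- droplet_scene(data.frame(x = 32, y = 32, r = 6, intensity = 3),
                      background = 0, shape = c(64, 64))
  img_b <- render_scene(sc, optics_config(blur_sigma = 1.5))
  expect_equal(sum(img_b), 3 * lattice_disk_count(6), tolerance = 1e-6)
})

test_that("generators are bit-reproducible for a fixed seed", {
  sc <- droplet_scene(data.frame(x = 32, y = 32, r = 6, intensity = 10),
                      background = 1, shape = c(64, 64))
  n <- noise_config(gaussian_sd = 0.5, poisson = TRUE, seed = 99)
  expect_identical(render_scene(sc, noise = n), render_scene(sc, noise = n))

  f1 <- simulate_frap_trace(noise_sd = 0.05, seed = 11)
  f2 <- simulate_frap_trace(noise_sd = 0.05, seed = 11)
  expect_identical(f1, f2)

  s1 <- simulate_timelapse("dissolution", list(k = 0.05), seed = 4)
  s2 <- simulate_timelapse("dissolution", list(k = 0.05), seed = 4)
  expect_identical(s1$ground_truth, s2$ground_truth)

  r1 <- simulate_turbidity_ramp(noise_sd = 0.01, seed = 2)
  r2 <- simulate_turbidity_ramp(noise_sd = 0.01, seed = 2)
  expect_identical(r1, r2)

  g1 <- simulate_phase_grid(seed = 7, noise = noise_config(gaussian_sd = 1, seed = 1))
  g2 <- simulate_phase_grid(seed = 7, noise = noise_config(gaussian_sd = 1, seed = 1))
  expect_identical(g1, g2)
})

test_that("dissolution kinetics follow the configured decay law", {
  # zero rate: radii constant
  s0 <- simulate_timelapse("dissolution", list(k = 0), n_droplets = 5,
                           duration = 20, dt = 5, seed = 1)
  gt <- s0$ground_truth
  rng <- tapply(gt$r, gt$id, function(r) diff(range(r)))
  expect_true(all(rng == 0))

  # exponential decay with k = ln2/20: every droplet halves its diameter in
  # 20 min and ground truth matches the closed form
  k <- log(2) / 20
  s1 <- simulate_timelapse("dissolution", list(k = k), n_droplets = 4,
                           duration = 40, dt = 1, init_diameter = 40,
                           min_diameter = 2, seed = 2)
  gt <- s1$ground_truth
  for (id in unique(gt$id)) {
    tr <- gt[gt$id == id, ]
    expect_equal(tr$r, tr$r[1] * exp(-k * tr$time), tolerance = 1e-12)
    d0 <- 2 * tr$r[1]
    t_half <- tr$time[which.min(abs(2 * tr$r - d0 / 2))]
    expect_equal(t_half, 20)
  }

  # droplets are removed below the resolution floor
  s2 <- simulate_timelapse("dissolution", list(k = 0.2), n_droplets = 3,
                           duration = 60, dt = 2, init_diameter = 20,
                           min_diameter = 4, seed = 3)
  expect_true(all(2 * s2$ground_truth$r >= 4))
  expect_lt(max(s2$ground_truth$time), 60)
  expect_error(simulate_timelapse("dissolution", list(k = 0.1), dt = 0),
               "dt")
})

test_that("assembly fusion conserves droplet volume", {
  expect_equal(fused_radius(4, 4), 4 * 2^(1 / 3), tolerance = 1e-9)
  expect_equal(fused_radius(3, 5)^3, 3^3 + 5^3, tolerance = 1e-9)

  # generated fusion event: child volume equals summed parent volumes
  ser <- simulate_timelapse("assembly",
                            params = list(nucleation_rate = 2, growth_rate = 0.05,
                                          plateau_diameter = 20, fusion = TRUE),
                            n_droplets = 2, duration = 120, dt = 1,
                            shape = c(64, 64), init_diameter = 16, seed = 23)
  expect_identical(nrow(ser$fusions), 1L)
  gt <- ser$ground_truth
  ev <- ser$fusions
  r_child <- gt$r[gt$id == ev$child & gt$frame == ev$frame]
  r_p1 <- gt$r[gt$id == ev$parent1 & gt$frame == ev$frame - 1]
  r_p2 <- gt$r[gt$id == ev$parent2 & gt$frame == ev$frame - 1]
  # parents grow slightly between the last pre-fusion frame and the merge
  expect_equal(r_child^3, r_p1^3 + r_p2^3, tolerance = 0.05)
})

test_that("FRAP traces follow the single-exponential recovery model", {
  # closed form at t = tau
  tr <- simulate_frap_trace(A = 0.8, tau = 10, sampling_dt = 1, duration = 60)
  expect_equal(tr$intensity[tr$time == 10], 0.8 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(tr$intensity[tr$time == 0], 0)
  expect_true(all(tr$intensity[tr$time < 0] == 1))

  # near t = 0 with large tau the ramp is linear with slope A/tau
  tr2 <- suppressWarnings(
    simulate_frap_trace(A = 1, tau = 1e4, sampling_dt = 0.5, duration = 5))
  post <- tr2[tr2$time >= 0, ]
  slope <- diff(post$intensity) / diff(post$time)
  expect_equal(slope, rep(1 / 1e4, length(slope)), tolerance = 1e-3)

  expect_warning(simulate_frap_trace(A = 0.5, tau = 100, duration = 50), "poorly")
  expect_error(simulate_frap_trace(tau = -1), "tau")
  expect_error(simulate_frap_trace(A = 1.5), "A must")
})

test_that("turbidity ramps sample the logistic transition per protocol", {
  rp <- simulate_turbidity_ramp(t_mid = 40, steepness = 1, a_max = 0.8)
  # 0.5 degC sampling from 60 down to 4
  expect_equal(rp$temperature[1], 60)
  expect_equal(tail(rp$temperature, 1), 4)
  expect_equal(unique(round(diff(rp$temperature), 10)), -0.5)
  expect_equal(rp$a600[rp$temperature == 40], 0.4, tolerance = 1e-12)

  # steepness -> 0 approaches a step function
  st <- simulate_turbidity_ramp(t_mid = 40, steepness = 1e-6)
  expect_true(all(st$a600[st$temperature > 40.01] < 1e-6))
  expect_true(all(st$a600[st$temperature < 39.99] > 1 - 1e-6))

  # cool/heat/cool cycling: turbidity appears, disappears, reappears
  cyc <- simulate_turbidity_ramp(t_mid = 40, steepness = 1,
                                 ramp = c(60, 4, 60, 4))
  a <- cyc$a600
  expect_gt(max(a[cyc$segment == 1]), 0.99)
  expect_lt(min(a[cyc$segment == 2 & cyc$temperature > 55]), 0.01)
  expect_gt(max(a[cyc$segment == 3]), 0.99)
  expect_error(simulate_turbidity_ramp(steepness = 0), "steepness")
  expect_error(simulate_turbidity_ramp(ramp = c(4, 60)), "cooling")
})

test_that("phase grids mark conditions above the binodal as separated", {
  # zero concentration everywhere: nothing separates
  g0 <- simulate_phase_grid(conc_values = 0, salt_values = c(100, 150), seed = 1)
  expect_true(all(!g0$conditions$separated))
  expect_true(all(vapply(g0$frames, function(f) diff(range(f)) == 0, TRUE)))

  # default binodal at 150 mM: 2 uM separated, 0.5 uM uniform
  g <- simulate_phase_grid(salt_values = 150, conc_values = c(0.5, 2), seed = 2)
  expect_identical(g$conditions$separated, c(FALSE, TRUE))
  expect_equal(diff(range(g$frames[[1]])), 0)
  expect_gt(diff(range(g$frames[[2]])), 0)

  # monotone binodal: one soluble -> separated switch per salt column
  gg <- simulate_phase_grid(seed = 3)
  for (s in unique(gg$conditions$salt)) {
    col <- gg$conditions[gg$conditions$salt == s, ]
    col <- col[order(col$conc), ]
    expect_true(all(diff(col$separated) >= 0))
  }
  expect_error(simulate_phase_grid(conc_values = c(-1, 2)), "concentrations")
})
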