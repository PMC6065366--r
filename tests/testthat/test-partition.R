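two_channel_scene <- function(ratios, r = 12, background = 10,
                              shape = c(160, 160), blur = 1, seed = 1) {
  # one droplet per ratio, well separated on a grid
  n <- length(ratios)
  gx <- ((seq_len(n) - 1) %% 3) * 50 + 30
  gy <- ((seq_len(n) - 1) %/% 3) * 50 + 30
  sc <- droplet_scene(data.frame(x = gx, y = gy, r = r,
                                 intensity = background * ratios),
                      background = background, shape = shape)
  render_scene(sc, optics_config(blur_sigma = blur), noise_config(seed = seed))
}

test_that("enrichment index is exact on uniform and unblurred scenes", {
  det <- data.frame(x = 32, y = 32, r = 8)
  u <- matrix(3, 64, 64)
  for (bg in c("annulus", "global")) {
    e <- enrichment_index(u, det, erosion = 2, background = bg)
    expect_equal(e$per_droplet$ei, 1)
  }
  # unblurred disk interior 270 on background 10: EI = 27 exactly
  sc <- droplet_scene(data.frame(x = 32, y = 32, r = 8, intensity = 270),
                      background = 10, shape = c(64, 64))
  img <- render_scene(sc)
  e27 <- enrichment_index(img, det, erosion = 2)
  expect_equal(e27$per_droplet$ei, 27)
})

test_that("enrichment on blurred scenes matches the ground-truth ratio", {
  img <- two_channel_scene(27, r = 12)
  det <- detect_droplets(img, 8, 16)
  expect_identical(nrow(det), 1L)
  e <- enrichment_index(img, det, erosion = 2)
  expect_equal(e$per_droplet$ei, 27, tolerance = 0.05)
  # pixel-mask oracle from known geometry: eroded true mask vs far field
  mask <- which(outer((0:159 - 30)^2, (0:159 - 30)^2, `+`) <= 10^2)
  truth <- mean(img[mask]) / median(img[-which(outer((0:159 - 30)^2,
                                                     (0:159 - 30)^2, `+`) <= 20^2)])
  expect_equal(e$per_droplet$ei, truth, tolerance = 0.02)
})

test_that("EI is scale-invariant but not offset-invariant", {
  img <- two_channel_scene(4, r = 12)
  det <- detect_droplets(img, 8, 16)
  e1 <- enrichment_index(img, det, erosion = 2)
  e2 <- enrichment_index(img * 13, det, erosion = 2)
  expect_equal(e1$per_droplet$ei, e2$per_droplet$ei, tolerance = 1e-9)
  e3 <- enrichment_index(img + 100, det, erosion = 2)
  expect_gt(abs(e3$per_droplet$ei - e1$per_droplet$ei), 0.5)
  # offset subtraction restores the ratio
  e4 <- enrichment_index(img + 100, det, erosion = 2, offset = 100)
  expect_equal(e4$per_droplet$ei, e1$per_droplet$ei, tolerance = 1e-9)
})

test_that("EI is insensitive to the erosion choice on large droplets", {
  img <- two_channel_scene(20, r = 12)
  det <- detect_droplets(img, 8, 16)
  e2 <- enrichment_index(img, det, erosion = 2)
  e3 <- enrichment_index(img, det, erosion = 3)
  expect_lt(abs(e3$per_droplet$ei - e2$per_droplet$ei) / e2$per_droplet$ei, 0.02)
})

test_that("reported enrichment ordering is reproduced across cargo classes", {
  # four cargo classes: excluded (<1), single RGG (~4), SZ pair (~20),
  # double RGG (~27); droplet geometry is detected on the scaffold channel
  # so dim cargo signals do not bias the segmentation
  ratios <- c(excluded = 0.8, single = 4, sz = 20, double = 27)
  gx <- c(30, 80, 130, 30); gy <- c(30, 30, 30, 80)
  sc <- droplet_scene(data.frame(x = gx, y = gy, r = 12,
                                 scaffold = 200, cargo = 10 * ratios),
                      background = c(scaffold = 10, cargo = 10),
                      shape = c(160, 160))
  opt <- optics_config(blur_sigma = 1)
  scaffold_img <- render_scene(sc, opt, channel = "scaffold")
  det <- detect_droplets(scaffold_img, 8, 16)
  expect_identical(nrow(det), 4L)
  cargo_img <- render_scene(sc, opt, channel = "cargo")
  e <- enrichment_index(cargo_img, det, erosion = 2)
  per <- e$per_droplet
  per <- per[order(1000 * per$y + per$x), ]   # grid order = ratio order
  expect_true(all(diff(per$ei) > 0))
  expect_lt(per$ei[1], 1)
  expect_equal(per$ei, unname(ratios), tolerance = 0.06)
})

test_that("co-recruitment correlates per-droplet enrichment across channels", {
  img1 <- two_channel_scene(c(20, 22, 25, 27), r = 12)
  det <- detect_droplets(img1, 8, 16)
  expect_identical(nrow(det), 4L)
  # identical channels: correlation 1, all colocalized
  cr <- co_recruitment(img1, img1, det)
  expect_equal(cr$correlation, 1)
  expect_true(all(cr$per_droplet$colocalized))
  # uniform second channel: EI 1, no colocalization, undefined correlation
  cr2 <- co_recruitment(img1, matrix(10, 160, 160), det)
  expect_equal(cr2$per_droplet$ei_ch2, rep(1, 4))
  expect_true(is.na(cr2$correlation))
  expect_equal(cr2$fraction_colocalized, 0)
  # dual-cargo scene at the reported indices 20 and 27
  img2 <- two_channel_scene(c(27, 27, 27, 27), r = 12)
  cr3 <- co_recruitment(img1, img2, det)
  expect_gte(cr3$fraction_colocalized, 0.95)
})

test_that("release traces recover the programmed EI decay half-time", {
  # EI decays 20 -> 1 with rate ln2/60; droplet geometry fixed by scaffold
  times <- seq(0, 240, 20)
  ei_t <- 1 + 19 * exp(-log(2) / 60 * times)
  frames <- lapply(ei_t, function(ei) two_channel_scene(ei, r = 12))
  det <- detect_droplets(frames[[1]], 8, 16)
  dets <- replicate(length(frames), det, simplify = FALSE)
  rt <- release_trace(frames, dets, times, erosion = 2)
  expect_equal(rt$half_time, 60, tolerance = 0.1 * 60)
  expect_true(all(rt$trace$n == 1))

  # constant EI: no release
  frames_c <- replicate(4, two_channel_scene(20, r = 12), simplify = FALSE)
  rt_c <- release_trace(frames_c, replicate(4, det, simplify = FALSE),
                        c(0, 1, 2, 3), erosion = 2)
  expect_true(is.na(rt_c$half_time) ||
                !isTRUE(attr(rt_c$half_time, "reached")))
  expect_equal(diff(range(rt_c$trace$mean_ei)), 0, tolerance = 1e-9)
})
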