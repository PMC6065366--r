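#!/usr/bin/env Rscript
# Cargo partitioning: enrichment indices across the four cargo classes
# (excluded, single RGG, SZ pair, double RGG), two-channel co-recruitment,
# and time-resolved cargo release with intact scaffold droplets.

suppressPackageStartupMessages(library(dropletkit))
dir.create("results", showWarnings = FALSE)
opt <- optics_config(blur_sigma = 1)

# four cargo classes in one two-channel scene; geometry from the scaffold
ratios <- c(excluded = 0.8, single_RGG = 4, SZ = 20, double_RGG = 27)
sc <- droplet_scene(data.frame(x = c(30, 80, 130, 30), y = c(30, 30, 30, 80),
                               r = 12, scaffold = 200,
                               cargo = 10 * unname(ratios)),
                    background = c(scaffold = 10, cargo = 10),
                    shape = c(160, 160))
det <- detect_droplets(render_scene(sc, opt, channel = "scaffold"), 8, 16)
e <- enrichment_index(render_scene(sc, opt, channel = "cargo"), det,
                      erosion = 2)
per <- e$per_droplet[order(1000 * e$per_droplet$y + e$per_droplet$x), ]
per$class <- names(ratios); per$truth <- unname(ratios)
write.csv(per, "results/enrichment_classes.csv", row.names = FALSE)
cat("Enrichment index per cargo class (measured vs ground truth):\n")
print(per[, c("class", "truth", "ei")], row.names = FALSE)

# dual-cargo co-recruitment (GFP-SZ2 + RFP-SZ2 style)
img1 <- render_scene(droplet_scene(
  data.frame(x = c(40, 100, 60), y = c(40, 60, 110), r = 12, intensity = 200),
  background = 10, shape = c(160, 160)), opt)
det2 <- detect_droplets(img1, 8, 16)
cr <- co_recruitment(img1, img1 * 0.9, det2, erosion = 2)
cat(sprintf("Dual-cargo scene: %d/%d droplets colocalized, EI correlation %.3f\n",
            sum(cr$per_droplet$colocalized), nrow(cr$per_droplet),
            cr$correlation))

# triggered release: cargo EI decays 20 -> 1 at ln2/60 per min while the
# scaffold (and hence droplet geometry) stays constant
times <- seq(0, 240, 20)
ei_t <- 1 + 19 * exp(-log(2) / 60 * times)
frames <- lapply(ei_t, function(ei) render_scene(droplet_scene(
  data.frame(x = 60, y = 60, r = 12, intensity = 10 * ei),
  background = 10, shape = c(120, 120)), opt))
scaffold_det <- detect_droplets(render_scene(droplet_scene(
  data.frame(x = 60, y = 60, r = 12, intensity = 200),
  background = 10, shape = c(120, 120)), opt), 8, 16)
rt <- release_trace(frames, replicate(length(frames), scaffold_det,
                                      simplify = FALSE), times, erosion = 2)
write.csv(rt$trace, "results/release_trace.csv", row.names = FALSE)
cat(sprintf("Release half-time: %.1f min (programmed 60 min); droplet count constant: %s\n",
            rt$half_time, all(rt$trace$n == rt$trace$n[1])))
cat("wrote results/enrichment_classes.csv, results/release_trace.csv\n")
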