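# dropletkit

Quantification toolkit for experiments on engineered, protease-controllable
protein droplets built from multivalent RGG domains (the arginine/glycine-rich
low-complexity domain of LAF-1). Proteins with RGG domains in tandem phase
separate into micrometre-scale liquid condensates with upper-critical-solution
(UCST) behavior; inserting protease cut sites, solubility tags (MBP), and
SYNZIP coiled-coil pairs into the scaffold makes droplet assembly,
disassembly, cargo recruitment, and cargo release enzymatically switchable.
Quantifying such experiments takes a pipeline of standard measurements, all
implemented here:

* **Detection** — circular Hough transform over microscopy frames: Sobel edge
  map, circumference-normalized (x, y, r) accumulator, subpixel refinement.
  Accuracy is documented and tested down to its 10 px-diameter floor
  (≈ 1 µm at the default 0.1 µm/px).
* **Tracking** — optimal (Hungarian) frame-to-frame assignment minimizing
  squared displacement, with gap memory, plus post-hoc fusion annotation by
  volume conservation (r³ additivity).
* **Kinetics** — normalized population diameter traces d(t)/d(0) with
  survivor counts, interpolated 50%-diameter times; turbidity transition
  temperatures as half-max crossings (or logistic midpoints) on cooling
  ramps sampled every 0.5 °C; phase diagrams as presence/absence grids with
  geometric-mean bracketing of the critical concentration.
* **Partitioning** — per-droplet enrichment index EI = mean interior
  intensity / local annulus (or global) background, two-channel
  co-recruitment, and release half-times on (EI(t)−1)/(EI(0)−1), with
  droplet geometry taken from a scaffold channel.
* **FRAP** — photobleaching correction, full-scale normalization anchored at
  the first post-bleach point, nonlinear fit of f(t) = A(1 − e^(−t/τ)), and
  D ≈ r²/τ for partial-spot bleaching.
* **Constructs** — protease digestion (TEV: ENLYFQ↓G, thrombin: LVPR↓GS,
  HRV3C: LEVLFQ↓GP), average fragment masses, RGG-valency census, and
  rule-table prediction of phase state (valency → transition temperature,
  MBP override) and cargo recruitment class — enough to express the
  two-protease AND gate and MBP-gated assembly.
* **Synthetic data** — seeded generators for images, movies (dissolution,
  assembly with fusion), FRAP traces, turbidity ramps, and phase-diagram
  grids, each with bundled ground truth, so the full pipeline is testable
  end to end.

See `vignettes/droplet-quantification.Rmd` for the models, parameter
defaults, and design decisions.

## Worked example

The numbered drivers under `analysis/` run the package's analyses and write
their tables to `results/`. The dissolution study
(`analysis/01_simulate_dissolution.R` → `02_detect_track.R` →
`03_dissolution_kinetics.R`) simulates a protease-triggered dissolution
movie at decay rate k = 0.0347 min⁻¹ (diameter halves in ~20 min), renders
it with blur and noise, re-detects and links the droplets from the TIFF, and
summarizes the kinetics. Output:

```
Simulated 4 droplets over 13 frames (dt = 2.5 min) at k = 0.0347 /min;
ground-truth half-time of every droplet: 19.98 min
Linked 52 detections into 4 trajectories.
Median radius error vs ground truth: 0.27 px (90%: 0.52 px)
Measured 50%-diameter time: 20.3 min (truth 20.0 min; +1.4%)
Max deviation from exp(-k t): 0.020
```

Every rendered droplet was re-found in every frame with sub-half-pixel
radius accuracy, and the measured population half-time lands within 1.4% of
the programmed truth. The other drivers report, for example:

```
Noiseless fit: A = 0.900, tau = 36.00 s, D = 0.0851 um^2/s (2 s.f.: 0.085)
Cooling ramp 60 -> 4 degC: transition at 40.00 degC (half-max)
Enrichment index per cargo class (measured vs ground truth):
      class truth         ei
   excluded   0.8  0.8006704
 single_RGG   4.0  3.9899441
         SZ  20.0 19.9363126
 double_RGG  27.0 26.9128488
TEV digestion of RGG-x-RGG: 2 fragments, average masses 17843.0 and 17907.0 Da
AND gate (25 degC): {} turbid/50, {TEV} turbid/40, {HRV3C} turbid/40,
                    {TEV,HRV3C} soluble/15
```

i.e. the FRAP path reproduces the tandem-RGG diffusion coefficient
(0.085 µm²/s), the turbidity estimator recovers the 40 °C miscibility
boundary, the partition path recovers the four reported cargo enrichment
classes in order, and the constructs module reproduces the predicted TEV
fragment masses and the protease AND gate. The construct sequence shipped in
`inst/extdata/` is a synthetic stand-in engineered to the published fragment
masses (see the vignette).

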