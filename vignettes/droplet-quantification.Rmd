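---
title: "Quantifying engineered RGG-droplet experiments: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying engineered RGG-droplet experiments: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropletkit)
```

# Scope

`dropletkit` quantifies in-vitro experiments on engineered multivalent
RGG-domain proteins: liquid droplets that assemble and disassemble under
protease control, recruit tagged cargo, and exchange material measurably by
FRAP. The package covers five measurement paths — droplet detection and
tracking in time-lapse images, dissolution/assembly kinetics, turbidity
transition temperatures and phase diagrams, cargo enrichment and release,
and FRAP recovery fitting — plus a rule-based constructs module that
predicts digestion products, fragment masses, and phase/recruitment
outcomes. A synthetic-data generator produces every input with known ground
truth, so each estimator is validated end to end without any instrument
data.

This vignette records the models, the tunable parameters, and the design
decisions taken where the underlying experimental conventions were open.

# Image model and droplet detection

## Synthetic image model

Rendered frames are flat background plus uniform-interior disks, convolved
with a Gaussian point-spread function, with optional Gaussian read noise and
Poisson shot noise. Coordinates are 0-based with pixel centers at integers;
a pixel belongs to a droplet when its center satisfies
$(x - x_0)^2 + (y - y_0)^2 \le r^2$. The default pixel size is 0.1 µm/px, so
a 1 µm droplet spans about 10 pixels — the scale at which circular-Hough
accuracy begins to degrade, which the detection module treats as its
validity floor. The model deliberately omits vignetting, surface wetting
(experimental chambers are passivated), cytoplasmic texture, and 3D
sectioning; consequences are discussed under Limitations.

## Circular Hough transform

`detect_droplets()` builds an edge map from the Sobel gradient magnitude,
thresholded at a fraction of its maximum (`edge_threshold`, default 0.25; a
relative threshold keeps the geometry invariant to intensity scaling). Every
edge pixel votes for candidate centers at each radius in `[r_min, r_max]`;
votes are divided by the number of distinct perimeter offsets so that one
`vote_threshold` (default 0.35, roughly "fraction of the perimeter
supported") is meaningful across the whole radius range. Candidates are
accepted greedily in descending score. A candidate is suppressed when its
center lies closer to an accepted center than the sum of the two radii plus
a 2 px margin: distinct droplets cannot be closer than touching, and a
strong circle of radius $R$ casts vote echoes on rings up to distance
$R + r$ that this rule absorbs. For overlapping (mid-fusion) droplets the
higher-scoring circle therefore wins; fusion is handled downstream by the
tracker. Accepted centers are refined to subpixel precision by the vote
centroid over a 5×5 accumulator neighborhood, and the radius by a
vote-weighted mean over adjacent radius planes — this sub-radius
interpolation is what lets dissolution traces shrink smoothly rather than in
1 px steps.

Two numerical details: a frame whose relative intensity range is below
$10^{-9}$ is treated as constant and yields no detections (FFT-based
blurring of a uniform frame otherwise leaves ~$10^{-13}$ ripples that a
relative edge threshold would amplify); and intensity measurement
(`measure_droplet()`) sums pixels whose centers fall in the optionally
eroded disk, so an unblurred disk of radius 3 at an integer center contains
exactly 29 pixels.

Detection accuracy is tested on noiseless disks (radius error ≤ 1 px for
diameters above 10 px), against an exhaustive normalized-cross-correlation
template oracle on small noisy frames, and for translation equivariance and
intensity-scale invariance.

# Trajectory linking and fusion

`link_trajectories()` assigns detections between consecutive frames by
minimizing total squared displacement with a Hungarian-style optimal
assignment (shortest augmenting paths), not greedy nearest-neighbor;
candidates beyond `max_disp` (default 5 px/frame) are forbidden. Tracks
missing from a frame persist for up to `memory` frames (default 2) with a
displacement budget scaled by the gap length. Rows are processed in
trajectory-id order, so equal-cost optima resolve deterministically toward
the smaller id. The implementation is checked against brute-force
enumeration of all per-frame permutations for ≤3 droplets over ≤6 frames.

Fusion is annotated post hoc rather than modeled inside the linker: an
event is recorded when a trajectory ends in contact with a neighbor and a
trajectory in the next frame has $r^3$ equal to the parents' summed $r^3$
within a relative `volume_tol` (default 0.1 — parents keep growing slightly
between the last pre-fusion frame and the merge, so exact equality is not
attainable at finite frame rate). The synthetic assembly generator conserves
volume exactly at the merge instant: both the instantaneous diameter and the
growth plateau combine as cube roots of summed cubes, and the child
continues under the older parent's id.

# Kinetics summaries

Dissolution movies use per-droplet diameter decay
$d(t) = d_0 e^{-kt}$ (a linear option exists); the generator default
$k = 0.0347\ \mathrm{min}^{-1}$ halves the diameter in ~20 min, matching the
published experimental regime of 50% diameter loss within 30 min.
`diameter_traces()` normalizes each trajectory to its own initial diameter
and averages droplets present at $t = 0$; droplets that fall below the
detection floor simply leave the average, and the survivor count is reported
per time point so the censoring is visible (the original analysis does not
state its censoring rule; averaging survivors of the $t=0$ cohort is this
package's declared choice, and assembly movies can instead include
late-nucleating droplets via `require_first_frame = FALSE`).
`half_time()` interpolates the first crossing linearly between samples.

Turbidity ramps follow the experimental protocol: absorbance at 600 nm
sampled every 0.5 °C while cooling (default 60 → 4 °C), generated as a
logistic $A(T) = a_{max} / (1 + e^{(T - t_{mid})/s})$. Because no numeric
definition of "transition temperature" accompanies the published
"approximately 40 °C", the package declares one: the temperature at which
absorbance first exceeds half the cooling segment's maximum, linearly
interpolated (a logistic-fit midpoint mode is provided as an alternative).
Both are invariant to absorbance scaling; concatenated cool/heat/cool cycles
are analyzed per segment and reproduce the appear/disappear/reappear
behavior with cooling transitions agreeing within 0.5 °C.

Phase diagrams are presence/absence grids, not fitted binodals: a condition
is called separated when at least `min_droplets` (default 3) droplets are
detected, and the critical concentration per salt is the geometric mean of
the highest soluble and lowest separated level — the bracketing estimator
appropriate to a discrete concentration grid. Columns where a separated cell
sits below a soluble one are flagged inconsistent and yield no estimate. The
generator's default binodal passes through 1 µM at 150 mM NaCl and rises
with salt (screening); with levels {0.25, 0.5, 1, 2, 4} µM the estimator
returns $\sqrt{1 \cdot 2} \approx 1.4$ µM, bracketing the truth. Note the
boundary convention: a condition exactly on the binodal is soluble
(separation requires concentration strictly above it).

# Cargo enrichment, co-recruitment, and release

The enrichment index (EI) of a droplet is mean interior intensity divided by
an outside estimate. The interior mask is eroded 2 px by default to exclude
the blurred rim (on blurred droplets with $r \ge 10$ px the estimate moves
by <2% between erosion 2 and 3 px, which is tested). "Outside" defaults to a
per-droplet annulus from $r+3$ to $r+8$ px excluding all dilated droplet
masks — robust to uneven illumination — with a global fallback (median of
pixels outside every dilated mask) used automatically, with a warning, when
an annulus is fully occluded. Medians are used for background estimates,
means for interiors. EI is invariant to multiplicative intensity scaling and
deliberately *not* to additive offsets; an optional camera-offset
subtraction restores the ratio interpretation when the detector pedestal
matters. Per-droplet means (not line scans) are the implemented estimator.

Droplet geometry for cargo measurements is taken from a scaffold channel,
for two reasons: dim or excluded cargo (EI < 1) is not reliably segmentable
in its own channel, and release kinetics must be decoupled from droplet
shrinkage. `co_recruitment()` pairs per-droplet EIs across two registered
channels and reports their Pearson correlation plus a colocalization call
(both EIs > 2 by default). `release_trace()` reports population EI versus
time and a release half-time defined on the excess enrichment,
$(EI(t) - 1)/(EI(0) - 1) = 0.5$, undefined when $EI(0) \le 1$.

Synthetic partitioning scenes use the published interior/exterior ratios as
ground truth — excluded ≈ 0.8, single-RGG-tagged ≈ 4, SYNZIP-recruited ≈ 20,
double-RGG-tagged ≈ 27 — and the full detect-then-measure path reproduces
both the values (within 5%) and the strict ordering.

# FRAP

Normalization is two-step: acquisition photobleaching is corrected by
dividing by a reference-region trace rescaled to its prebleach mean (the
reference may be an unbleached droplet or the whole field; both enter
through the same optional `reference` column), then the trace is full-scale
normalized anchored at the first post-bleach point,
$f(t) = (I(t) - I(0^+)) / (I_{pre} - I(0^+))$. The anchor choice is the
package's own convention. `fit_recovery()` fits
$f(t) = A(1 - e^{-t/\tau})$ by nonlinear least squares (Levenberg–Marquardt,
parameter tolerance $10^{-10}$), initialized at $A_0$ = last observed value
and $\tau_0$ = first time the trace exceeds $0.63 A_0$. Degenerate inputs
(flat traces, fewer than 5 post-bleach points) raise errors rather than
returning garbage; a residual RMS above 0.1, or $A > 1.2$, flags the fit low
confidence. The diffusion coefficient uses the half-bleach-spot
approximation $D = r^2/\tau$, valid for partial bleaching of a spot much
smaller than the droplet (~10× smaller diameter); for whole-droplet
bleaching the conversion is flagged not interpretable. In the tandem-RGG
regime ($\tau = 36$ s, $r = 1.75$ µm) the pipeline returns
$D = 0.085\ \mu m^2/s$ to two significant figures, and over 50 noisy
replicates (noise sd 0.05) the median $\hat{D}$ stays within
[0.080, 0.090] µm²/s.

# Constructs: digestion, masses, and rule tables

Cleavage rules: TEV cuts ENLYFQ↓G, thrombin LVPR↓GS, and HRV3C LEVLFQ↓GP.
The HRV3C motif is the canonical recognition sequence, declared explicitly
because experimental protocols typically do not print it; it is
overridable via `protease_sites()`-style rule lists. Digestion is complete
and simultaneous at all selected sites (the experiments this models report
near-100% cleavage); partial digestion is out of scope. Digestion is
idempotent and conserves mass up to one water (18.0153 Da) per cut, which is
tested to 0.01 Da.

Masses are average (not monoisotopic) — the right convention for linear-mode
MALDI-TOF of ~18 kDa proteins — computed from a bundled Expasy-style residue
table plus one water per chain, no PTMs, initiator Met as written. The
implementation is cross-checked in tests against frozen values computed
independently from elemental composition.

The bundled FASTA (`inst/extdata/RGG_x_RGG_synthetic.fasta`) is a
**synthetic stand-in**, not the real plasmid sequence (which lives in the
original supplementary material and is not redistributed here): an RGG-like
low-complexity sequence (R/G/Y/D/S-rich repeats) carrying a single TEV site,
constructed so its two TEV fragments have average masses 17,843 and
17,907 Da — the published predicted values for the real construct. The
digest/mass machinery treats it like any sequence; what the stand-in cannot
show is agreement of the *sequence itself* with the real plasmid.

Phase behavior is encoded as a measured rule table, not thermodynamics:
transition temperature by RGG valency (1 → 15 °C, 2 → 40 °C, 3 → 50 °C;
empirical point estimates, required to increase with valency), an MBP
override (MBP-tagged species stay soluble), and recruitment classes
(untagged → excluded, 1×RGG → EI ≈ 4, SZ2-with-SZ1-scaffold → EI ≈ 20,
2×RGG → EI ≈ 27). `predict_phase_state()` refuses valencies beyond the
table rather than extrapolating. These rules reproduce the protease AND
gate — the triplet construct stays turbid at 25 °C under either single
protease and dissolves (threshold 15 °C) only under both — and MBP-gated
assembly.

# Synthetic-data generator: fidelity and non-goals

The generator emulates: droplet radii of 1–20 µm at 0.1 µm/px; optical blur
and read/shot noise; exponential (or linear) dissolution with removal below
a resolution floor (default 3 px diameter); Poisson-in-time nucleation with
saturating growth and volume-conserving pairwise fusion; single-exponential
FRAP recovery with prebleach samples; logistic turbidity ramps sampled per
the 1 °C/min, 0.5 °C protocol; and two-channel scenes with configurable
in/out ratios. Nucleation size distributions are exposed as a configurable
lognormal (CV 0.1 by default) without any claim of fidelity — the source
experiments do not report one.

Not emulated (and therefore not demonstrated by passing tests): Ostwald
ripening and coalescence-driven coarsening statistics, 3D sectioning,
uneven illumination, wetting, autofluorescent background texture, detector
nonlinearity. Estimators that are robust here may still need illumination
correction on real microscope data; the EI annulus background and the
relative Hough thresholds are the designed-in mitigations.

Every generator accepts a seed and restores the caller's RNG state;
identical configuration and seed give bit-identical output, which is under
test for every generator.

# Problem sizes and runtimes

The validation suite runs on deliberately modest sizes: 96×96 to 512×512 px
frames, 4–10 droplets, 13-frame movies, 50-replicate Monte-Carlo FRAP runs,
and a 20-movie dissolution-recovery study (each movie re-analyzed through
the full detect → track → kinetics path, with ≥18/20 required to land
within ±10% of the 20 min half-time; in practice 20/20 do). These sizes keep
the whole suite under a few minutes on one core while leaving every
estimator in the regime it is designed for (droplet diameters above the
10 px accuracy floor, recovery traces ~8× longer than τ).

# Known limitations

* Radius estimates below 10 px diameter carry no accuracy guarantee, so
  dissolution traces are censored once droplets approach the floor; the
  reported survivor counts make the bias inspectable but do not remove it.
* The tracker has no motion model; droplets are assumed near-stationary
  between frames relative to `max_disp`. Splitting events are not detected.
* The release half-time assumes a monotone EI decay; transient re-uptake
  would be reported as the first crossing.
* Rule-table predictions are empirical lookups: they interpolate nothing
  and refuse unseen valencies by design.
* The synthetic construct sequence validates arithmetic, not biology; real
  plasmid records should be supplied as FASTA for real analyses.
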