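---
title: "Methods: droplet metrology, Poisson occupancy, and 3D invasion quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: droplet metrology, Poisson occupancy, and 3D invasion quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gelbead quantifies droplet-microfluidic invasion assays in which cancer
cells are encapsulated in ~100 µm Matrigel beads (a basement-membrane
mimic) that are then embedded in collagen I (a stromal mimic). Three
measurements drive such an assay: whether the droplet maker produces
monodisperse beads at a useful rate, how many cells each bead receives,
and how far cells invade out of the bead into the surrounding matrix.
This vignette describes the models and algorithms behind each, the
parameters that matter, and the choices made where more than one
reasonable design existed.

## Droplet sizing and monodispersity

Bright-field videos of the production channel show droplets as dark
rings translating across the frame. `detect_circles()` applies a
circular Hough transform: Sobel edge pixels vote at distance *r* along
±gradient for every candidate radius, votes are pooled in a 3×3 window
and normalised by the perimeter 2π*r*, and accumulator peaks are refined
to sub-pixel precision with an algebraic least-squares circle fit on the
supporting edge pixels. Voting along the gradient (rather than over the
full perimeter) keeps the accumulator sharp and the cost linear in edge
pixels; the refinement step removes the integer-bin bias that would
otherwise propagate into the mean diameter.

Key parameters (pixels unless noted):

* `radius_range` — the search interval. The shipped CLI default of
  35–65 px assumes ~1 µm/px optics and ~100 µm droplets; at other
  magnifications scale accordingly (the synthetic video default uses
  2 µm/px, hence 15–35 px in the examples).
* `sensitivity` (0–1, default 0.9) — peaks scoring at least
  `(1 − sensitivity)` of the strongest peak are kept. There is also an
  absolute floor `min_score = 0.25` so empty or noisy frames yield no
  detections rather than weak false positives.
* `min_separation` — non-maximum suppression distance, default the
  minimum search radius.

Detections are linked frame-to-frame by greedy nearest-neighbour
association (`link_tracks()`): the closest (track, detection) pairs
within `max_displacement` are matched first; unmatched detections open
new tracks; a track may bridge at most `max_gap` skipped frames
(default 0). Greedy association is appropriate because droplets move
quasi-unidirectionally at near-constant spacing; it is *not* a global
assignment and would mis-link paths that cross.

To prevent double counting, a droplet is counted once, and only when its
track crosses the vertical centre line of the frame
(`count_center_crossings()`): the sign of `center_x − line` must change
along the track. A sample lying exactly on the line is resolved by the
next off-line sample, and multiple crossings still count once.

`summarize_sizes()` reports, over counted tracks only, the count *N*,
the mean diameter *D*~av~, and the dispersity

> Ð = sd(diameters) / mean(diameters),

reported as a percent. Two deliberate choices: the per-track diameter is
the **median** of 2·radius over the track's detections (robust to
partial rings at the frame edges), and the standard deviation is the
**population** form, since Ð describes the distribution itself; at
*N* ≈ 10³ the difference from the sample form is negligible. Ð is scale
invariant, so it is unaffected by pixel-size calibration errors that
rescale every diameter equally.

## Poisson occupancy, throughput and loading arithmetic

With cells arriving independently at the flow-focusing junction, the
number of cells per droplet follows a Poisson law:

> P(k cells) = λ^k e^(−λ) / k!,

with λ the mean number of cells per droplet. The package evaluates the
pmf in log space (`poisson_pk()`), estimates λ as the arithmetic mean of
per-droplet counts (the maximum-likelihood estimate,
`estimate_lambda()`), and reports occupancy in the conventional 0 / 1 /
2 / 3+ bins. The 3+ bin is always the closed form 1 − P₀ − P₁ − P₂,
never a truncated sum, so the four proportions sum to one exactly.

`goodness_of_fit()` adds a Pearson chi-square over those bins — an
extension beyond a visual observed-versus-expected comparison, and
labelled as such. Degrees of freedom are bins − 1 when λ is supplied
externally (e.g. counted at the junction) and bins − 2 when λ is
estimated from the same data; bins with expected count below 1 are
merged into their smaller neighbour, and samples under 20 droplets are
flagged rather than refused.

Unit conversions are centralised in two exact constants (1 µL = 10⁹ µm³,
1 mL = 10¹² µm³) because volume-unit mistakes are the dominant bug risk
in this arithmetic. On the printed operating point — 1 µL/min dispersed
flow, 100 µm droplets — `droplet_rate()` gives ≈ 1910 droplets/min, and
an occupancy of 16–27 % translates to ≈ 288–486 cell-bearing beads per
minute (`cell_bearing_rate()`). The nominal rate implied by the loading
density, `nominal_lambda(2.5e6, 100)` ≈ 1.31, exceeds the λ ≈ 0.17–0.31
implied by that occupancy range: the package reproduces this gap as a
property of the numbers (cells sediment in the supply tubing before
encapsulation; the package does not model the kinetics).

## 3D nucleus segmentation and invasion metrics

Confocal stacks of stained nuclei have much coarser resolution along z
than in x–y, which biases any watershed towards x–y splits. The pipeline
in `segment_nuclei()` is:

1. **z inflation** (`interpolate_z()`): insert linearly interpolated
   planes until the z spacing roughly matches x–y
   (`ceiling(dz/dx) − 1` planes per gap by default). Inserted planes are
   exact linear blends; x–y samples are untouched.
2. **Smoothing**: separable Gaussian, `smooth_sigma = 1 µm` isotropic in
   physical units (the natural scale is set by the ~4 µm nucleus radius,
   not by the voxel grid).
3. **Thresholding**: a single global Otsu threshold on the smoothed
   stack. Per-slice thresholds would fragment dim planes; a global
   threshold treats the stack as one object.
4. **Distance transform**: an exact anisotropic 3D Euclidean distance
   map in micrometres (two-pass per-axis lower-envelope algorithm,
   compiled).
5. **Marker-controlled watershed** on the negated distance map, seeded
   at distance-map local maxima at least `seed_min_distance = 6 µm`
   apart (≈ one nucleus diameter). Ties are broken by higher distance
   value, then scan order; the flooding queue breaks priority ties
   first-in-first-out — all deterministic.

Region centroids and volumes are reported in physical micrometres with
the voxel-centre convention (position = 0-based index × spacing). Each
region's radius comes from its sphere-equivalent volume,
r = (3V / 4π)^(1/3).

**Oversized-region splitting** (`split_oversized()`): a region whose
volume exceeds `split_factor = 2` times the average region volume is
divided into m = round(V / average) parts (at least 2) by re-running the
watershed inside the region from its m strongest distance-map maxima;
when fewer than m distinct maxima exist the voxels are divided by 1D
k-means on their projection onto the region's principal axis
(deterministic quantile-spaced initial centres). One pass only, and
sub-region voxel counts always sum to the parent's. A consequence of
the 2× trigger worth knowing: a fused pair of *equal-size* nuclei never
exceeds twice the average when its peers are the same size — the rule
catches pairs of above-average nuclei and larger clumps.

**Bead model and classification**: the bead centre is the unweighted
mean of the nucleus centroids (`estimate_bead()`); its radius defaults
to 50 µm — half the 100 µm target diameter measured in the droplet
module — because the stack itself does not image the bead. This
estimator is biased towards invaded cells by roughly
(n_i/n) × mean displacement; with invasion directions distributed around
the sphere the bias largely cancels, and the residual error is small
against the invasion distances of interest. A cell is **invaded** when
its distance from the bead surface, max(0, ‖c − centre‖ − R), exceeds
its own sphere-equivalent radius (`classify_invasion()`). The report
carries n_b (resident), n_i (invaded), d_max (largest surface distance
over invaded cells, 0 when none), and percent invaded
(100·n_i/(n_b+n_i), rounded half-up to an integer for reporting, full
precision retained). d_max is referenced to the bead *surface*, not the
centre — consistent with the invasion rule — and the centre-referenced
distance is also emitted per cell for transparency.

**Group comparison** (`compare_conditions()`): pairwise two-tailed
pooled-variance Student t-tests plus a Tukey–Kramer
honest-significant-difference comparison across all groups (studentized
range, unequal-n correction), with groups summarised as mean ± sd.
Pairs in which both groups have zero variance are flagged and given
p = 1 (identical means) or p = 0. Note that at very small group sizes
the exact permutation distribution of the t statistic deviates from the
Student law by order 1/n — a pooled t p-value and a permutation p-value
on the same 5-vs-5 data legitimately differ by ~0.01–0.04, which is not
a defect of either computation.

## Synthetic data: what it emulates, and what it does not

The generators provide seeded ground truth for every stage
(`simulate_droplet_video()`, `simulate_occupancy()`,
`simulate_confocal_stack()`), with defaults chosen to match the study
conditions: ~100 µm droplets at 3 % CV filmed at 30 fps; λ ≈ 0.3 cell
loading; stacks of ~60–110 nuclei (radius 4 ± 0.3 µm) in a 50 µm-radius
bead with a minority displaced 10–70 µm outward, on a 1 × 1 × 4 µm
voxel grid with anisotropic blur (0.8 µm in x–y, 2 µm in z) and 2 %
Gaussian noise.

Aggregation of cells in suspension is emulated as a compound Poisson:
clusters per droplet ~ Poisson(λ_c), cells per cluster geometric with
parameter `p_agg`; with the mean matched to λ this shifts mass from the
singleton bin into the 3+ bin — the qualitative signature seen when
suspensions clump — without asserting a mechanistic clumping model.

Deliberate simplifications: nuclei are uniform-intensity spheres (the
analysis uses only thresholded geometry), the optical blur is Gaussian
rather than a physical PSF, invasion directions are uniform on the
sphere, droplets are rendered as clean rings with Gaussian pixel noise,
and there is no time-lapse dynamics. Passing tests on this material
therefore demonstrates the *computational* correctness of the pipeline —
detection, association, segmentation and the metric arithmetic — not
robustness to textured chromatin, uneven staining, vignetting, or
deformed droplets.

## Numerical choices and degenerate inputs

* Empty or constant frames, and stacks with empty foreground, return
  empty results rather than errors; zero counted droplets and zero
  regions for bead estimation are explicit errors.
* A single-plane stack cannot be z-interpolated and raises an error
  pointing to 2D analysis, which this pipeline deliberately does not
  cover.
* Reporting percentages round half *up* (`14.5 → 15`), matching the
  integer percentages quoted for the published stacks.
* All simulation entry points take an integer seed and restore the
  caller's RNG state; the same seed reproduces outputs bit for bit.
* The open "3+" bin of pre-binned CSV input is expanded as exactly 3
  cells, which biases a subsequently estimated λ low; the reader warns
  and recommends supplying λ explicitly in that case.

## Problem sizes used by the test suite

The suite checks end-to-end recovery on a 200-droplet video (count
exact, mean diameter within 2 px, dispersity within one percentage
point) and on confocal stacks of 65 and 93 nuclei matching the published
stack scales (total count exact, invaded count within ±1, d_max within
one native voxel diagonal, i.e. √(1²+1²+4²) ≈ 4.2 µm); the acceptance
script additionally runs the largest published scale, 108 nuclei with
44 invaded. These sizes exercise the pipelines at realistic density
while keeping a full run in minutes on one core. At this density,
nuclei whose surfaces nearly touch at the z-resolution limit can
occasionally be oversplit by one region (<1 % of the count) — the same
failure mode the oversized-split rule addresses from the other
direction.

## Known limitations

* Greedy tracking mis-links crossing trajectories (not a droplet-channel
  scenario, but a constraint on reuse).
* The bead is never imaged directly; its centre estimate inherits a
  small invasion-dependent bias, and its radius must come from the
  droplet-sizing module or the user.
* The Hough stage assumes near-circular droplets; deformed or
  overlapping droplets are out of scope.
* Condition labels containing "-" would confuse the Tukey contrast
  parser; use alphanumeric labels.
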