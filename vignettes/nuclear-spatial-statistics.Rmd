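---
title: "Spatial statistics of nuclear object patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial statistics of nuclear object patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nucleospat)
```

## The question the package answers

Telomeres and centromeres appear in 3D fluorescence volumes as dozens of
foci inside a nucleus whose size and shape vary strongly from cell to cell
and across the cell cycle. "Are the foci attracted to the nuclear envelope?",
"are they clustered or regularly spaced?", "are they polarized along one
nuclear axis?" cannot be answered by raw distance histograms, because the
geometry itself biases them: in a sphere, 87.5% of the volume is closer to
the border than to the center, so even uniformly placed objects look
"peripheral". The package's core idea is therefore *conditional* inference:
every observed pattern is compared against patterns simulated **in the same
nucleus**, with the same number and sizes of objects, under an explicit null
model. Heterogeneity of nuclear morphology then cancels by construction.

## Shape representation and geometric conventions

A nucleus is an isotropic binary voxel mask plus a triangular boundary mesh.

* **Coordinates.** Voxel `(i, j, k)` (1-based) is centered at
  `(i − 0.5) · spacing` µm; all pattern coordinates are physical µm. The
  center-of-voxel convention avoids a half-voxel bias in every distance.
* **Surface extraction.** The mesh collects every voxel face separating
  foreground from background, consistently oriented outward, and is therefore
  closed and watertight by construction; its enclosed volume equals the voxel
  volume exactly before smoothing. Two Laplacian passes (each vertex moved to
  the mean of its neighbors) then remove the voxel terracing, which would
  otherwise inflate surface area by up to 50% and depress sphericity. After
  smoothing, a digitized 5 µm ball at 100 nm measures sphericity 0.993 and a
  mesh/voxel volume ratio of 0.999. More smoothing passes shrink volume;
  two are enough to stabilize area without measurable shrinkage at these
  grids.
* **Border distances.** Two interchangeable estimators: exact point-to-
  triangle distance against the mesh (reference), and trilinear interpolation
  of a signed Euclidean distance field computed from the mask (fast path).
  The field is `EDT_in − EDT_out − spacing/2` so its zero level sits on the
  voxel boundary surface; the two methods agree within one voxel on random
  interior points. All Monte-Carlo machinery uses the fast path *for both
  observed and simulated patterns*, so any residual estimator bias cancels
  in the SDI rank.
* **Principal axes.** Eigenvectors of the foreground-voxel coordinate
  covariance, ordered major → minor; each axis's sign is fixed by making its
  largest-magnitude component positive. The polarity index uses
  `max(N⁺, N⁻)` and is provably invariant to that sign choice (tested).

## Distance functions and the Spatial Distribution Index

Five per-nucleus distance samples: B (object→border), C (object→center),
G (nearest neighbor), H (all pairs), F (distance from reference positions to
the nearest object; 1000 uniform interior reference points drawn once per
nucleus and shared across all simulation replicates, so F compares like with
like).

Each sample is reduced to a scalar summary — the sample mean by default,
because it is monotone in the location of the distance CDF. The summary is a
pluggable argument (`summary_fn`) of `compute_sdi()`: the index is a rank
statistic, so any location summary yields an exactly calibrated SDI, and
users can substitute e.g. the median without touching the machinery.

With `n_sims` null summaries (default 99, giving resolution 0.01), the SDI is
the randomized rank `(k + u(t + 1))/(n_sims + 1)` with `k` simulations
strictly below the observed summary, `t` ties and `u ~ Uniform(0, 1)` from the
seeded stream. The randomization makes the SDI *exactly* uniform on [0, 1]
under the null despite the discreteness of ranks — measured: mean 0.487,
KS p = 0.81 over 120 model-drawn patterns. Population-level inference is a
one-sample Kolmogorov–Smirnov test against Uniform(0, 1) at the 5% level,
with R's default p-value — exact below 100 tie-free observations, which keeps
the measured type-I error at ≈ 4.9% for cohorts of 40 nuclei (the asymptotic
approximation would be conservative there, ≈ 4%).

## Null models

* **Completely random.** Objects uniform and independent in the nuclear
  volume, by rejection sampling from the foreground bounding box (acceptance
  ≈ 50% for typical nuclei; a diagnostic error fires below 1%). With
  `hardcore = TRUE`, sequential dart throwing additionally enforces center
  separations of at least the sum of the two equivalent radii and border
  clearance of at least each radius — used for sized objects such as
  centromeres. Per-object radii (not one pooled radius) are used: the
  stricter reading when objects have measured individual sizes. Dart
  throwing caps at 10⁴ attempts per object and reports the violated
  constraint on failure; it samples the conditional "uniform up to
  non-intersection" law faithfully at the low packing fractions involved
  (< 1% here; a feasibility guard refuses packing fractions ≥ 0.3).
* **Orbital.** Each object is resampled uniformly among interior positions
  whose border distance matches its observed value within
  `band_tolerance_um` (default 0.05 µm). Implementation: interior voxels are
  sorted by their distance-field value; a voxel is drawn from the matching
  band, jittered uniformly within the voxel, and accepted if the interpolated
  distance stays within tolerance. The model preserves the B function by
  construction and therefore isolates *non-radial* structure: clustering
  explained purely by a shared peripheral shell disappears under it.

One numerical caveat: when a pattern with *continuous* positions is scored
against the voxel-binned orbital sampler on coarse grids (≥ 150 nm), a small
grid-discretization bias of order a few hundredths of an SDI can appear. The
calibration property is exact when observed patterns are themselves drawn
from the sampler (exchangeability), which is how the package tests it; for
real data at the 100 nm working resolution the effect is negligible.

## Segmentation pipelines

All stages run on isotropic resampled volumes (linear interpolation, 100 nm
default). Defaults, each overridable via `seg_params()`:

| parameter | default | role |
|---|---|---|
| `gaussian_sigma_um` | 0.1 | pre-smoothing of every channel |
| `closing_length_um` | 0.5 | line length of the directional closing (nucleus) |
| `h_minima`, `h_maxima` | 10% of dynamic range | extrema depth for marker detection / peak simplification |
| `echo_fraction` | 0.5 | echo filter proportion |
| `echo_radius_um` | 0.15 lateral × 0.6 axial | echo neighborhood half-extents |
| `threshold_scan` | 64 steps, median → just below max | candidate thresholds for the CV criterion |
| `min_object_voxels` | 5 | discard speckle components |
| `low/high_threshold` | 20% / 60% of range | dual threshold (blob pipeline) |
| `opening_radius_um` | 0.1 | size opening (blob pipeline) |

The **nucleus** pipeline closes small gaps in the lamina signal with line
elements along each axis combined by voxelwise maximum, detects extended
minima at depth `h_minima`, floods a marker watershed, discards regions
touching the image border and keeps the largest remaining region.

The **spot** pipeline suppresses axial reconstruction ghosts first: a voxel
is zeroed when its value falls below `echo_fraction` times the maximum of an
axially elongated box around it — ghosts sit inside the neighborhood of their
(brighter) parent spot, isolated spots are their own maximum. The operation
is idempotent. After h-maxima simplification, the threshold is chosen
automatically by minimizing the coefficient of variation of object size.
Two guards make that criterion robust: the scan spans the median to just
below the image maximum (pure quantile ranges stall in the background
pedestal, because spots occupy well under 1% of voxels), and the CV is
minimized only over thresholds that retain at least 90% of the maximum
object count seen along the scan — without this, a high threshold keeping
two equal-sized peak tips wins with CV = 0. Selection against the nucleus
mask uses geodesic semantics: an object with any voxel inside the mask is
kept whole, never truncated.

The **blob** pipeline binarizes at a low threshold, labels seeds at a high
threshold, and dilates the seeds inside the low mask (multi-source BFS, each
voxel joining its geodesically nearest seed), so touching blobs whose cores
separate at the high threshold remain distinct labels.

Interactive removal of rare false positives is replaced by an explicit
`exclude_labels` parameter, keeping runs reproducible. Connectivity is 26
for component labeling and 6 for reconstruction and flooding fronts; results
are bit-reproducible given a configuration.

## The synthetic-data generators

The generators emulate the study conditions for HeLa nuclei: volumes of
800 µm³ (G1/S-like) to 1300 µm³ (G2-like) digitized as smooth ellipsoids
(elongation ~1.2–1.6, optional smooth radial perturbation), telomere-like
patterns of up to 142 point objects, centromere-like patterns of ~67–84
objects of 0.21–0.27 µm³, and pattern classes with known structure:
peripheral bands, short-range Gaussian clusters, hard-core regularity and
axis polarity. Rendered images place isotropic Gaussian spots at the object
centers plus one axially displaced echo ghost per spot (`echo_gain` of the
spot amplitude; reconstruction echoes are predominantly axial), Gaussian
noise, and a lamina channel as a Gaussian shell on the surface with optional
gaps. A 1 µm clear margin separates the surface from the volume faces, as in
real fields of view. qPCR tables are constructed so the ΔΔCt estimator
recovers the requested folds exactly at zero noise under the 100%
amplification-efficiency assumption.

What the generators deliberately do **not** model: optics (no OTF, no stripe
artifacts beyond the axial echo), chromatin texture, non-star-shaped or
lobulated 3D nuclei, chromatic shift, or clustering of foci into unresolvable
aggregates. Green tests therefore demonstrate that the *statistical
machinery is calibrated and the pipelines recover known ground truth under
realistic geometry and noise* — they do not reproduce the biological values
measured on the deposited microscopy dataset, which would require those
images.

## Numerical choices and degenerate inputs

* Polarity projections of exactly 0 count as positive (deterministic,
  measure-zero in practice).
* The SDI tie count enters the randomized rank, so exact ties (possible in
  contrived integer geometries) do not break uniformity.
* `population_uniformity_test()` requires ≥ 5 SDIs; the cohort pipeline
  marks smaller groups "insufficient n" instead of testing.
* Empty patterns are typed errors for polarity and the distance functions
  that need objects; an empty cohort produces a report with an explicit
  "no nuclei" marker.
* Rejection samplers (interior, band, hard-core, polarized) fail loudly with
  the violated constraint rather than looping forever.
* 2D circularity uses marching squares with linearly interpolated crossings
  on a lightly smoothed copy of the mask; raw midpoint crossings on the
  binary staircase overestimate a digitized disk's perimeter by ~6% and
  would push a perfect disk below the conventional abnormality band.

## Problem sizes used by the test suite

The statistical tests run on cohorts of 40 nuclei with 30 objects each and
99 simulations per SDI; the type-I-error experiment uses 400 replicate
cohorts; power checks use 50 nuclei per arm. Cohort nuclei are drawn from a
reused pool of eight digitized ~800 µm³ nuclei on a 150 nm grid: the SDI is
computed conditionally on each nucleus, so reusing shapes does not affect
calibration, while patterns and simulations are fresh in every replicate.
Segmentation recovery uses a full-scale case: 142 spots with echo ghosts at
40% gain and additive noise in an 800 µm³ nucleus at 125 nm.

## Known limitations

* Nuclei are treated one at a time; no cross-nucleus interactions and no
  mitotic (non-star-shaped) shapes in the generator.
* The orbital sampler is voxel-binned (see the calibration caveat above).
* Ripley-type K/L statistics, pair-correlation functions and parametric
  point-process fits are out of scope; the five distance functions plus two
  null models cover the attraction/repulsion/radial questions addressed
  here.
* ΔΔCt assumes ~100% amplification efficiency; no standard-curve fitting.
* Cell-cycle staging is an input annotation, not inferred from images.
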