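---
title: "Design-based stereology of microglial morphology: models and methods"
author: "stereoglia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-based stereology of microglial morphology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereoglia)
```

## The problem

Microglia react to sensory nerve injury by proliferating and remodelling:
in the deafferented superficial dorsal horn their cell bodies multiply
several-fold, somata hypertrophy, and the branched processes become
shorter and more numerous.  Quantifying this reaction without shape or
orientation assumptions requires design-based stereology: geometric test
probes (planes, cycloid arcs, counting boxes, measurement lines) applied
with randomised position and orientation, whose intersection counts are
converted into densities by closed-form estimators.

`stereoglia` implements the four probe families such a study needs, a
synthetic tissue simulator with exact ground truth to validate them, and
an end-to-end pipeline.  All internal geometry is in micrometres;
densities are converted to mm-based units (mm/mm^3, cells/mm^3) only in
reports.

## Estimators

**Isotropic virtual planes** estimate the length density of curves from
transversal crossings with families of parallel planes of isotropically
random normal, spacing `d` (default 20 um), swept through a sampling box:

$$\hat L_V = \frac{2\,\Sigma Q}{\Sigma a(\mathrm{plane})},$$

where `sum a(plane)` is the total plane area clipped to the box, computed
here analytically by exact plane-box polygon clipping.  A corner-point
form (`p_box = 4` topmost box corners against the reference space) is
provided for boxes that only partially overlap the region.  The key
identity `E[SumQ] = L / (2 d)` for isotropic probes is exercised directly
by the tests.

**Total vertical projections (TVP)** estimate curve length from a thin
sub-stack (default 4 um) projected at `n = 5` evenly spaced angles
(0-144 degrees) about a vertical axis, counting intersections `I_j` of a
cycloid test system with the projected curves:

$$\hat L = 2\,\frac{a}{l}\,\frac{1}{M}\,\frac{1}{n}\sum_j I_j .$$

The cycloid minor axis is *perpendicular* to the vertical axis — the
length-from-projections convention, opposite to the surface-area one.
With that orientation the tangent density of the arcs is proportional to
the cosine of the angle from the vertical, which makes vertical
structures exactly unbiased at every angle and horizontal ones unbiased
after averaging over angles.  The test suite enforces the convention by a
stress test: a 90-degree-rotated grid must *fail* a horizontal test
segment by more than 30%.

Length density follows by dividing by a point-counting reference volume
(`V_ref = hits x area-per-point x depth` on the 0-degree frame).

**The optical disector** counts cell bodies (reference point: the soma
centroid) in 3D boxes under the half-open rule — low faces in, high faces
out — so tiling a volume counts every cell exactly once.  Boxes are
placed by systematic uniform random sampling covering a set area fraction
(10% for length work, 40% for the scarcer cell bodies).  Densities are
corrected for z-axis collapse of the processed sections with the
`SumQ`-weighted measured thickness:

$$\hat N_V = \frac{\Sigma Q^-}{V_{\mathrm{sampled}} \cdot t_{\mathrm{cut}} / \bar t_Q}.$$

The direction of the correction is pinned by a recovery test: with
z-shrinkage 0.5 the uncorrected estimate is twice the truth and the
corrected one recovers it.

**The vertical rotator** estimates soma volume from systematic horizontal
measurement lines of spacing `h` (default 1 um) through a profile,
`V = (pi h / 2) sum(l+^2 + l-^2)` with distances from a vertical axis
through the profile centroid, generalised to multiple boundary intercepts
per line.  Averaged over uniformly random rotations of the profile plane
about the vertical axis it is exactly unbiased for star-shaped bodies;
the package follows the projection workflow (profiles are silhouettes in
three rotated views, 0/72/144 degrees) and reports the small silhouette
overestimate as a diagnostic rather than hiding it (`mode = "section"`
gives the central-section estimate used in the closed-form validation).

**Precision** of systematic samples is predicted by the covariogram CE
with smoothness class `m = 1` by default (the standard choice for count
data; `m = 0` is available — the methodological source leaves the choice
open and per-section counts of the original study are unpublished, so
neither class can be verified against its printed CE values):
`CE^2 = (noise + [3(A - noise) - 4B + C]/240) / (sum f)^2`, with Poisson
noise `sum f`.  A single section degrades gracefully to `1/sqrt(Q)`.

## The simulator

`build_tissue()` generates a rectangular tissue block with:

* soma centres from a homogeneous Poisson process at the regime's
  intensity;
* lognormal soma volumes matched to the regime's mean/SD, mildly
  anisotropic ellipsoids (axis-ratio sdlog 0.12) with uniformly random
  orientation;
* arbors grown by recursive binary branching: primary count from a
  rounded gamma; exponential segment lengths with per-order decay;
  tortuous polylines with von Mises-Fisher step directions
  (concentration 12); radii tapering per branch order down to a 0.1 um
  floor.

Two one-time design choices deserve emphasis:

* **Periodic boundaries.**  Arbor geometry leaving the block wraps to the
  opposite face, so length density is exactly stationary: the block
  ground truth `L_V = (sum of arbor lengths) / volume` holds without any
  edge deficit, and probes placed anywhere in the block are unbiased.
* **Exact length calibration.**  After growth, all arbors are rescaled
  about their somata by one common factor so the realised mean per-cell
  length equals the configured target exactly (a one-step fixed point;
  the published constraints are summary statistics, not mechanisms).
  Between-cell relative variability is preserved; between-block
  variability in mean length is deliberately suppressed.

The two built-in regimes anchor to the published morphometry of mouse
Sp5C microglia.  `control`: 10,311 cells/mm^3, 817 um of process per cell
(the immunofluorescence-level truth), soma 149 +/- 74 um^3, 4.1 primary
processes.  `deaff`: cell density x5 and length density x2.5 of control —
hence 408.5 um per cell — soma 249 +/- 118 um^3, 9.0 primaries.  The
deafferented per-cell length printed for real tissue (279-361 um) is
lower than this generating value because the printed numbers fold in
detection and masking losses; the simulator encodes detection-free truth
and reproduces those losses downstream through its detection models.  An
optional `orient_bias` parameter emulates the superficial-lamina
tendency of processes to run parallel to the dorsal surface (default
off); within-block density is otherwise homogeneous, which is a known
simplification of laminar microgliosis gradients.

Sectioning (`cut_sections()`) clips geometry into 40-um slabs (every
fifth kept when emulating the full histological series), rescales z by a
shrinkage factor, and retains the nominal thickness as metadata.

**Detection models.**  Immunofluorescence (`IF`) detects everything.
The chromogenic model (`DAB`) drops whole segments of mean radius below
0.26 um with probability 0.66.  These two numbers were calibrated once
against the control regime — about 46% of control arbor length lies below
the threshold, so the induced length-detection deficit is about 30%,
matching the reported sensitivity gap between the two labelling
procedures — and then frozen.  In the thicker-processed deafferented
regime the same model loses only ~10% of length, less than the ~26%
reported for real tissue; the radius taper model, not the detection
model, is the limiting approximation there.

**Rendering.**  `render_stack()` rasterises centrelines into calibrated
voxel grids (radius-dependent dilation and intensity), with optional
Gaussian PSF and additive noise; `rotate_and_project()` produces
maximum-intensity projections about the vertical axis (bilinear x-z
interpolation, zero-padded — mass-conservation and projection-geometry
tests bound the interpolation error at 2%); `binarize_and_skeletonize()`
thresholds (Otsu by default, in place of interactive visual
discrimination) and thins to a one-pixel central spine (Zhang-Suen).
Realistic confocal optics — Airy PSF, depth attenuation, photobleaching —
are out of scope; image mode exists to reproduce the *structure* of the
image-analysis workflow (central-spine counting, masking losses), not
microscope physics.

## Randomisation design

Orientation sampling for repeated plane-probe placements uses systematic
uniform random sampling of orientation space: `cos(theta)` stratified
into one band per placement with a common random phase, azimuths on a
golden-angle sequence with a random start.  Each placement is marginally
isotropic (so every estimate is individually unbiased) and jointly they
cover the hemisphere evenly, which collapses the between-placement
orientation variance — the same idea as systematically rotating the
orientation per field of view.  `isotropic_direction()` itself is plain
uniform and is what the distributional tests check.

Cycloid grids and point grids receive fresh uniform phase offsets per
placement; `shift_cycloid_grid()` re-places a grid by translation within
one tiling period (chords are generated with a one-period margin so
coverage is preserved).  Projection angles are fixed at the published
0/36/72/108/144 degrees; with five fixed angles purely horizontal or
purely optical-axis structures carry a residual +1.7%/-3.3%
discretisation remainder that cancels for isotropic material and is well
inside the stated tolerances.  All angles are counted with equal weight;
per-angle counts are reported so masking near 90 degrees can be
inspected.

One master seed fans out to per-stage child seeds (`seed * 1000 + stage`),
making every report bit-reproducible.

## Numerical choices

* Crossing tie-breaks are half-open everywhere: a point exactly on a
  plane belongs to the non-negative side; a vertex on a test line is one
  crossing, not two; disector faces are half-open.  These are
  measure-zero events that nevertheless need a deterministic rule.
* Plane areas come from exact convex polygon clipping, not point
  counting, whenever the box is fully inside the region.
* Cycloid arcs are polygonised with chords of at most `r/5` (geometric
  mode; sagitta error below 0.5% of a crossing count), `0.25` pixel in
  image mode.
* Edge handling: boundary sampling boxes are kept with their in-region
  overlap area (so the realised sampling fraction equals the target and
  `fraction = 1` tiles the region); plane-probe boxes are placed fully
  inside, which is unbiased because simulated blocks are stationary.
* Test-system densities in the validation suite are chosen to collect
  on the order of 100-200 intersections per case, the usual stereological
  counting workload (e.g. `a/l = 5` um for 200-um test segments,
  `d = 20` um for block recovery).

## Problem sizes in the validation suite

The bundled validation works at desk scale, chosen so the whole suite
runs in minutes on one CPU: recovery blocks of (100 um)^3 with ~5,000 um
of curve, 200 probe placements; 300-400 cycloid placements on 200-um test
segments; four replicate soma-only blocks (up to 1.2 mm side) per
disector intensity; a 3+3-side experiment on 260 x 260 x 160 um blocks.
Monte-Carlo tolerances (3-5%) correspond to 2-3 standard errors at these
sizes.  Passing them demonstrates estimator correctness on the simulator's
assumptions — homogeneous Poisson somata, branching-tree arbors, simple
detection dropout — not performance on real image stacks, where
segmentation error, uneven staining and true anatomical gradients add
variance the simulator does not model.

## Reference worked example

`mg_reference_values()` packages the published group means (length
density, cell density, length per cell by group/stain/side) together with
soma-volume and single-cell-reconstruction summaries;
`derived_percentages()` re-derives the nine summary percentages from
them, with the pooling fixed to the arithmetic that reproduces each
printed integer: side ratios within the nerve-transected group for the
x4.45/x5.55 cell-density and 53%/45% per-cell-length changes; the mean of
the two per-stain side ratios for the ~250% length-density change;
between-stain differences on pooled control sides relative to the larger
mean (3% and 30%); the reconstruction-vs-stereology deficit relative to
the pooled control immunofluorescence estimate (27%); and the soma excess
relative to control (67%).  Percentages are rounded half away from zero.
The deafferented-side between-stain differences are *not* derivable from
any pooling of the published group means (they come from per-animal
paired values that were never published); `reference_check()` flags them
instead of guessing.  Likewise, the printed per-cell lengths are means of
per-animal ratios, so no consistency between the printed columns is
asserted — the `L_N = L_V / N_V` identity is enforced only on rows this
package computes itself.

## Known limitations

* Masking in dense projections is reproduced, reported per angle, and
  bounded by tests, but not corrected analytically — the estimator
  inherits the method's accepted underestimation in heavy microgliosis.
* The silhouette-based rotator overestimates elongated somata; the
  central-section mode quantifies this but real projections cannot be
  converted.
* The simulator's radius taper is deterministic per branch order, which
  compresses the radius distribution relative to real arbors and limits
  how faithfully the chromogenic detection gap can depend on regime.
* Sampling-box dimensions and disector heights of the original study are
  not published; defaults here (60 x 60 x 12 um boxes, `d = 20` um,
  disector height = measured thickness minus 2-um guards) are explicit
  configuration, not reconstructions.
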