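---
title: "Distance deviation: model, conventions, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance deviation: model, conventions, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contourdev)
```

## The measurement model

Contouring variability is measured from the perspective of every voxel of
the image on which the contours were drawn. Each structure — a set of
closed polygons per slice — is converted into a signed Euclidean distance
image `D`: the value at a voxel is the distance in mm from the voxel
*centre* to the nearest point on the structure's contour, negative inside
the structure and positive outside. The deviation of those distances across
the compared contours is then a per-voxel statistic:

* `dd_pair()`: `|D_1 - D_2|` for two contours;
* `dd_vs_reference()`: the RMS of `D_i - D_R` over the N analysed contours
  when a reference delineation exists;
* `dd_std()`: the standard deviation of the `D_i` around their mean
  distance image `mean_distance_image()` when it does not. The average
  contour itself is never constructed — only its distance image is needed,
  and that is the voxelwise mean of the individual distance images.

Because every voxel observes all contours symmetrically, any difference
between contours is detected regardless of shape complexity (lobes,
multiple segments, interior holes), and results are absolute, in mm.
Both RMS and SD divide by N, matching the defining formulas; the
`sample = TRUE` argument exposes the N−1 variant but is off by default.
With N = 1 the RMS reduces to the pairwise deviation and is computed by the
same `abs()` expression so the identity holds bit-exactly.

Two scalar estimates compress a deviation image:

* `DD_max`, the maximum over the *region of contour disagreement* `ΔI`
  (voxels covered by at least one but not all of the M delineations,
  reference included). Deviations outside the union of all delineations,
  or inside their common intersection, cannot exceed the maximum over
  `ΔI` — for the voxel-lattice construction used here this follows from
  the triangle inequality applied to the nearest contour voxel — so
  restricting the search loses nothing and is cheaper. For M = 2,
  `DD_max` is the symmetric Hausdorff distance of the two contours (up to
  lattice resolution; the suite checks agreement with a brute-force
  Hausdorff oracle to within one voxel diagonal).
* `DD_mean`, the mean over the union region `Î`, balancing regions of
  large disagreement against stretches of good agreement.

`DD_mean` is *not* a metric: it can violate the triangle inequality
because the averaging domain differs per pair. The suite contains a
concrete three-structure fixture, found by randomized search, where
`DD_mean(A, C) > DD_mean(A, B) + DD_mean(B, C)` — mean deviations must
therefore never be compared indirectly through an intermediate contour.

## Rasterization and distance computation

**Membership rule.** A voxel belongs to a structure when its centre is
inside the slice's polygons under the even-odd rule, applied jointly to all
polygons of the slice; a centre lying exactly on an edge (within 1e-7 mm)
counts as inside. The even-odd rule makes winding order irrelevant and
gives interior holes ("void interior") for free: an inner polygon simply
toggles membership off. The boundary-inside tie-break is a deterministic
convention of this package; no sub-voxel or anti-aliased rasterization is
attempted.

**Exact path.** `signed_distance_exact()` computes, per voxel, the minimum
point-to-segment distance over all polygon edges of the slice, signed by
the membership test. It is exact up to floating point and is the oracle
against which the fast path is validated, as well as the default choice
for small grids and for analytic test cases.

**Fast path.** `signed_distance_fast()` composes two Euclidean distance
transforms of the rasterized mask, `D = EDT(to foreground) - EDT(to
background)`, each measuring centre-to-centre distances in physical mm
(the separable lower-envelope transform in `src/edt.cpp` handles
anisotropic spacing exactly, e.g. 0.625 × 0.625 × 3.9 mm MR grids). The
zero crossing therefore sits between boundary voxels rather than on the
contour, which is why the contract with the exact path is agreement within
one in-plane voxel diagonal, not equality. The suite sweeps 20 randomized
star/ellipse/annulus shapes to enforce that bound.

**2D vs 3D.** The default mode `slice2d` transforms each slice
independently, preserving the 2D nature of drawn contours; `volume3d`
runs one anisotropic 3D transform over the stacked mask for studies of the
delineated volume as a 3D object.

**Slice restriction.** In `slice2d` mode a distance is undefined on slices
without contours; those slices are stored as `NA` and every downstream
statistic is restricted to `valid_slices` — the slices contoured by *all*
compared structures. This also resolves an ambiguity in the union-region
average: a slice contoured by only some observers contributes neither to
`Î` nor to `ΔI` here, since mixing contoured with uncontoured slices would
compare distances against an undefined quantity. This is a deliberate
deviation from a literal all-slices reading of the union sum.

**Caps.** Distances are capped at the grid's physical diagonal so no
infinities propagate; the cap only affects voxels far from any contour,
where deviations are constant anyway.

**Refinement.** `refine_grid(grid, factor)` subdivides in-plane voxels
when higher accuracy is wanted; there is no prescribed default beyond
factor 1, and the refinement keeps the physical extent and slice positions
unchanged.

## Angular representation

`angular_profile()` collapses one slice of a deviation image into bins over
(−180°, 180°], default 1° (360 bins). For each bin a ray is cast from the
contour centre; the field `DD · 1[ΔI]` — the deviation zeroed outside the
disagreement region, following the defining max expression — is sampled
along the ray at radial steps of half the minimum in-plane spacing, with
bilinear interpolation for the deviation values and nearest-neighbour
lookup for region membership (interpolating a binary mask would invent
fractional membership). The bin value is the maximum over samples inside
`ΔI`; bins whose ray never meets the region are *missing* (`NA`), which is
rendered white and is distinct from a measured 0 mm. Zeroing outside the
region before interpolation guarantees that values outside `ΔI` can never
influence a profile; the price is a slight downward blend within one voxel
of the region edge, covered by the raster tolerance in all assertions.

Angle 0° points to the image top (anterior on a standard axial view),
−90° to the image right, +90° to the left, ±180° posterior. The centre
defaults to the per-slice centroid of the reference mask (union mask if no
reference) and can be overridden globally, e.g. with an applicator axis.
The centre choice strongly influences angular results — for eccentric
shapes a ray may cross the disagreement region far from the anatomy the
angle suggests, blurring (but not exaggerating) the spatial attribution —
so the centre used is always recorded in the profile and in the run
manifest. When a ray exits and re-enters the region, the maximum over all
its region samples is kept.

## Rendering

Overlays use HSV: the medical image keeps its grayscale appearance as the
value channel (per-volume robust 1st–99th percentile window, recorded in
the manifest; a flat image maps to mid-gray), and deviation is coded as
hue, 240° (blue, 0 mm) falling linearly to 0° (red) at the cap, default
5 mm, traversing cyan/green/yellow; saturation is fixed at 0.8. Deviations
above the cap get a distinct dark purple, and voxels with undefined
deviation stay pure grayscale. The hue endpoints, path and chroma are this
package's declared defaults — only blue-for-agreement / red-for-
disagreement and the 5 mm cap are inherited conventions. The angular
heatmap uses the same ramp at full value, with missing cells white.

## Synthetic generators and what tests show

`make_fixture()` produces the geometric regimes the measure must handle:
circles and ellipses (smooth, convex), stars (pronounced extremes), annuli
(void interior), congruent offset pairs (pure translation, known Hausdorff
distance), and perturbed families — one reference circle plus N observer
circles of radius `r + eps_i`, `eps_i ~ Normal(0, sigma)` drawn once per
contour. The constant-radial-offset model makes the deviation field
analytically flat (`DD_S` equals the population SD of the offsets
everywhere), anchoring the recovery tests; a `per_vertex` option adds
smooth low-order Fourier deformations for more realistic, non-flat cases.
Default conditions for the multi-observer studies are radius 20 mm,
sigma 1.5 mm, N = 20 observers, 720 vertices per contour, on a
1 × 1 × 3 mm grid with an 8 mm margin — a scale comparable to pelvic
structures on MR while keeping a test run in seconds. All randomness flows
from the spec's explicit seed through a private RNG stream.

These generators emulate observer spread in contour position and smooth
shape deformation. They do not emulate intensity-driven behaviour (real
observers disagree most where edges are ambiguous), inter-slice
correlation of errors, or anatomically shaped structures — so passing
tests demonstrate the correctness of the *measure*, not claims about any
clinical population.

Problem sizes in the suite and acceptance script were chosen to exercise
every code path at sub-minute runtimes: grids of 31–61 voxels per side,
20-fixture randomized sweeps, N = 20 observer families, and 360-bin
profiles.

## Numerical conventions, in one place

* Coordinates are physical mm; voxel index (0,0,0) maps to the grid
  origin, which is that voxel's centre. Slice keys are 0-based.
* Polygons are implicitly closed; a duplicated closing vertex is dropped
  on read; polygons need ≥ 3 vertices and nonzero area.
* Contour files store coordinates with 17 significant digits, so
  write/read round-trips reproduce vertices bit-exactly.
* Empty `ΔI` (perfect agreement) gives `DD_max = 0`; an empty union
  region on the valid slices is an error.
* `dd_pair` is bit-exactly symmetric; `dd_std` is invariant to input
  order; `dd_std` of two images equals `dd_pair / 2` voxelwise (population
  SD of two values is half their absolute difference).
* The zero-noise limit of every stochastic generator yields zero deviation
  end-to-end, up to last-ulp rounding introduced by the mean image in the
  reference-free analysis.
* Pipeline runs are byte-reproducible: uncompressed NIfTI volumes, CSV and
  JSON artifacts with no timestamps.

## Known limitations

* Deviations are evaluated at voxel centres only; the lattice is dense
  enough to detect any contour difference, but reported extrema carry a
  raster tolerance of about one voxel diagonal (reducible via
  `refine_grid`).
* `DD_mean` is not a metric (see above) and a low value does not exclude
  large local errors; `DD_max` warns about local discrepancies but says
  nothing about overall agreement. They are complementary and reported
  together.
* Angular profiles discard the radial location of each maximum and depend
  on the centre choice; they are a compact summary, not a replacement for
  the deviation image.
* The package reads its own JSON contour format only; DICOM RT-STRUCT
  parsing, contour smoothing/resampling, and dose- or anatomy-weighted
  deviations are out of scope.
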