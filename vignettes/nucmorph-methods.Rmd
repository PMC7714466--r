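---
title: "Methods: 3D nuclear morphometry in nucmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D nuclear morphometry in nucmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

nucmorph quantifies nuclear morphology and intranuclear organization from 3D
wide-field fluorescence stacks of DNA-stained tissue. This vignette explains
the models and algorithms behind each stage, the parameters that matter, the
numerical choices taken where the design was genuinely open, and what the
synthetic-data validation does and does not demonstrate.

## The pipeline

A wide-field stack contains tens of nuclei at different depths and with
different staining intensities. The pipeline decomposes the analysis into

1. **autocrop** — detect every nucleus-sized object and cut a padded 3D box
   around it, so that later per-nucleus segmentation can adapt to local
   intensity;
2. **segmentation** — delineate the single nucleus inside each crop, by two
   complementary methods;
3. **surface geometry and morphometrics** — volume, surface area (two
   estimators), flatness, elongation, sphericity;
4. **nuclear domains** — chromocenters in the DNA channel and FISH signals
   in probe channels, with distances to the nuclear envelope (NE).

## Autocrop

The full stack is binarized at the Otsu threshold of a 256-bin histogram
spanning the stack's intensity range (the rescaling makes thresholds
comparable across bit depths). Connected components are labelled in 3D with
26-connectivity — the standard choice for blob detection, and the reading we
adopt where the original description is silent. Components are kept when
their physical volume exceeds `min_volume_um3` (default 1 µm³); we read the
published "above 1 µm" size filter as a volume because it is applied to
computed component volumes. This filter removes debris and autofluorescent
organelles such as chloroplasts.

Each retained component's tight bounding box is expanded by
`padding_voxels` (default 20) on every side and clamped to the stack. Boxes
are optionally merged to a fixed point whenever the shared voxel volume
reaches `merge_fraction` (default 0.5) of the smaller box; we interpret the
"50% shared surface" grouping rule volumetrically, the natural 3D reading.
Box coordinates are serialized 0-based with inclusive extents (XStart,
YStart, ZStart, width, height, depth), and the same coordinate table can be
re-applied to other wavelength channels so that FISH probe crops align
voxel-for-voxel with the DNA crops. An inverted maximum-intensity
Z-projection with numbered box outlines supports visual curation.

## Modified-Otsu segmentation

A single global threshold is rarely right for every nucleus, so each crop is
re-thresholded locally: candidate thresholds scan a window of ±20 grey bins
(of 256) around the crop's plain Otsu value. For each candidate the largest
26-connected component is kept and interior holes are filled, slice-wise in
2D and then in 3D — unstained nucleoli otherwise leave cavities. Candidates
whose volume falls outside the plausible bounds
(`seg_min_volume_um3` = 0.5, `seg_max_volume_um3` = 2000, both
configurable) are discarded, and among the survivors the mask with the
highest sphericity \(36\pi V^2 / S^3\) wins. Sphericity scoring encodes the
prior that a nucleus is compact; it is what makes the method "modified"
rather than plain Otsu. The volume bounds target calibrated plant nuclei;
analyses of other objects (for instance unit-voxel digitized test spheres)
should widen them.

A crop is classified **bad crop** when no threshold yields a plausible
component, or when the winning mask touches two opposing crop faces — the
object is then truncated by the field of view. Each crop therefore ends in
exactly one of the `otsu/`, `gift/` or `bad_crop/` output folders.

## 3D gift-wrapping

The second method is an edge-based closure of the modified-Otsu mask. We
wrap the existing binary mask rather than the raw intensities: it reproduces
all the documented behaviours (superset volume, hole repair) while keeping
the operator a pure, testable geometric transform.

The object is cut into 2D slices along all three orientations (XY, XZ, YZ).
In each slice a gift-wrapping (Jarvis-march) walk traverses the boundary
pixels of each 8-connected component: from the current vertex the walk moves
to the candidate within physical distance `td` that makes the sharpest
available outward turn, skipping candidates whose edge would cross the
existing chain. Where the convex-hull jump is longer than `td`, the most
extreme reachable point lies on the object boundary, so the walk descends
into the concavity and follows it. The filled walk polygon (pixel centres
inside the polygon) is united with the input slice. Consequences, which the
test suite checks directly:

* the output contains the input (growth-only) and stays inside the filled
  convex hull of the input's pixel centres;
* concavities with mouth narrower than `td` are bridged, wider ones are
  preserved;
* with `td = ∞` the walk degenerates to the exact convex hull (verified
  against a brute-force all-pairs-edge oracle).

The threshold distance is `td = r_eq / 2`, half the radius of the sphere
with the object's volume — measured in physical units and converted
per-orientation with the in-plane calibration, since XZ and YZ slices are
anisotropic. The three reconstructions are united (union, not intersection),
the largest component kept, residual cavities filled. A wrapped mask that
touches two opposing crop faces is classified bad crop.

Two design notes. First, the walk rasterizes polygons by the
centre-in-polygon rule. This keeps the wrap exactly idempotent on convex
objects and exactly bounded by the convex hull of the voxel centres, at the
price that a perfectly convex digitized sphere is returned unchanged —
reference implementations that rasterize polygon edges inclusively dilate
convex objects slightly instead; the two behaviours cannot be combined, and
we chose the invariant-preserving one. Second, the walk is run per
8-connected component, which guarantees termination and leaves disjoint
islands (possible in extreme slices of a 3D object) untouched; the
three-orientation union then reconnects them in 3D.

## Surface area

Two estimators are computed for every nucleus.

**Exposed-face (initial) estimator.** The sum of the physical areas of all
voxel faces adjacent to background. It is simple and monotone but
systematically over-counts curved surfaces: for a digitized ball the
exposed-face area tends to 1.5× the true sphere area (the L1 projection of
the normal), and small radii are worse. Over spheres of radii 5–50 voxels
the mean observed/theoretical ratio is about 1.51.

**Gradient/surfel (new) estimator.** Every exposed face (surfel) contributes
its area multiplied by the inner product of the local outward unit normal
with the face direction, clamped at zero. The normal field is estimated
from central finite differences of the image \(f\), scaled by the
anisotropic voxel calibration — the raw crop when available, the binary
mask for binary objects. If the local patch normal is accurate this
projection removes the staircase over-count exactly (on a 45° ramp each
stepped face contributes \(1/\sqrt 2\) of its area, on a flat slab the full
area). Where the gradient vanishes (isolated voxels), the surfel falls back
to the full face contribution.

`estimate_normals()` additionally offers iterated on-surface smoothing of
the gradient field (averaging over 26-adjacent boundary voxels, default 2
passes), which brings every digitized-sphere boundary normal within a few
degrees of the true radial direction. The **area** path, however, uses the
unsmoothed gradient by default (`surfel_iterations = 0`). The reason is a
deliberate calibration choice: with well-smoothed normals the clamped
projection is essentially unbiased and lands a ratio slightly *below* 1 on
digitized spheres (the digitized ball is marginally smaller than the
continuous ball), whereas the estimator's reference behaviour — a stable
mean ratio a few percent *above* 1 across radii 5–50 — arises precisely
from the quantization of raw finite-difference normals interacting with the
clamp. Smoothing the normals would "improve" each normal and move the area
estimate away from the published operating point, so smoothing stays a knob
(`surfel_iterations`) with default 0 on the area path and default 2 on the
normal-field API, whose own accuracy contract it serves.

Per-surfel contributions are clamped at zero to guard against
inward-flipped normals on noisy data; since each contribution is scaled by
a factor ≤ 1, the surfel area never exceeds the exposed-face area.

## Morphometrics

Volume is the voxel count times the physical voxel volume. Flatness and
elongation follow the equivalent-ellipsoid convention: with eigenvalues
\(\lambda_1 \ge \lambda_2 \ge \lambda_3\) of the covariance of the
calibrated foreground voxel coordinates, elongation is
\(\sqrt{\lambda_1/\lambda_2}\) and flatness \(\sqrt{\lambda_2/\lambda_3}\);
both equal 1 for a sphere and are invariant to scale and axis-aligned
rotation. Sphericity is \(36\pi V^2/S^3\) with \(S\) the surfel surface
area (the corrected estimator); the exposed-face variant is reported
alongside for comparison. Masks with fewer than four non-coplanar voxels
are flagged as degenerate rather than silently measured.

## Nuclear domains

Chromocenters and FISH signals are segmented inside a given nucleus mask by
a seeded 3D watershed with a documented, reproducible contrast rule in
place of an interactive threshold:

1. A two-pass nucleoplasm estimate: the mean intensity over the mask is
   computed, voxels above `contrast ×` that mean are provisionally removed,
   and the mean is recomputed over the remainder — so bright domains do not
   inflate their own reference level. The super-threshold region is all
   mask voxels above `contrast ×` the refined mean (defaults: 1.5 for
   chromocenters, 2.0 for FISH channels).
2. Seeds are the regional 26-connected intensity maxima inside that region,
   after a light Gaussian smoothing (1 xy-voxel, z scaled by the
   calibration ratio). Note that taking whole super-threshold components as
   seeds could never split two fused domains; maxima can.
3. A priority-flood watershed (brightest voxel first) grows the seeds over
   the region; every seed voxel keeps its label and the labels partition the
   region.
4. Shallow adjacent basins merge when their saddle lies within `merge_h`
   (default 0.15) of the lower peak, relative to that peak's height above
   the threshold — this absorbs maxima created by residual noise while
   preserving genuine two-peak dumbbells, which split at the neck.
5. Domains smaller than `domain_min_volume_um3` (default 0.02 µm³, ≈ 10
   voxels at the default calibration) are discarded.

Distances to the nuclear envelope use an exact anisotropic Euclidean
distance transform of the mask interior (physical units; voxels outside the
array count as background one spacing step beyond the border). Per domain,
the border distance is the minimum over its voxels and the barycenter
distance is the transform at the voxel nearest its volume barycenter; the
border distance can therefore never exceed the barycenter distance. The
per-nucleus summary reports the domain count, mean and total domain volume,
and the mean border and barycenter distances.

## The synthetic-data generator

All validation inputs are generated in code; nothing is downloaded.

* **Digitized spheres** (radii 5–50 voxels) are strict ball rasterizations:
  a voxel belongs to the sphere when its centre is within the radius. The
  rasterization rule is a choice (the alternative — any voxel whose cell
  intersects the ball — inflates the volume of an r = 20 sphere by ~8%,
  violating the volume-convergence property we require of the fixtures).
* **Bead fields** emulate fluorescent calibration microspheres of 1–4 µm:
  homogeneous spheres on the anisotropic grid, lightly blurred, placed
  without contact, with the theoretical volume recorded in the metadata.
* **Nucleus fields** place ellipsoidal nuclei (radius 1.2–2 µm by default,
  configurable axis ratios and random orientation) on a jittered grid or at
  random with bounded retries, each with its own intensity scale (±20%) to
  emulate staining variability. Chromocenters are bright isotropic blobs at
  3× the nucleoplasm level; the nucleolus is an intensity well at 0.2× the
  nucleoplasm level — not zero, matching the residual signal of unstained
  nucleoli. Anisotropic Gaussian blur (σ = 0.1, 0.1, 0.3 µm — a wide-field
  PSF stand-in at 0.103/0.103/0.2 µm voxels) and additive Gaussian noise
  (5% of the nucleoplasm level) finish the image. All randomness flows from
  one seed; identical parameters and seed give bit-identical stacks.

The tangent-nucleolus fixture deserves a note. The artifact of interest is
a border indentation where an unstained nucleolus meets the envelope.
Exact internal tangency produces a zero-width mouth that the PSF seals and
hole-filling then removes, so the tangent placement carries a small
envelope overlap (5% of the nucleolus radius) giving the indentation an
open mouth. Likewise the indentation is only laterally resolvable: with
0.2 µm z-sampling and 0.3 µm axial blur an axially tangent nucleolus is
smeared into the envelope, so artifact fixtures constrain the tangency
direction to the imaging plane — which is also where such artifacts are
observed and curated in practice.

What passing on these fixtures does **not** show: the generator has no
optical aberrations, no depth-dependent attenuation, no structured
background (cytoplasmic autofluorescence, neighbouring tissue), and its
PSF is a separable Gaussian. Real acquisitions will be harder; the
synthetic results bound the algorithmic, not the photographic, error.

## Numerical choices and degenerate inputs

* Otsu threshold: 256 bins over the observed range; binarization is
  `value > threshold`; a constant image raises a typed single-class
  condition which the batch pipeline converts to "zero crops, warning".
* The hull walk caps its steps at 8× the number of boundary points; a walk
  that fails to close leaves the slice unchanged (growth-only is never
  violated). Collinear candidates are tied by nearest-first, which makes
  the walk follow boundaries pixel by pixel; an exact backtrack is ranked
  last so collinear chains cannot close the polygon prematurely.
* The distance transform is the exact two-pass parabolic-envelope
  algorithm per axis with physical sample spacings.
* Watershed ties (equal intensity) are broken first-in-first-out on a
  stable queue, so label maps are deterministic.
* Degenerate masks: empty masks measure zero area and volume; masks with
  fewer than 4 voxels or coplanar voxels raise a degeneracy error in the
  ellipsoid fit; isolated voxels fall back to full per-face surfel
  contributions.

## Problem sizes used in validation

The shipped validation suite runs on: six digitized spheres (radii 5–50),
fields of 9–10 nuclei in 256–300² × 44–48-voxel stacks (50 nuclei for the
parameter-recovery and hull-property studies), ten single-nucleus
tangent-nucleolus fixtures, and twelve chromocenter fixtures. These sizes
exercise every code path at full fidelity while keeping the whole suite in
the minutes range on one CPU; the pipeline itself is routinely applicable
to full-size acquisitions (tens of stacks, hundreds of nuclei) since every
stage is linear or near-linear in voxel count.

## Known limitations

* The gift-wrap slice walk bridges concavities per-slice; a concavity
  aligned exactly with all three slicing orientations (a rare axis-aligned
  wedge) can be under-filled relative to a true 3D closure.
* The watershed contrast rule assumes domains are brighter than the
  nucleoplasm by a roughly uniform factor; strongly vignetted crops would
  need per-region contrast.
* Multi-channel input is one TIFF per channel; ImageJ hyperstack dialects
  are not parsed.
* The surfel estimator's operating point is calibrated on digitized
  spheres; on strongly prolate objects with few voxels the residual bias
  can be larger than the sphere figure suggests.
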