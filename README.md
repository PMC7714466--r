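# nucmorph

3D nuclear morphometry from wide-field fluorescence stacks, in R.

A single wide-field acquisition of DNA-stained tissue contains tens of
nuclei at different depths, sizes and staining intensities. Quantifying
nuclear morphology (volume, surface area, flatness, elongation) and
intranuclear organization (chromocenters, FISH signals, their distances to
the nuclear envelope) at scale requires automating three tedious steps:
finding each nucleus, segmenting it despite local intensity variation and
unstained nucleoli, and measuring it with estimators that do not inflate
with voxelization. nucmorph is a scriptable implementation of that whole
workflow for plant (and other) nuclei, aimed at microscopists building
large curated datasets.

## What it computes

* **Autocrop** — Otsu binarization of the whole stack, 26-connected
  components, a volume filter (default > 1 µm³), one padded bounding box
  per object (default 20 voxels), optional merging of boxes sharing ≥ 50%
  volume, per-object TIFF crops, a coordinate table, and a numbered
  inverted Z-projection. The same table re-crops other wavelength channels
  voxel-identically.
* **Two segmentation methods per crop** — a *modified Otsu* (sphericity-
  maximizing threshold scan with hole filling) and a *3D gift-wrapping*
  closure: a slice-wise Jarvis march in XY, XZ and YZ whose hull edges are
  limited to a threshold distance *td* = r_eq/2 (half the equivalent-sphere
  radius), so nucleolus indentations narrower than *td* are bridged while
  true shape is preserved; the three orientations are united. Unsegmentable
  or truncated crops are classified *bad crop* — every crop ends in exactly
  one of `otsu/`, `gift/`, `bad_crop/`.
* **Surface area, two ways** — the classical exposed-voxel-face sum, which
  overestimates curved surfaces (≈ 1.5× on digitized spheres), and a
  discrete-geometry *surfel* estimator: each exposed face contributes its
  area projected onto the local outward normal estimated from the
  anisotropic image gradient, S = Σ A_s · max(0, n̂·ê_s). On digitized
  spheres of radii 5–50 voxels the mean observed/theoretical ratio drops
  from ≈ 1.51 (exposed-face) to ≈ 1.05 (surfel).
* **Shape metrics** — volume, both areas, equivalent radius, flatness
  √(λ₂/λ₃) and elongation √(λ₁/λ₂) from the covariance eigenvalues of the
  calibrated voxel coordinates, sphericity 36πV²/S³.
* **Nuclear domains** — seeded 3D watershed with a reproducible two-pass
  contrast rule (chromocenters: 1.5× nucleoplasm; FISH: 2×), plus an exact
  anisotropic Euclidean distance transform for border-to-envelope and
  barycenter-to-envelope distances.
* **Synthetic ground truth** — digitized spheres, bead fields, and
  multi-nucleus stacks with chromocenters, tangent dark nucleoli,
  anisotropic blur and noise, all seeded and bit-reproducible.

## Worked example

```r
library(nucmorph)

field <- make_synthetic_field(n_nuclei = 9, n_chromocenters = 3, seed = 42)
ac <- autocrop_stack(field$stack, nucmorph_config(), file_name = "field9.tif")
head(ac$table, 3)
#>     FileName id XStart YStart ZStart width height depth
#> 1 field9.tif  0     88     88      0    72     72    45
#> 2 field9.tif  1    187     92      0    69     73    46
#> 3 field9.tif  2    197      0      0    59     66    44

crop <- ac$crops[[1]]
otsu <- modified_otsu_segment(crop, crop_id = 0)
gift <- gift_wrap_segment(crop, otsu)
compile_metrics(list(otsu, gift), list(crop, crop))
#>   method volume_um3 surface_area_initial_um2 surface_area_new_um2 flatness elongation sphericity
#> 1   otsu       19.4                     55.0                 34.8        1       1.02       1.01
#> 2   gift       19.6                     53.6                 34.5        1       1.02       1.06

dom <- envelope_distances(watershed_domains(crop, gift), gift)
domain_summary(dom)
#>        channel n_domains volume_mean_um3 volume_total_um3 d_border_ne_um d_barycenter_ne_um
#> 1 chromocenter         3           0.307            0.921          0.641               1.05
```

Nine boxes are found for the nine planted nuclei. For box 0 the two
segmentations agree to 1% in volume (the wrap grows the object slightly, by
construction); the exposed-face area (55 µm²) exceeds the surfel area
(35 µm²) — the staircase over-count the surfel projection removes — and the
three planted chromocenters are recovered with their volumes and envelope
distances.

The same workflow runs from a shell via the thin CLI in `inst/cli`:

```sh
nucmorph autocrop stacks/ --out run1
nucmorph segment run1/crops --out run1/seg
nucmorph domains run1/crops --masks run1/seg/gift --out run1/dom
nucmorph fixtures --out demo --seed 1
```

Parameters (calibration, padding, volume filters, threshold window, domain
contrasts, ...) live in `nucmorph_config()` and flat `key=value` config
files; see the methods vignette (`vignettes/nucmorph-methods.Rmd`) for what
each parameter means and why the defaults are what they are.

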