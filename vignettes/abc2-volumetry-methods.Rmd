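---
title: "ABC/2 volumetry for epidural hematoma: model, measurement and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ABC/2 volumetry for epidural hematoma: model, measurement and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edhvol)
```

## The problem

Traumatic epidural hematoma (tEDH) volume guides treatment: evacuation is
recommended above roughly 30 mL, and volume correlates with outcome. The
reference measurement, planimetry, requires slice-by-slice segmentation;
the bedside alternative is the ABC/2 family of estimators, which treats
the lesion as an ellipsoid. An ellipsoid with axis lengths A, B, C has
volume π/6·ABC ≈ ABC/2, hence the classic formula: half the product of
the maximum in-plane length (A), the maximum width perpendicular to it
(B), and the cranio-caudal depth (C).

Several variations of ABC/2 coexist in clinical use. They differ in two
choices:

* **Representative slice** for A and B — the slice with the largest
  lesion area (A1, B1) or the central hematoma-bearing slice (A2, B2).
* **Depth** — the unadjusted count of hematoma-bearing slices times the
  slice thickness (C0), or the slice-weighted adjusted depth (C1).

Crossing the two choices gives four traditional variations
(coefficient 0.5, no intercept). Regressing planimetry on each of the
four A·B·C products gives four calibrated variations with fitted slope
and intercept. `variation_registry()` holds all eight.

This package implements the measurement chain on binary segmentation
masks, the estimator family, the regression calibration, and the
accuracy evaluation, and validates the chain on synthetic phantoms with
analytically known volumes.

## Per-slice measurement

A slice is a binary mask with in-plane pixel spacing (mm). The
measurement algorithm works on the lesion's contour:

1. **Contour** — foreground pixels with at least one background
   8-neighbour (grid edges count as background), ordered along the
   outer boundary by Moore-neighbour tracing. When a slice carries
   several 8-connected components, only the largest is measured and a
   warning is raised (a detached island is treated as segmentation
   noise; the study population excluded concurrent adjacent lesions).
2. **Maximum length A** — the largest pairwise distance between contour
   pixel centers, in physical mm. The farthest pair of a planar point
   set lies on its convex hull, so the default path runs the exact
   brute-force distance computation on the hull vertices only; the full
   brute-force path is retained and tested to be bit-identical.
3. **Maximum perpendicular width B** — for every contour pixel, the
   full line through it perpendicular to the length axis is intersected
   with the closed polygon through the ordered boundary pixels; the
   farthest intersection from the pixel gives that pixel's chord, and B
   is the maximum over pixels. On concave outlines the farthest of
   multiple crossings is used, which maximises the chord.
4. **Area** — foreground pixel count × pixel area.

Numerical choices worth knowing:

* Distances are between **pixel centers in physical mm**; anisotropic
  in-plane spacing is supported. (Whether the original implementation
  used pixel units when pixels were anisotropic is not documented; CT
  pixels are near-isotropic, so the difference is small either way.)
* Exact ties for the maximum length return the lexicographically
  smallest endpoint pair, making outputs deterministic.
* The chord polygon used for the width is the raw traced boundary. The
  handful of "inner corner" pixels whose only background contact is
  diagonal belong to the contour *set* (and serve as anchors) but are
  not spliced into the polygon: the traced curve is identical under
  grid rotations and flips, which keeps the width measurement exactly
  rotation-invariant. One pixel diagonal remains the natural tolerance
  when comparing against analytic shapes.
* A single-pixel lesion has positive area but zero lengths; an empty
  slice yields a lesion-free record.
* 8-connectivity is used for components and boundary tracing (the
  original tool's connectivity is undocumented; 8-connectivity is the
  common choice for foreground in binary image analysis).

## Depth model

Let area(i) be the lesion area of slice i and ref the largest-area
slice. With slice thickness t (mm):

* **C0** = t × #{i : area(i) > 0}.
* **C1** = t × Σ w(area(i)/area(ref)) over bearing slices, where the
  weight w is 1 for ratios above 0.75, 0.5 for ratios in [0.25, 0.75],
  and 0 below 0.25.

The reference slice for the ratios is the largest-area slice: it is the
only choice that guarantees ratios ≤ 1 (hence C1 ≤ C0) and matches the
slice-weighting convention the adjusted depth originates from. Band
edges are read inclusively into the middle band (exactly 0.25 or 0.75 →
0.5); both thresholds are arguments of `weight_for_ratio()` for
sensitivity analyses. The central slice is the middle element of the
ordered bearing list (not the geometric z-midpoint); with an even
count, the larger-area slice of the middle two wins and an exact tie is
broken by a seeded random draw whose seed is recorded in the output.
Lesion-free gaps inside the span are allowed but warned about, and gap
slices do not count toward C0 (the depth counts *hematoma-bearing*
slices).

Slice thickness above 5 mm triggers a warning rather than an error: the
study population excluded thick-slice scans, but the arithmetic remains
well defined.

## Estimators and units

Lengths are kept in mm; products A·B·C are divided by 1000 so that
estimates, coefficients and intercepts all live on the mL scale of the
planimetry reference (an intercept of −1.04 only makes sense in mL).
Planimetry is computed as Σ area × thickness — the voxel-count volume
that slice-wise segmentation software reports.

`measure_case()` runs the full chain on a 3-D mask and is
self-consistent by construction: each estimate equals
`coefficient × product + intercept` on the record's own products.

## Calibration

`fit_linear_calibration()` is plain ordinary least squares with
intercept (the default linear regression of the statistics package the
study used); no robust or weighted scheme, no cross-validation. R² is
the ordinary coefficient of determination. `derive_variation()` wraps a
fit as a usable variation spec.

The packaged cohort table only prints the traditional half-product
estimates, so the products are reconstructed as exactly twice those
columns. Because the printed columns are rounded to 2 decimals, fits on
the reconstruction match the study's parameters to about 2 decimals
(slopes/intercepts) and 3–4 decimals (R²) — that rounding, not the
regression, limits the agreement.

## Evaluation

* **Percentage deviation** is the absolute relative deviation × 100.
  The study never writes the formula, but its printed deviation ranges
  are non-negative, which forces the absolute value.
* **Deviation bins**: "<10%" is strict; exactly 10% or 20% falls in the
  middle "10–20%" bin (by elimination from the table's headings).
* **Closest value**: per case, the variation with the smallest absolute
  difference from planimetry wins. Differences within 1e-8 mL of the
  case minimum are treated as tied — printed tables produce ties whose
  text-parsed doubles differ in the last ulp. The default tie policy
  awards the **earliest-listed** tied variation (listing order 1, 2, 3,
  4, 1′, 2′, 3′, 4′). The choice is empirical: 19 of the 53 packaged
  cases print identical variation-2/4 estimates (the largest-area slice
  *is* the central slice), so the tie policy dominates the traditional
  intra-group tally, and only earliest-listed reproduces the study's
  counts (30/53 for variation 2 intra-group; 1, 2, 1, 0, 3, 18, 10, 18
  overall). `"last"` and seeded `"random"` policies remain available
  and the policy is recorded in the output.
* **Mean comparison**: Levene's test (center = mean) gates a pooled
  two-sample t-test (p > 0.05) versus Welch's; always two-sided and
  unpaired — the study reports an *independent* t-test. A paired test
  would be the more powerful design, but it is not what is being
  reproduced.
* **Bland–Altman**: mean difference ± 1.96 sample SD; the payload
  (pair mean vs difference) can be plotted with `plot_bland_altman()`.
* Summary means and SDs use the sample (n−1) convention.

## Synthetic phantoms: what they do and do not establish

The generators emulate axial CT mask stacks: in-plane spacing around
0.4–0.6 mm, slice thickness 3–5 mm (≤ 5 mm, the study's inclusion
limit), lesion volumes log-normally distributed with mean 31.72 mL and
SD 39.24 mL truncated to 3–240 mL — the moments and range of the study
cohort. Three shapes are provided:

* **Ellipsoid** (`make_ellipsoid_phantom()`) — closed-form truth
  4/3·π·abc; the ABC/2 idealisation itself.
* **Biconvex lens** (`make_lens_phantom()`) — intersection of two equal
  spheres (radius R, centers d apart), truth π(4R + d)(2R − d)²/12; the
  textbook epidural-hematoma shape. The lens axis lies in-plane, as it
  does anatomically (perpendicular to the skull).
* **Irregular** (`make_irregular_phantom()`) — a star-shaped radial
  perturbation of an ellipsoid by a smooth seeded random field on the
  sphere, normalised so an amplitude below 1 guarantees
  star-shapedness; truth from a voxel-count oracle on a grid at least
  4× finer in every dimension.

A voxel is foreground iff its center lies inside the analytic surface —
simple and unbiased to first order in the spacing. The default shape
mix (0.35/0.45/0.2) is lens-heavy because most tEDHs are biconvex.

Phantoms validate the geometry, not the clinic: binary masks with
perfect boundaries say nothing about segmentation error, partial-volume
effects, window/level settings, or reader variability. A green phantom
test establishes that the measurement chain computes what it claims on
known shapes at the claimed convergence rate — nothing more.

One systematic effect is worth understanding: C0 overestimates the true
axial extent by about one slice thickness (every slice whose center
falls inside the lesion counts fully), so the traditional estimate on a
perfect ellipsoid approaches (3/π)·(1 + t/2c) of truth, not 3/π. The
property tests therefore use thin slices (1 mm) when checking the
analytic 3/π ≈ 0.955 ratio; at clinical 5 mm thickness the same bias is
one reason the C1-based variations outperform the C0-based ones.

## The packaged cohort table

The 53-case per-case table (planimetry plus the eight printed variation
estimates, with sex and age) ships as a CSV fixture with an embedded
checksum; `load_study_fixture()` verifies integrity, and attaches the
reconstructed products. Raw CT/DICOM data were never deposited, so the
printed table is the only machine-readable ground truth available; the
identities it satisfies (traditional columns = half products, primed
columns = fitted line applied to products within double-rounding
tolerance, ±0.012 mL) are tested.

## Known limitations

* Masks are trusted as given; no intensity processing, no segmentation.
* NIfTI-1 support is a minimal reader/writer (single-file `.nii`/
  `.nii.gz`, common datatypes); DICOM series are not read.
* One slice thickness per series; no interpolation between slices.
* Contours with interior holes are handled but ordered only along the
  outer boundary; hematoma masks are solid in practice.
* The calibrated coefficients come from 53 cases at a single center;
  they are reproduced here as published, not re-validated on new data.
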