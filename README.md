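# edhvol

Automatic ABC/2 volumetry for traumatic epidural hematoma (tEDH) on CT
segmentation masks — per-slice geometric measurement, adjusted-depth
estimation, regression calibration of the estimator family, and the
accuracy-evaluation statistics used to compare the variations against
planimetry, validated on synthetic phantoms with analytically known
volumes.

## Who this is for

Neuroimaging researchers and methodologists who need reproducible
hematoma volumetry from binary masks (e.g., ITK-SNAP segmentations
exported to NIfTI), or who want to study the accuracy of ABC/2-type
bedside estimators without re-implementing the measurement chain.

## The model

An ellipsoid with axis lengths A, B, C has volume π/6·ABC ≈ ABC/2. On
an axial mask stack the package measures, per slice, the lesion area,
the maximum length A (largest pixel-center distance, a Feret diameter)
and the maximum width B perpendicular to it (longest perpendicular
chord through a boundary pixel). Depth is either

* `C0` — slice thickness × number of hematoma-bearing slices, or
* `C1` — slice thickness × Σ weights, each bearing slice weighted
  1 / 0.5 / 0 by its area ratio to the largest-area slice
  (>75% / 25–75% / <25%).

A and B come from the largest-area slice (A1, B1) or from the central
bearing slice (A2, B2). Each variation is `a·(A·B·C/1000) + b` in mL:
the four traditional forms use `a = 0.5, b = 0`; the four calibrated
forms use the slopes/intercepts fitted by ordinary least squares of
planimetry on the corresponding product (0.37/−0.75, 0.65/−1.04,
0.39/−0.04, 0.65/−0.17). Planimetry (Σ area × thickness) is the
reference standard throughout.

## Worked example

```r
library(edhvol)

# a biconvex lens phantom: two spheres of radius 30 mm, centers 35 mm
# apart -- the textbook epidural-hematoma shape, true volume known
p <- make_lens_phantom(R = 30, d = 35, spacing = 0.5, thickness = 4)
p$true_volume_mL
#> [1] 25.36343

rec <- measure_case(p$mask, p$spacing, p$thickness, case_id = "lens-demo")
rec
#> <case_record> lens-demo: planimetry 25.26 mL, A1 48.0 B1 25.0 A2 48.0 B2 25.0 C0 52.0 C1 28.0 mm
#>     1     2     3     4    1p    2p    3p    4p
#> 31.19 16.79 31.19 16.79 22.33 20.79 24.29 21.66
```

Planimetry on the voxelized phantom (25.26 mL) sits within 0.5% of the
closed-form truth. The lens is 48 mm long and 25 mm thick in-plane;
`C0` (52 mm) overshoots the true 48.7 mm axial extent by about one
slice, while the adjusted `C1` (28 mm) down-weights the thin marginal
slices — which is why the C1-based variations (2, 4 and their
calibrated forms) track the truth better on biconvex lesions.

Reproducing the packaged 53-case cohort analysis:

```r
res <- reproduce_study()
res$summary
#> <evaluation_summary> 53 cases, tie policy 'first'
#>  variation      estimate    p       closest       dev_pct lt10 b10_20 gt20
#>         v1 43.49 ± 52.34 0.19   6/53 | 1/53 40.29 ± 19.96    2      7   44
#>         v2 25.19 ± 30.13 0.34  30/53 | 2/53  19.13 ± 6.33    5     24   24
#>         v3 40.51 ± 49.73 0.31   7/53 | 1/53 32.72 ± 17.04    4      7   42
#>         v4 24.60 ± 30.23 0.30  10/53 | 0/53  21.28 ± 6.80    2     21   30
#>        v1p 31.43 ± 38.73 0.97   5/53 | 3/53  11.84 ± 9.04   25     20    8
#>        v2p 31.71 ± 39.17 1.00 19/53 | 18/53   7.29 ± 5.90   38     13    2
#>        v3p 31.56 ± 38.79 0.98 10/53 | 10/53 11.25 ± 11.00   29     16    8
#>        v4p 31.82 ± 39.30 0.99 19/53 | 18/53   6.42 ± 5.74   45      6    2

res$calibration[["2p"]]$fit
#> <regression_fit> y = 0.6502 x -1.0427 mL, R2 0.9968, n = 53
```

Each row is one variation: mean ± SD of its estimates (mL), the
Levene-gated independent t-test p-value against planimetry, closest-
value wins (within its group | among all eight), mean ± SD percentage
deviation, and the <10% / 10–20% / >20% deviation bin counts. The
calibrated C1-based variations (`v2p`, `v4p`) are the most accurate:
mean deviations 7.29% and 6.42%, with 38 and 45 of 53 cases inside 10%.

## Command line

```sh
inst/cli/edhvol measure   --mask lesion.nii.gz            # per-case JSON
inst/cli/edhvol estimate  --mask lesion.nii.gz --variation 2p
inst/cli/edhvol calibrate --product A1B1C1 --out fit.json
inst/cli/edhvol evaluate  --out report/                   # summary tables
inst/cli/edhvol simulate  --n 10 --seed 7 --outdir phantoms/
inst/cli/edhvol reproduce-study --out report/
```

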