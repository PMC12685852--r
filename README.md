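# mvquant

Quantitative mitral valve geometry from labelled 3D/4D transesophageal
echocardiography (TEE) volumes.

Pre-procedural assessment of mitral regurgitation — in particular eligibility
for transcatheter edge-to-edge repair (M-TEER) — hinges on the mitral valve
area and its dynamics over the cardiac cycle. Once the valve has been
segmented (by a network or by hand) into anterior leaflet, posterior leaflet
and annulus labels, turning those labels into reproducible measurements is a
purely geometric problem. `mvquant` solves that problem:

* **Annulus reconstruction** — sparse manual control points placed along the
  annulus (3D Slicer markups JSON) are fitted with a closed interpolating
  periodic spline, sampled at 100 parameter values, thickened into a 1.5 mm
  tube, voxelized by exact point-to-segment distance, and cleaned by
  connected-component post-processing (size gate, then highest mean
  z-coordinate).
* **Per-frame valve geometry** — the annulus label is thinned to its 3D
  centerline, the centerline is ordered by constrained nearest-neighbour
  traversal, the valve plane is the PCA plane of the ordered points (normal =
  eigenvector with the smallest eigenvalue), and all structures are projected
  onto it with exact voxel footprints and calibrated isotropic pixels.
* **Effective orifice area (EA)** — the projected annulus ring is closed and
  hole-filled; a flood fill from the ring centroid over structure-free pixels
  measures the functional opening in mm².
* **Temporal analysis** — per-frame EA assembles into a curve; the
  maximum-opening (mid-diastolic) frame is its argmax; summaries and
  Pearson / Bland–Altman agreement statistics against reference measurements
  are built in.
* **Segmentation objectives** — the multi-class generalized Dice loss
  (averaged over classes present in the image), focal loss (γ = 2, summed
  over all classes), their combination, deep supervision with
  nearest-neighbour downsampled ground truth, and Dice / precision / recall /
  FPR evaluation metrics, all network-independent.
* **Synthetic phantoms** — analytic saddle-annulus valve phantoms with a
  known plane, orifice schedule r(t) and EA(t) = πr(t)², so the whole chain
  is testable without any patient data.

In the notation used throughout: label volumes map voxel indices to world mm
through a stored affine; the valve plane is `(centroid c, normal n, basis u,
v)` with `n` the smallest-eigenvalue eigenvector of the centerline
covariance; EA is `#(flooded pixels) × pixel area`.

## Worked example

Generate a 4-frame phantom, rebuild its annulus from the exported control
points, and quantify the cycle — from R or from the shell via the bundled
CLI (`inst/cli/mvquant`):

```sh
mv=$(Rscript -e 'cat(system.file("cli", "mvquant", package = "mvquant"))')
Rscript $mv phantom --out ph --frames 4
Rscript $mv enhance-annulus --markups ph/annulus.mrk.json \
        --template ph/frame_000.nii.gz --out enhanced.nii.gz
Rscript $mv curve --seq ph --out curve.csv --summary summary.json
```

which prints and writes:

```
wrote 4 frames, markups and truth to ph
wrote enhanced volume (annulus voxels: 5092) to enhanced.nii.gz
curve over 4 frames; peak frame 2 (EA 316.31 mm^2)

# curve.csv
frame,anterior_mm2,posterior_mm2,annulus_mm2,ea_mm2
0,242.312500,242.375000,243.375000,12.812500
1,192.562500,192.625000,243.375000,112.437500
2,90.562500,90.750000,243.375000,316.312500
3,192.562500,192.625000,243.375000,112.437500
```

Reading the numbers: the phantom's orifice opens from r = 2 mm (analytic EA
π·2² ≈ 12.6 mm²) to r = 10 mm at mid-cycle (π·10² ≈ 314.2 mm²); the measured
EA tracks both within a few percent, leaflet area shrinks as the orifice
opens, annulus area is constant, and the detected peak frame (2 of 4) is the
analytic maximum opening. The same pipeline is available programmatically:

```r
library(mvquant)
spec  <- phantom_spec()                       # 16 frames, 96^3, 0.5 mm
seq   <- make_phantom_sequence(spec)
curve <- compute_ea_curve(seq$frames)
curve$peak_frame                              # 8 == seq$truth$peak_frame
compare_measurements(seq$truth$ea_per_frame_mm2, curve$ea_mm2)
#> paired validation (n = 16): r = 1.000, bias = -0.363, 95% LoA [-3.783, 3.058]
```

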