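---
title: "Methods: mitral valve geometry and effective orifice area from labelled 4D echo volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitral valve geometry and effective orifice area}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`mvquant` implements the deterministic, non-learned core of an automated
mitral valve assessment pipeline for labelled 3D/4D transesophageal
echocardiography (TEE) volumes. Its input is a per-frame integer label volume
— background (0), anterior leaflet (1), posterior leaflet (2), annulus (3) —
plus, for annotation enhancement, sparse 3D control points placed manually
along the annulus. Its outputs are per-frame calibrated structure areas and
the effective orifice area (EA), the EA curve over the cardiac cycle with the
maximum-opening (mid-diastolic) frame, and agreement statistics against
reference measurements. The package also provides, independent of any
network, the multi-class segmentation objectives (generalized Dice loss,
focal loss, their combination, deep supervision on downsampled ground truth)
and evaluation metrics used to train and assess valve segmentation models.

Segmentation itself (the CNN stage) is out of scope: `mvquant` starts from
labels, whether they come from a model or from manual annotation.

# Annulus reconstruction from control points

Manual annulus annotations arrive as ordered world-coordinate control points
(3D Slicer markups JSON). Reconstruction proceeds in four steps:

1. **Spline fit.** Each world coordinate is fitted against a normalized
   chord-length parameter. The annulus is a ring, so the default fit is a
   *closed periodic* interpolating cubic spline (`splines::periodicSpline`);
   open curves use a natural interpolating spline. The default smoothing is
   zero: the curve passes through every control point exactly (residual
   below 1e-6 mm), which is the right behaviour for deliberate manual
   annotations. A positive smoothing penalty switches to a cubic smoothing
   spline for noisy input.
2. **Dense sampling.** The spline is evaluated at 100 equally spaced
   parameter values (configurable); for closed curves the first and last
   samples coincide, closing the polyline exactly.
3. **Tube voxelization.** A cylindrical tube of radius 1.5 mm is voxelized
   onto the target grid by exact point-to-segment distance: a voxel is set
   iff its world-space center lies within the radius of the sampled
   polyline. This is grid-independent and testable against closed-form
   volumes (a straight tube recovers the analytic cylinder volume within the
   digitization error plus the two hemispherical end caps; a closed ring
   recovers the torus volume).
4. **Component post-processing.** 26-connected components are labelled;
   among components at least 25% the size of the largest, the one with the
   highest mean world z is kept. The size gate and the height rule are
   deliberately separate: "significance" alone is ambiguous when a spurious
   fragment sits above the true annulus, and the height rule alone would
   promote a one-voxel speck. Both candidates are logged when the gate
   matters.

The reconstructed tube is written as label 3 without overwriting leaflet
labels: the leaflets are the thin structures of interest, while the tube
radius is a modelling artifact of the annotation.

# Per-frame valve geometry

For each frame:

1. **Skeletonization.** The annulus label is thinned to its centerline by
   homotopic 3D thinning: simple border points (points whose removal
   provably preserves 26/6 topology, checked by the standard two-condition
   neighbourhood characterization) are removed sequentially until
   stabilization; endpoints are preserved. For tube-like annuli the skeleton
   is a one-voxel-wide closed ring hugging the tube axis.
2. **Centerline ordering.** Skeleton points are ordered greedily: start at
   the point with minimal first world coordinate (ties broken on the second
   and third coordinates, then voxel index — this makes ordering fully
   deterministic), then repeatedly append the nearest unvisited point whose
   step direction does not reverse the previous direction (dot product >= 0,
   i.e. turns under 90 degrees). When no candidate satisfies the constraint
   the nearest point is taken and a backtrack event is logged. The path is
   closed iff the end-to-start gap is at most twice the median step.
3. **Plane fit.** PCA on the ordered centerline: the plane passes through
   the centroid, and the normal is the eigenvector with the smallest
   eigenvalue. The in-plane basis spans the top two eigenvectors,
   orthonormalized and right-handed. The normal is oriented away from the
   leaflet centroid (the ventricular side), making signed quantities
   reproducible; without leaflets the +z convention is used.
4. **Projection and rasterization.** Every labelled voxel is projected
   orthogonally onto the plane. Rather than splatting center points, the
   *exact footprint* of each voxel cell (the shadow of the cell along the
   plane normal) is rasterized: for each pixel the chord length of the
   projection ray through the cell is accumulated into a per-structure
   material-depth raster. The raster pixel size defaults to half the
   minimum voxel spacing; because projection is performed exactly in world
   coordinates, spatial calibration holds for any angle between valve plane
   and voxel grid, and for anisotropic voxels.
5. **Areas.** Structure areas are pixel counts times pixel area on the
   *majority-coverage* silhouette: pixels whose material depth is at least
   half the structure's median positive depth. The alternative — counting
   any pixel the silhouette touches — systematically inflates thin oblique
   structures: a digitized 1 mm leaflet sheet tilted 30 degrees to the grid
   grows an 8-10% staircase fringe of pixels covered only by cube corners.
   The majority rule suppresses exactly that fringe and keeps areas stable
   (under 5% change) under rigid rotation of the volume, while leaving
   axis-aligned geometry untouched.
6. **Effective orifice area.** The *any-material* silhouette of the annulus
   ring is morphologically closed (disc radius of three tube radii, logged
   when it changes the ring) and its enclosed region extracted by hole
   filling. A flood fill seeded at the ring centroid (relocated to the
   nearest free pixel if the centroid is occupied, e.g. in systole) grows
   over pixels free of any projected structure inside the enclosed region;
   EA is the flooded pixel count times pixel area. Blocking deliberately
   uses the conservative any-material silhouette: any projected leaflet
   material should stop "flow". If the ring cannot be closed the frame
   fails with an open-ring error carrying the estimated gap size, which the
   sequence level records as a gap rather than aborting.

# Temporal analysis

The per-frame pipeline is mapped over the cycle; failed frames become logged
gaps. The maximum-opening (mid-diastolic) frame is the argmax of the EA
series, ties broken by the earliest frame. The agreement utility reports the
Pearson correlation of paired measurement series plus Bland–Altman bias and
95% limits of agreement (bias ± 1.96 SD of differences), optionally
stratified at the median pair mean. Frames are treated as uniformly spaced
in index space; timestamps, when present in the source, are carried through
unchanged.

# Segmentation objectives

Probability maps are `[H, W, C]` arrays of per-pixel class probabilities;
ground truth is one-hot. With `p_ic` the predicted probability and `g_ic`
the indicator:

* **Generalized Dice loss** averages the per-class soft Dice complement over
  the classes *present in the image* (`C'`), with a small epsilon
  (default 1e-6) guarding the denominator:
  `L = 1 - (1/|C'|) * sum_c (2 sum_i p_ic g_ic + eps) / (sum_i p_ic + sum_i g_ic + eps)`.
  Absent classes contribute nothing, so extending the legend never changes
  the loss.
* **Focal loss** sums over *all* classes with focusing parameter gamma = 2
  by default: `L = -(1/N) sum_i sum_c (1 - p_ic)^gamma g_ic log p_ic`, with
  probabilities clipped to `[1e-7, 1 - 1e-7]` before the logarithm. At
  gamma = 0 it reduces exactly to mean cross-entropy.
* **Combined loss** is the unweighted mean of the two.
* **Deep supervision** adds the combined loss of each intermediate output
  against the ground truth downsampled to its size by nearest neighbour
  (source index = floor(output index × scale), a fixed deterministic
  convention), preserving discrete labels; the terms are summed unweighted.

Evaluation uses the hard Dice coefficient `2|A∩B|/(|A|+|B|)` plus per-class
precision, recall and false positive rate from the binarized confusion
counts. Conventions for degenerate cases, which matter when averaging over
images where a structure is absent: empty-vs-empty Dice is 1; an empty
denominator in precision/recall/FPR yields 0 and is flagged. Tables across
image sets report per-image mean ± SD per class.

# The synthetic phantom

Every stage is tested against an analytic 4D phantom, generated in code:

* a saddle annulus ring of radius `R` (default 14 mm) with height modulation
  `h cos(2θ)` (default h = 2 mm; two high points, two low points, the
  textbook saddle shape), thickened into a tube of radius 1.5 mm;
* two leaflet sheets (anterior θ ∈ [0, π), posterior θ ∈ [π, 2π)) spanning
  from the annulus inward to the frame's orifice radius, blending from the
  saddle height at the annulus to the mid-plane at the orifice rim, about
  two voxels thick (default 1 mm) — thin sheets deliberately stress the
  projection and flood-fill stages the way echocardiographic leaflets do;
* a cosine orifice schedule
  `r(t) = r_min + (r_max - r_min)(1 - cos(2πt/n))/2` (defaults 2-10 mm over
  16 frames), so EA(t) = πr(t)² in closed form and the peak frame is n/2;
* optional rigid tilt of the whole valve relative to the grid axes;
* default grid 96³ at 0.5 mm isotropic spacing, chosen so the tilted
  annulus fits with at least a two-voxel margin.

Where tube and leaflets overlap, the phantom keeps the annulus label, so
label 3 is exactly the voxelized tube and closed-form volume/Dice oracles
apply. The truth object records the exact plane, per-frame EA and peak
frame. Generation is fully deterministic given the spec.

The phantom emulates geometry only. It has no speckle, no B-mode texture, no
dropout, no regurgitant jets, and no pathological morphology (prolapse,
flail, clips); passing its tests demonstrates the correctness of the
geometric measurement chain on clean labels, not robustness of any
segmentation to real image artifacts.

# Numerical choices and limitations

* Problem sizes in the test-suite and acceptance runs: 96³ default phantoms,
  a 0.4 mm / 96³ phantom for reconstruction overlap, ten randomized phantoms
  with three frames each for the EA validation, and 32×32×11 toy maps for
  the loss oracles. These sizes keep the full suite to roughly half a
  minute while leaving the digitization error well below the tolerances the
  contracts state.
* EA accuracy is limited by digitization: at 0.5 mm spacing the recovered EA
  stays within ~5% of the analytic value down to orifice radii of 2 mm
  (where a half-voxel boundary shift is already 12% of the area — the exact
  footprint rasterization is what keeps the error far below that bound).
* The ordering constraint threshold (turns < 90°) and the ring-closing
  radius (3 tube radii) are heuristics; both log when they take effect.
* `compare_measurements` is agnostic to where its two series come from; in
  clinical use the reference and prediction should be planimetered at
  comparable cardiac phases.
* World-coordinate conventions (RAS vs LPS) of markups files are read from
  the file when present and can be overridden (`--coords`); the package
  never guesses silently.
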