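---
title: "Serial-section reconstruction of red pulp microvasculature: methods"
author: "splenvas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial-section reconstruction of red pulp microvasculature: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Human splenic red pulp is supplied by terminal arterioles that end in
*sheathed capillaries*: post-arteriolar capillaries wrapped for up to four
sequential dichotomous bifurcations by a cuff of CD271-strong stromal cells,
accompanied by B lymphocytes. The capillaries release open-ended side
branches that cross the sheath and end freely at its surface, and
non-sheathed bypass capillaries connect arterioles directly to the cord
capillary network; contacts between that network and venules are rare. None
of this microanatomy is visible in single sections — it only emerges from
three-dimensional reconstruction of serial sections.

`splenvas` implements the reconstruction pipeline for such data: stacks of
RGB brightfield sections (0.5 µm/pixel in plane, nominally 7 µm thick),
triple-immunostained so that every section carries smooth-muscle actin (SMA,
brown) and the endothelial marker CD34 (blue), while alternating sections
add either CD271 (sheath stroma) or CD20 (B cells) in red. Because no public
scanned series exists, the package ships a synthetic phantom generator that
renders exactly this acquisition from a known vascular ground truth, so
every stage — and the pipeline end to end — is testable.

## Pipeline overview

1. **Color normalization** (`reinhardNormalize`): per-channel mean/sd
   transfer in the logarithmic lαβ color space against a chosen standard
   section. Intended for series stained in batches; the phantom renders one
   "batch", so the reference profile ships with normalization disabled.
2. **Registration** (`extractRegistrationChannel`, `registerStack`,
   `applyAlignment`): sparse, stack-global recovery of per-section rigid
   transforms from the color-deconvolved blue (CD34) channel blurred with a
   Gaussian of σ = 6 px. Transforms are applied to the unblurred RGB
   sections, followed by a central crop.
3. **Stain unmixing** (`subtractBackground`, `colorDeconvolve`,
   `channelToIntensity`, `unmixStack`): white-point correction, conversion
   to optical density, rowwise solution of the 3×3 stain system, and
   channel-specific reduction to 8-bit intensity with a stack-wide stretch.
4. **Volume building** (`flowInterpolateZ`, `nnResizeZ`,
   `filterChannelVolume`): optical-flow z-interpolation from
   0.5 × 0.5 × 7 µm voxels to 0.5 × 0.5 × 1 µm for SMA and CD34 and from
   14 µm to 2 µm for CD271 (which lives on every other section); CD20 stays
   at its native 14 µm spacing. Channel-specific grayscale morphology
   follows (see below).
5. **Meshing** (`isosurface`, `repairWatertight`): marching-cubes extraction
   at iso-value 100 (CD34, CD20) or 160 (SMA, CD271), then watertight
   octree-style repair at depth 9 (CD34), 7 (SMA) or 8 (CD271, CD20).
6. **Mesh post-processing** (`taubinSmooth`, `removeSmallComponents`,
   `quadricDecimate`): ten Taubin iterations (λ = 0.5, µ = −0.53, all
   channels except CD20); removal of components whose bounding-box diagonal
   is under 2 % (CD34), 10 % (SMA) or 5 % (CD271) of the mesh main diagonal
   (CD20 exempt); quadric decimation to 10 % of the faces for CD34 and 50 %
   for CD271 and CD20.
7. **Painting and pruning** (`paintByProximity`, `pruneCellComponents`):
   CD34 vertices strictly closer than 8.75 µm to the SMA surface are painted
   white (arteriolar wall proximity), the rest blue; B-cell components
   smaller than 10 µm in diameter, or farther than a configurable distance
   from the sheath mesh, are pruned.
8. **Scoring** (`recoverTopology`, `geodesicPathLength`): with phantom
   ground truth available, sheath coverage, open-ended side branches,
   bypass capillaries and venule contacts are matched to the meshes, and
   the designed long sheathed path is measured entry-to-exit as an
   on-surface geodesic.

`runPipeline()` orchestrates all stages deterministically from one master
seed (per-stage seeds are derived by a fixed fan-out), caches stage outputs
when an output directory is given, and returns a manifest with timings and
the recovery report. A thin command-line wrapper is installed under
`inst/cli/splenvas.R`.

```{r}
library(splenvas)
man <- runPipeline(defaultPipelineConfig(seed = 1L), verbose = TRUE)
man@outputs$report
```

## The stain model

Transmitted brightfield color follows Beer–Lambert mixing: with per-stain
column densities $A_s$ and unit optical-density vectors $M_{s\cdot}$ (rows
of the stain matrix; defaults are the published DAB / alkaline-phosphatase
Fast Blue / Fast Red unmixing vectors, as the original stains' vectors are
not published), the renderer produces

$$I_c = 256\cdot 10^{-\sum_s A_s M_{sc}} - 1 ,$$

and the unmixer inverts with $OD_c = -\log_{10}((I_c+1)/256)$ and
$A = OD\,M^{-1}$. The +1/256 transmittance convention guards
$\log 0$ and makes rendering followed by deconvolution exact to machine
precision, which the tests exploit (round-trip error below $10^{-6}$).
Channel reduction mirrors the original workflow: the blue stain is
re-rendered through its own vector and reported as 255 − G, brown as
255 − B, red as the CMYK magenta component under the naive conversion
$K = 1 - \max(R,G,B)/255$, $M = (1-G/255-K)/(1-K)$; intensities are then
stretched linearly over the stack-wide min/max so iso-values are
comparable across slices.

## Registration details

Features are local maxima of the blurred blue channel with quadratic
subpixel refinement and normalized 21×21 patch descriptors. Candidate
matches combine a position prior (serial sections cannot move far) with a
loose appearance gate; a 2-point RANSAC rigid consensus cleans each pair of
sections up to k = 2 apart. All retained matches enter a global
Gauss–Newton solve over per-section rigid transforms (similarity with scale
locked to 1; the reference section is fixed to the identity). The robust
loss is a redescending Tukey biweight (c = 3 px): vessel segments crossing
the block obliquely drift coherently from section to section and would bias
any monotone M-estimator, so far-drifting matches must lose *all* influence.
The initial solution is then refined by alignment-guided re-matching at
shrinking radii (15 → 1.5 px) of mutual nearest features, now also across
long z offsets (4, 6, 8, 12, 16, 24, 32 sections). The long baselines are
what makes the optimization genuinely stack-global: neighbor-only matching
cannot constrain low-frequency drift of the whole series, while structures
that persist across dozens of sections (terminal arteries, venules) pin it.

On the desk-scale phantom with jitter up to ±10 px translation and ±2°
rotation, recovered transforms agree with the true jitter to about 0.2–0.35
px RMS over structure pixels (the acceptance bound is 0.5 px).

## Volume filtering

All morphology uses digital-ellipsoid structuring elements (voxel centers
within the ellipsoid; radii are x-y-z half-axes in voxels) implemented as
exact running-extrema decompositions, verified against a brute-force
oracle. On the interpolated volumes: CD34 gets a closing of uniform radius
7 and Gaussian σ = 1; SMA a dilation 7-7-4, closing 8-8-4, Gaussian σ = 2;
CD271 a dilation 8-8-2, closing 5-5-5, Gaussian σ = 1; CD20 passes through
untouched.

The flow interpolator estimates dense bidirectional optical flow per slice
pair (coarse-to-fine iterative Lucas–Kanade) and blends the two
flow-compensated warps; original slices are preserved bit-exactly at their
positions and the output has $(Z-1)\,f+1$ slices. Flow is only observable
where there is image structure, so the fields are propagated across empty
background by content-weighted (normalized-convolution) smoothing before
warping — without this, unmoved copies of fast-moving vessels ghost into
the interpolated slices and can fuse into spurious bridges.

## Meshing and repair

The iso-surfacer is a marching-cubes variant whose case table is generated
at load time: on every cube face the iso-crossings are connected by
marching-squares segments with one fixed rule for the ambiguous diagonal
case (the inside corners are kept separate); the segments close into
polygons that are star-triangulated from a patch centroid. Because the face
rule depends only on the face's own corner states, neighboring cubes always
agree, and the triangulation is crack-free; values exactly equal to the
iso-value count as inside; crossings are placed by linear interpolation.
By default the volume is padded with one zero layer so structures cut by
the block boundary are capped (`padBoundary = FALSE` reproduces the
classic open behavior).

Two numerical properties matter for interpreting the tests. On smoothly
sampled (partial-volume) data the extracted surface is accurate: a
digitized ball of radius 20 voxels meshes to within ~2 % of the analytic
sphere area and volume. On *strictly binary* data, however, any
edge-interpolating marching-cubes surface carries the well-known staircase
metrication bias: enclosed volume stays accurate (~1 %) but surface area
runs ~8–10 % above the smooth sphere. The package does not hide this; the
unit tests pin the bias and downstream smoothing removes most of it.

Watertight repair rasterizes the mesh into a cubic grid of $2^{d}$ cells
spanning its bounding cube (conservative separating-axis triangle/box
overlap — a sampled rasterizer leaves pinholes through which the flood
fill would leak), flood-fills the exterior from the grid boundary, and
re-extracts the boundary of the occupied-plus-enclosed set. The result is
always a closed 2-manifold; for closed inputs the symmetric Hausdorff
distance to the input stays under two cell sizes. An input with a large
opening comes back as a closed thin shell (both walls) rather than a
filled solid, which is why the pipeline caps surfaces at extraction time
instead. Large vessels meshed from thick-walled staining can produce
double-walled envelopes; this mirrors the behavior of the original
workflow and is left visible rather than suppressed.

Geodesics are measured on a refined edge graph (mesh edges plus
edge-midpoint links inside every triangle), which removes most of the
overestimation of pure edge-graph shortest paths; a 300 µm straight
cylinder measures within ~1 %.

## What the phantom emulates — and what it does not

The generator builds a centerline graph with per-edge radii and classes:
terminal-artery columns spanning the whole depth; arteriole stems and
branches off them (SMA+CD34); sheathed capillaries whose CD271 shell
(inner radius 4.5 µm, outer 10 µm) covers one to four bifurcations; child
branches that cross the shell; open-ended side branches ending at the
shell surface; post-sheath cord capillaries meandering to the bottom of
the block with short twigs; near-vertical cord capillary columns; bypass
capillaries; one venule with a configurable number of capillary contacts;
and B-cell spheres around each sheath. Sections are rendered by
integrating soft (partial-volume) occupancy through each 7 µm slab,
Beer–Lambert mixing, per-section rigid jitter and Gaussian noise. The
default desk scale is 256 × 256 px × 48 sections (128 × 128 × 336 µm) —
small enough for routine testing, deep enough to host the designed long
sheathed path described below.

Three deliberate design choices make the phantom a *calibration target*
rather than a histology simulator:

* **Persistent vertical anchors.** Real blocks contain large structures
  (follicles, trabecular vessels, arteries) that persist across dozens of
  sections and anchor registration. The phantom provides them as artery
  columns and near-vertical cord capillaries. Without such anchors,
  sub-pixel recovery of absolute jitter is not achievable by any method —
  content that drifts coherently between sections is indistinguishable
  from misalignment.
* **A designed long sheathed path.** The first arteriole feeds a gently
  turning helical capillary (radius ≈ 18 µm, 45° and 16 µm of depth per
  segment, four covered bifurcations) whose entry-to-exit geodesic exceeds
  300 µm. Its exit ends free in the cords (open ends are documented
  anatomy), and later structures keep a 26 µm clearance corridor around
  it, because a single touching vessel — after a closing with radius
  7 voxels — would short-circuit the geodesic. Bends are kept gentle
  because hairpin folds would be glued shut by the same closing.
* **Surface-geodesic ground truth.** The reference value for the designed
  path is measured as an on-surface geodesic on a 0.5 µm voxelization of
  the path alone (`heroReferenceGeodesic`), not as centerline length: on a
  curved tube the surface geodesic is shorter than the centerline by
  roughly (tube radius) × (total turning), a definitional effect that
  would otherwise masquerade as reconstruction error. Both the reference
  and the pipeline measurement are therefore the same kind of quantity.

The phantom does **not** emulate tissue texture (parenchyma, erythrocytes,
autofluorescence), stain batch variation, antigen-retrieval deformation
(jitter is strictly rigid), out-of-focus optics beyond an optional
Gaussian defocus, or the cellular composition of sheaths. Passing the
end-to-end tests therefore demonstrates that the *algorithms* recover
known geometry under the stated acquisition physics — not that the
pipeline is robust to every artifact of real scanned tissue.

## Recovery scoring

`recoverTopology()` replaces the original expert labeling in virtual
reality with ground-truth-driven checks: a sheath counts as detected when
at least half of the rings sampled on its mid-shell surface are covered by
the CD271 mesh (coverage = inside the closed mesh, tested on a voxelized
occupancy of the mesh, or within tolerance of its surface — filtered
shells are thick solids, so surface distance alone would misclassify
interior points); a side branch when its free tip lies within tolerance
plus its own radius of the CD34 surface; bypass chains and venule contacts
by centerline sampling; and the designed path by its measured geodesic.
The registered stack lives in the reference section's jittered frame, so
ground truth is mapped by that section's (known) jitter before scoring.
The default tolerance is 4 µm — about one capillary radius.

## Numerical choices and degenerate rules

* OD epsilon: the +1 in $-\log_{10}((I+1)/256)$ is fixed, documented, and
  shared with the renderer.
* Intensity stretch is stack-wide per channel, never per section, so z
  profiles stay comparable.
* Iso tie rule: grid values exactly equal to the iso-value are inside.
* `channelToIntensity` of an all-constant map returns zeros (degenerate
  stretch); Reinhard normalization of a zero-variance channel returns the
  reference mean; background subtraction refuses images whose white point
  is near black.
* Component "diameter" in B-cell pruning is the approximate minimal
  bounding-sphere diameter (cells are spheroid); "main diagonal" in
  component removal is the bounding-box diagonal of the whole channel mesh
  in world µm.
* Distance thresholds compare strictly (`<`), matching "closer than".
* World coordinates: 0-based voxel indices, voxel centers at
  origin + (index + ½) · spacing; the section at index k has z = k ·
  thickness. Interpolation preserves world slice positions by adjusting
  the volume origin by (spacing_in − spacing_out)/2, and central crops
  advance the x/y origin, so meshes from any stage are in one consistent
  µm frame.
* One master seed fans out to per-stage seeds by a fixed derivation, so
  stages are independently reproducible.

## Known limitations

* Registration assumes rigid per-section motion; deformable artifacts
  (retrieval contraction, folds) are out of scope.
* The stain matrix is configured, never estimated from data; badly wrong
  vectors degrade unmixing silently.
* Flow interpolation is intensity-based; structures moving more than a few
  tube diameters per section blur toward their partial-volume footprint.
* Repair of radically open surfaces yields closed shells, not solids
  (capped at extraction instead).
* The CD20 channel keeps 14 µm z spacing; B-cell meshes are coarse in z by
  construction.
* Scoring requires ground truth; there is no unsupervised quality metric
  for real scanned series beyond registration residuals.
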