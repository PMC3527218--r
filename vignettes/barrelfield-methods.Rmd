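---
title: "Reconstructing and standardizing the rat barrel cortex: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and standardizing the rat barrel cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barrelfield)
```

## The problem

The rat vibrissal ("barrel") cortex contains one cytoarchitectonic unit —
a barrel in layer 4 — per large facial whisker, laid out somatotopically
in rows (A–E) and arcs (greek, 1–4). Single-neuron reconstructions from
*in vivo* experiments come in arbitrary, experiment-specific coordinate
frames; comparing or pooling them requires a common anatomical reference.
`barrelfield` implements the complete chain from raw tangential section
images to such a reference:

1. **Segmentation** of barrel outlines from high-resolution optical
   sections (Voronoi-confined region growing around manual seed points)
   and of pia / white matter (WM) outlines and blood vessels from
   low-resolution images.
2. **3D reconstruction** of each animal's barrel field: vessel-based
   section alignment, z-smoothing of contours, surface reconstruction
   from serial outlines, vessel-constrained estimation of each barrel
   column's vertical (BC) axis, and extraction of five parameters per
   column: barrel area, barrel top (BT) and bottom (BB) depth, column
   height (pia–WM distance) and column orientation.
3. **Standardization**: rigid generalized Procrustes registration (GPA) of
   many animals' BT/BB landmark sets, averaging into a standard model, and
   quantification of the residual across-animal variability.
4. **Layout parameterization**: three second-order polynomials mapping the
   discrete (Row, Arc) coordinates to 3D barrel-center positions.
5. **Morphometrics**: depth-resolved overlap of neighboring columns,
   voxelized column/septum volumes by cortical layer, tangential parameter
   gradients.
6. **Neuron registration**: a four-step procedure (global rigid
   registration, orientation refinement, landmark-depth correction,
   stepwise linear scaling) that places an SWC morphology into the
   standard model.

Every stage can be exercised without experimental data through the
synthetic-data module, which generates ground-truth barrel fields,
rendered image stacks and neurons under the cohort conditions of the
shipped parameter table.

## Coordinate conventions

All lengths are micrometers. The z axis increases towards the pia; depth
below the pia is positive and measured along the *local column axis*;
axis unit vectors point pia-ward. Volumes are converted to mm³ only on
output. The canonical analysis frame (`build_c2_frame`) has its origin at
the C2 barrel center, `ez` along the C2 column axis, `ex` towards the C3
barrel center (approximately along the whisker row) and `ey = ez × ex`
(approximately along the arc). Greek-arc barrels receive half-integer Row
coordinates (α = 0.5 … δ = 3.5, Arc 0); the exact half-integer values are a
convention (they interleave the greek barrels between the integer rows)
since only "half-integer" is prescribed.

## The synthetic cohort: what it emulates

`generate_barrel_field()` draws, per barrel and animal, the barrel area,
BT depth, barrel height and column height from per-label normal
distributions whose means and SDs are the shipped cohort table
(`barrel_parameters()`, mean ± SD over 12 animals). BB depth is BT depth
plus height, so the three depth quantities stay mutually consistent.
Barrel centers sit on a 450 µm row/arc lattice with 50 µm across-animal
lateral scatter.

The pia is modeled as the osculating quadratic dome with two curvature
radii whose principal directions lie along the two *diagonals* of the
map: 4 mm along the "3-2-1" diagonal (A4→B3→C2→D1→δ) and 12 mm along the
perpendicular "1-2-3" diagonal. Axis-aligned curvature cannot reproduce
the observed tilt anisotropy (≈17° at A4 versus ≈6° at E4 relative to
C2); the rotated-diagonal dome does, with both radii safely above the
cortex thickness. Column axes are local pia normals plus an across-animal
angular scatter of 3° (`axis_angle_sd`); combined with the ~1.4° of
rotational registration noise this reproduces an observed axis
variability of roughly 4–5°. Vessels descend perpendicular to the pia
with 2° angular noise. The WM surface is a smooth quadratic fit through
the per-column WM points.

Rendered stacks (`render_section_stack()`) show barrels as bright
ellipsoidal bodies (maximal cross-section equal to the drawn area)
against a darker septum, dark circular vessel cross-sections, and
additive Gaussian intensity noise (SD 0.05 on a 0–1 scale at a
barrel/septum contrast of 0.35). Default imaging geometry is 4 µm/px and
10 µm optical-section spacing. *Not* emulated: optics (point-spread
function, shading, depth attenuation), staining gradients, tissue
deformation and cutting artifacts. Passing tests on this material
therefore validates the geometry and statistics of the pipeline, not its
robustness to every imaging nuisance of real Cytochrome-oxidase material.

Synthetic neurons (`generate_neuron()`) are pyramidal (apical trunk along
the true local axis, tuft reaching the pia) or spiny stellate (descending
main axon). The scene is re-expressed in a cutting frame rotated by the
sectioning mismatch (drawn from the observed 14.0 ± 7.6°) and translated
randomly; landmarks carry the manual-tracing biases — principal-column
BT/BB/WM shifted by the per-column manual-minus-standard offsets
(published only for D2: +68, +59, −7 µm), the traced pia 39 µm above the
true pia (tuft-to-pia calibration) plus 20 µm first-section thickness
error — and isotropic 15 µm landmark noise, a typical manual tracing
precision. The recorded pipette depth deviates from the true soma depth
by −46 ± 102 µm.

## Numerical and algorithmic choices

**Image filtering.** `preprocess_barrel_image()` uses a small median
filter (impulse noise), a grayscale closing at the vessel scale (removes
dark vessel cross-sections), an optional 15×15 local-mean smoothing, and
an affine rescale. This preserves barrel/septum contrast monotonically.
`preprocess_stack()` rescales with the global stack range so signal-free
sections are not stretched into fake contrast.

**Segmentation gates.** Within each seed's Voronoi region an Otsu
threshold separates barrel from septum; the component at the seed is kept
and closed (radius 4 px). A section yields no contour unless (i) Otsu's
class separability (between-class / total variance) exceeds 0.75 — pure
Gaussian noise reaches only ≈0.64, so this gate is scale-free — (ii) the
interior/exterior mean ratio exceeds 1.10 and their difference 0.12, and
(iii) the mask covers between 25 px and half the Voronoi region. Contours
are traced through boundary pixel centers and expanded radially by half a
pixel (center-tracing otherwise bites half a pixel of area).

**Vertical extent.** The equivalent-diameter profile d(z) is smoothed
with a centered 3-point moving average; BT is the shallowest plateau-aware
local minimum above the global maximum, BB the deepest below it, with the
plateau section closest to the maximum chosen (conservative extent).
Profiles without interior minima fall back to the endpoint sections with
a low-confidence flag. On 50 simulated single-barrel stacks at 10 µm
optical spacing the mean absolute BT/BB error is below 10 µm, dominated
by section quantization plus the conservative one-section bias at the
caps.

**Surfaces.** `build_surface()` rasterizes each closed outline to a
signed 2D distance map on a 10 µm grid, interpolates maps linearly
between sections, extracts the zero level set of every level
(`contourLines` pieces pooled and resampled at 48 polar angles) and
triangulates consecutive rings. Analytic cylinders and cones are
reproduced to well under one grid cell.

**Column axes.** Candidate axes run from the barrel center to every pia
triangle centroid within 2 mm; the score is
`cos(perpendicularity angle) / (length / min length)` — monotone in both
stated criteria and dimensionless. Among candidates parallel (default 5°)
to the mean orientation of the vessels around the barrel (polylines
passing within the maximal circumference + 200 µm), the best-scoring one
wins; without such a candidate the overall best is used and flagged. The
winning direction is refined below mesh resolution by rescoring
barycentric sub-centroids of the top candidate triangles, giving ≈0.5–1°
accuracy on meshes with 100–150 µm edges. Vessels tilted more than 10°
against the pia normal are discarded beforehand.

**GPA.** Landmarks are the BT and BB points of all barrels; missing
barrels participate only in the correspondences they have. Translations
align centroids; rotations come from the SVD of the cross-covariance,
with the reflection case corrected by flipping the smallest singular
vector. Iteration stops when the maximum point displacement falls below
1 µm (typically after one or two iterations). No scaling is permitted
anywhere. The standard model is re-expressed in its own C2 frame, making
it independent of the arbitrary registration pose; the transform is kept
so that variability can be evaluated in the model frame.

**Variability attribution.** Per label, the covariance of aligned BT (and
BB) positions is diagonalized; each eigen-SD is attributed to the frame
direction (row / arc / axis) its eigenvector is most parallel to,
processed in order of decreasing eigenvalue. With only 12 animals the
sample eigenvalues of isotropic scatter spread apart (largest biased up,
smallest down); recovery tests therefore compare direction-averaged
eigen-SDs, which are unbiased enough for a 20 % check.

**Layout fit.** Ordinary (unweighted) least squares of each BC coordinate
on (1, Row, Arc, Row², Row·Arc, Arc²); 18 coefficients of which the 3
constants are excluded from comparisons, leaving the 15 informative ones.
Leave-one-out prediction uses the average of the other animals'
coefficients; the C2 per-barrel RMSE is reported as the mean of C1 and C3
because C2 anchors the frame. The reported RMSE is the root mean squared
*3D distance*, which for isotropic noise is √3 times the per-direction
SD — consistent with the printed RMSE-to-SD ratios.

**Overlap and voxels.** Overlap uses a deterministic stratified grid
(default 5 µm) inside the central cylinder, in 50 µm depth bins along its
axis — reproducible, and within 1 % of a seeded Monte-Carlo volume oracle
on analytic two-cylinder configurations. Voxelization uses 10 µm voxels
between the pia and WM height fields; a voxel inside several extrapolated
cylinders is counted once (flagged), so column + septum volumes conserve
the total exactly on the grid. Layer boundaries are each column's own
BT/BB depths; septum voxels interpolate BT/BB from the three laterally
nearest columns (inverse-distance) and measure depth vertically below the
local pia — at tilts ≤17° the difference to axis-parallel depth is ≤2 %
and spatially smooth. Tests use single- or few-column fields so the
default resolutions stay fast; the acceptance checks run the overlap
oracle at the default 5 µm grid and voxel checks at 5–10 µm.

**Neuron registration.** Step 1 matches the traced principal BC exactly
and rotates about it (constrained Kabsch) — the principal-column residual
is zero by construction. Step 2 computes the smallest-inertia axis of the
apical dendrite from length-weighted segment midpoints (sampling-density
independent); stellate cells fall back to the main axon provided it
leaves the soma within 30° of the local axis. Step 3 subtracts the
per-column manual-minus-standard offsets (editable CSV; published values
for D2, zeros elsewhere) and the 39 + 20 µm pia corrections. Step 4
scales only the axial coordinate piecewise-linearly between (pia, BT, BB,
WM), continuous at the knots, extended with the boundary factors beyond
pia and WM. The deviation reported for recording depths is
`recording − registered`. End-to-end, somata of synthetic neurons land
within ~25 µm (mean) of their true positions at default landmark noise,
dominated by the tracing noise of the principal BC.

## Problem sizes used in validation

The test and acceptance suites simulate 12 fields (full cohort pipeline),
50 single-barrel image stacks (BT/BB detection bias), 12 neurons
(end-to-end registration), 30 neurons (cutting-angle statistics), 25
neurons (recording-depth bias), and two-cylinder overlap oracles at
4×10⁵ Monte-Carlo samples per bin across several bins. These sizes make
the statistical checks sharp at the tolerances used while keeping the
default suite run in a few minutes.

## Known limitations

* The segmentation is tuned on synthetic contrast statistics; real
  Cytochrome-oxidase material will need threshold calibration
  (`min_separability`, `min_ratio`, `min_contrast` are exposed).
* The image pipeline assumes in-plane-aligned stacks with known pixel
  size; nonrigid section unwarping is out of scope, as is any nonrigid
  averaging of label fields for the standard model.
* Per-column landmark-depth offsets are published for D2 only; other
  columns default to zero until calibrated on a user's own cohort.
* The cylindrical column model is the only one implemented; anisotropic
  or projection-defined columns are not.
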