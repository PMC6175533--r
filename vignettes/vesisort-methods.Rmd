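---
title: "vesisort: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vesisort: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesisort)
```

This vignette documents the scientific model behind `vesisort`, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic phantoms can and cannot tell you
about real electron tomograms.

## The problem and the pipeline

Electron tomograms of synaptic boutons show two vesicle populations:
clear-core vesicles (CCVs) — small spheres whose stained membrane encloses
an electron-lucent lumen — and dense-core vesicles (DCVs), larger spheres
filled with electron-dense material. The pipeline turns a raw gray-value
stack plus one user-supplied active-zone (AZ) point into a per-vesicle
feature table, a CCV/DCV call per vesicle, and pool-level statistics.

Segmentation follows a registration-style workflow: the stack is rescaled
to 1 nm/px in x/y (bilinear; z untouched so no interpolated slices are
invented), contrast-stretched to an 8-bit working range, smoothed with a
circular mean filter (radius 3.45 px) and an edge-preserving bilateral
filter, thresholded per slice at the slice's mean brightness (stained
structures are dark, i.e. below the mean), hole-filled per slice so lumina
become solid, split by a per-slice 2D watershed followed by a 3D watershed
seeded from the Gaussian-smoothed (sigma 3.45 voxels) 3D Euclidean distance
transform, and finally filtered by particle shape.

Features are then measured **on the scaled duplicate of the original
stack**, not on the filtered copy: the filters exist to stabilize
thresholding and would flatten exactly the membrane/lumen contrast that the
gray-value features quantify.

## The four features

* **r** — inner radius: the vesicle mask is eroded by the membrane
  thickness (4.5 nm per side, consistent with the +9 nm outer-diameter
  correction), and r is the mean Euclidean distance from the eroded
  region's centroid to its surface voxels, in nm.
* **gv** — mean gray value over the eroded 3D region, in display polarity
  (electron-dense = dark = low). CCV lumina are bright, so CCVs have the
  *higher* gv.
* **GVSD** — sample standard deviation (n − 1) of gray values over the
  full, non-eroded footprint on the z-slice through the vesicle centroid,
  computed on a slice-wise Gaussian-blurred copy (sigma 3.45 px) so dark
  membrane pixels spread into the footprint. CCVs (shell + lumen contrast)
  score high, DCVs (uniform core) low.
* **distAZ** — 3D Euclidean distance (nm) from the vesicle centroid (full
  mask, intensity-unweighted) to the AZ point, honoring anisotropic voxel
  spacing.

## The shipped classifier and its sign conventions

The default model standardizes `(r, gv, distAZ, GVSD)` with means
(10.4, 129.1, 259.1, 5.9) and SDs (3.1, 4.7, 118.5, 1.7) and applies the
hyperplane

$$ m \;=\; -1.69\,z_r + 1.65\,z_{gv} - 0.76\,z_{distAZ} + 1.21\,z_{GVSD}
\;+\; 4.36, $$

assigning CCV when $m \ge 0$. Three conventions deserve explicit
statement:

* **Intercept.** The hyperplane constant is folded into the margin, so
  $m = 0$ lies exactly on the published decision boundary and the all-means
  feature vector has margin $+4.36$ (CCV).
* **Ties.** $m = 0$ goes to CCV, the majority class under the roughly 9:1
  pool imbalance — the choice that minimizes expected error.
* **gv polarity.** The weight signs are only mutually consistent if gv is
  measured in display polarity: DCVs are *larger* (negative r weight),
  *further from the AZ* (negative distAZ weight), *flatter in contrast*
  (positive GVSD weight rewards CCVs) — and *darker*, so a positive gv
  weight must reward the bright CCV lumen, i.e. dark = numerically low.
  We verified this empirically: retraining a linear SVM on synthetic
  tables reproduces the (−, +, −, +) sign pattern only under display
  polarity. `feature_params(gv_polarity = "invert")` is available for
  stacks stored with the opposite orientation.

Brightness transfer between tomograms is handled by the optional gv
offset: if the darkest vesicle of a tomogram is lighter than a configured
reference level, all gv values are shifted so that vesicle lands on the
reference. The offset is disabled (`NA`) by default because the reference
level is dataset-specific; it exists for transferring the classifier to
differently exposed material.

## Retraining and evaluation

`train_classifier()` supports a linear SVM (cost C = 1 by default), an RBF
SVM, a random forest (bootstrap resamples of the training-set size,
probability-weighted voting; 10 or 1500 trees are the reference settings)
and KNN (k = 10, uniform weights, Euclidean metric). Labels follow the
training-file convention: `D` → −1, `E` rows dropped, everything else
(`C` and `N`) → +1, because non-determinable vesicles resemble CCVs.

Evaluation is leave-one-file-out: each tomogram's table is held out once,
standardization constants come from the training folds only, and the
report aggregates accuracy, precision, recall and F-score (dense-core
positive) as mean ± sample SD over folds. Folds whose validation file
contains no DCVs leave precision/recall/F undefined; these are excluded
from the averages (setting them to 0 or 1 would bias the summary for
DCV-free tomograms) and listed in the printout. For a linear SVM the
fitted hyperplane is exportable as a standalone model
(`export_linear_model()`), and a cross-module test pins the exported
model's predictions to the trainer's.

## The phantom generator

`phantom_spec()` describes a synthetic bouton tomogram:

| parameter | default | meaning |
|---|---|---|
| shape, spacing | 320 × 320 × 100 vox at (1, 1, 2) nm | field of a typical NMJ tomogram |
| n_vesicles | 100 | pool size of a typical bouton |
| dcv_fraction | 0.13 | pooled DCV abundance |
| ccv_radius | N(9.6, 1.5) nm | clear-core inner radii (medians 9–10 nm) |
| dcv_radius | N(15.7, 2.2) nm | dense-core inner radii (medians 15–17 nm) |
| membrane_nm | 4.5 | one membrane side; outer diameter = 2r + 9 |
| gray | bg 110, lumen 140, membrane 40, core 50 | display polarity; lumina brighter than cytoplasm |
| bouton_radius_nm | 45% of the in-plane extent | dark plasma-membrane shell around the pool |
| dcv_distance_bias | 2 | DCV centres accepted with prob. (d/dmax)² |
| noise_sd | 0 | additive Gaussian noise |

Rendering details that matter for realism: the bouton membrane is a
cylindrical shell with an angular gap (real sections never show a closed
ring; a closed ring would also be filled solid by per-slice hole filling),
the AZ point sits on that membrane, vesicles keep a 6 nm clearance from
the stack border, and placement is rejection-sampled with a retry cap so
overlaps are impossible by construction. The class mixture of the
per-class feature sampler (`sample_feature_table()`) was chosen so the
pooled moments reproduce the shipped model's standardization constants
while the class separations echo the reported medians.

What the phantoms do **not** emulate: tomographic reconstruction physics
(missing wedge, ray artifacts — only an optional z-blur approximates
elongation), membrane deformation or non-spherical vesicles, organelles
and cytoskeleton clutter, and spatially varying stain. Passing tests on
phantoms therefore demonstrate the correctness of the algorithms under
controlled geometry and contrast, not field performance on arbitrary real
tomograms; intensity-scale adaptation (the gv offset, or retraining) is
expected when moving to differently contrasted material.

## Particle filter

Candidates must satisfy: volume within [300, 300 000] nm³ (the upper bound
admits an 80 nm-diameter dense-core vesicle), sphericity
$\psi = \pi^{1/3}(6V)^{2/3}/A \ge 0.8$, moment-matched-ellipsoid residual
(symmetric-difference fraction) ≤ 0.15, and no contact with the stack
border (truncated vesicles and structures leaving the field, such as the
plasma membrane, are not usable candidates). The surface area $A$ counts
boundary faces corrected by the Cauchy factor 2/3, which removes the ~1.5×
voxelization bias for curved surfaces: a digital ball then scores
$\psi \approx 1$ while a 3×3×40 rod scores ≈ 0.49 with face counting exact
for boxes. On phantoms, genuine vesicles score residuals around 0.02 and
membrane fragments ≥ 0.24, so the 0.15 bound separates them with a wide
margin. All thresholds are config-exposed
(`particle_criteria()`, `inst/extdata/defaults.yaml`).

## Numerical choices

* **Distance transform.** Exact separable (lower-envelope) squared EDT
  with anisotropic physical spacing, implemented in C++; infinities are
  replaced by a large finite sentinel because envelope intersections of
  two infinite parabolas are undefined.
* **Watershed.** Priority-flood from plateau-aware regional maxima of the
  smoothed distance map; 26-connectivity in 3D, 8 in 2D; ties on equal
  priority are broken by FIFO insertion order, making label maps fully
  deterministic.
* **Erosion depth.** The EDT measures distance to background voxel
  *centres*, about half a voxel beyond the true surface; membrane
  exclusion therefore erodes to `membrane_nm + 0.5·min(spacing)`.
* **Degenerate inputs.** Essentially constant slices yield empty
  foreground (guarding against float ripple from the filters);
  zero-variance stacks make the contrast stretch an identity; erosion that
  empties a region falls back to the full mask and flags the record;
  single-voxel GVSD footprints return 0, flagged.
* **Rounding.** Scaled dimensions round half to even; reported
  percentages round half away from zero at the requested precision.
* **Determinism.** Every stochastic step (phantom placement, noise, RF
  bootstrap) consumes an explicit seed; reruns of the pipeline with equal
  seeds are byte-identical on all CSV outputs.

## Statistics

Group comparisons use the two-sided Mann-Whitney U test (exact null for
groups of ≤ 8 without ties, otherwise the tie-corrected normal
approximation), with significance stars at 0.05/0.01/0.001 and no
multiple-testing correction by default (a Bonferroni flag exists). gv and
distAZ are min–max normalized per tomogram before pooling, which removes
brightness and cell-size differences between tomograms but also makes the
normalized values sensitive to single extreme vesicles; radii are compared
in nm. Distance distributions are summarized by the empirical CDF and a
Gaussian KDE whose bandwidth is 0.07 × the data maximum — a rule that ties
smoothing to the pool extent and is reproduced here verbatim as the
default.

## Problem sizes used in the validation suite

The test suite and the acceptance script run entirely on generated data:
recovery checks use a 280 × 280 × 140 nm bouton phantom with 20
well-separated vesicles (≥ 12 nm surface gaps), noiseless and at a noise
SD of 10 gray levels (10% of the membrane/lumen contrast); end-to-end
determinism uses an 8-vesicle 200 × 200 × 100 nm phantom;
cross-validation uses 15 synthetic tables of 133 vesicles each. These
sizes exercise every code path while keeping a full run in the
single-digit minutes on one CPU.

## Known limitations

* The per-slice mean-brightness threshold assumes a substantial dark
  content per slice; on nearly empty fields it dilates masks (the halo of
  the mean filter falls below threshold). Real bouton tomograms and the
  default phantoms provide that content; extremely sparse fields would
  need a different threshold rule.
* The inner radius inherits a small positive bias (≲ 1 nm at 1 nm/px)
  from threshold-side mask dilation; the erosion-depth correction removes
  the discretization half of it.
* The shipped classifier's standardization constants are tied to the
  intensity scale of its training material; on material with a different
  gray-value distribution use the gv offset or retrain.
* `cell_volume()` integrates user-supplied closed outlines; it does not
  segment the cell boundary itself.
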