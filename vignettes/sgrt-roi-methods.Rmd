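---
title: "Automated ROI construction for breast SGRT: models and methods"
author: "sgroi package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated ROI construction for breast SGRT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgroi)
```

## The problem

Surface-guided radiotherapy (SGRT) monitors patient position during
whole-breast treatment by rigidly registering a live optical surface to a
reference surface inside a region of interest (ROI). That ROI is drawn by
hand today: it should cover the stable chest wall, stay off the mobile
arm/armpit region, and extend far enough superiorly and inferiorly to give
the registration traction. `sgroi` implements two automated constructions of
this coronal-plane ROI:

* **Body-contour-based** (`generateAroiBody`): the superior boundary is set
  from the two collar-bone joints and the inferior boundary from the
  mid-spine (Spine2) joint, with tunable shifts. Joints are predicted from a
  coronal silhouette image by a small regression network trained entirely on
  synthetic human bodies.
* **Breast-contour-based** (`generateAroiBreast`): the superior/inferior
  boundaries are set from the delineated ipsilateral breast's
  superior-inferior (S-I) extent, with per-category extensions.

Both share the remaining steps: the chest width is measured on the body
silhouette at the row midway between the two boundaries; the ROI spans 3/4
of that width, anchored at the ipsilateral silhouette edge; and the
ipsilateral-superior corner is chamfered by 80 mm along both edges to
exclude the armpit.

## Coordinate conventions

Patient frame: x = patient-left positive, y = anterior positive,
z = superior positive, all in mm. Rasters are stored with row 1 most
superior and column 1 most patient-right (the radiographic front view), and
each image records the patient (x, z) of the center of pixel [1, 1]. Under
this convention the patient's *left* collar projects to the *larger* column
index.

## Construction parameters

All tunables live in one `ShiftConfig` object; the defaults are the method's
working constants.

| parameter | default | meaning |
|---|---|---|
| `upperShiftMm` | 10 | superior extension above the mean collar-joint z |
| `lowerShiftMm` | 30 | inferior extension below the Spine2 z |
| `lrFraction` | 0.75 | lateral span as a fraction of chest width |
| `retractionMm` | 80 | chamfer distance at the ipsilateral-superior corner |
| `breastEvalSupMm` / `breastEvalInfMm` | 27 / 12 | extensions from a breast-only contour |
| `ptvSupMm` / `ptvInfMm` | -24 / 17 | extensions from a PTV contour |

The negative PTV superior extension means the ROI's upper boundary sits
*inferior* of the contour's superior boundary: nodal PTVs reach well above
the stable chest-wall region the ROI should cover. The 10/30 mm joint shifts
are not hard-coded into the algorithm; `tuneShifts` re-derives them by grid
search (0-45 mm in 5 mm steps, both boundaries jointly) maximizing the mean
Dice similarity coefficient (DSC) against reference ROIs. The joint 2-D
sweep contains the two 1-D sweeps as slices, so it is the more general
reading of the tuning procedure; ties break toward the smaller
(upper, lower) pair.

## The synthetic body and what it does (not) emulate

No clinical data ship with the package. The training and evaluation inputs
come from a procedural parametric body: stacked elliptical cross-sections
for torso, neck, head and legs, plus round tubes for the arms, posed
arms-raised (upper arm ~40 degrees from vertical, forearm folded in over
the head - the deep-inspiration breath-hold setup posture). Joints sit at
fixed anatomical fractions of the template stature; four shape scales
(torso width/depth, shoulder width, limb length) are drawn uniformly from
[0.8, 1.2], spanning roughly the anthropometric spread of a breast
radiotherapy cohort (statures 149-161 cm are sampled in the synthetic
cohort). `heightMm` is defined as the S-I vertex extent of the posed mesh
and `scaleToHeight` rescales isotropically; the working height default is
1617 mm, the average US adult female stature.

What this emulates well: coronal silhouette topology, the relative joint
geometry that drives the crop and the ROI construction, and body-size
variation. What it does not emulate: soft-tissue deformation, breast shape
asymmetry, CT couch/arm artifacts, garment edges, or surface noise from the
optical camera. Tests passing on these fixtures therefore validate the
*geometry and learning machinery*, not clinical-image realism; absolute
joint-error magnitudes on real patients will differ.

Images are orthographic coronal projections where each silhouette pixel
encodes the normalized anterior depth of the frontmost surface (background
exactly 0, body in (0, 1]). The torso crop draws its upper boundary
uniformly between the Nose and Head joint rows and its lower boundary
uniformly between the Spine2 and Spine1 rows, emulating the scan range of a
breast CT; the window is squared laterally about the silhouette midline
(so pixels stay isotropic rather than stretching the crop - a divergence
risk when comparing absolute pixel errors against other implementations)
and resampled bilinearly to 200 x 200. A crop that would exclude a target
joint is redrawn (at most 10 times). The reference dataset is 3000 images
split 85:15 into training and validation by a seeded shuffle.

## The joint regressor

The backbone is deliberately pluggable and small. The default
(`backbone = "pool_mlp"`) average-pools the image into a 20 x 20 patch grid,
standardizes each pooled feature with train-split statistics (per-feature
scale floored at 10% of the median scale, so near-constant background
patches cannot blow up), and regresses the six outputs - (row, col) for
LeftCollar, RightCollar, Spine2, in coordinates normalized to [0, 1] -
through one hidden ReLU layer (64 units). Training minimizes the MSE with
Adam (default step 1e-3, batch 32), a cosine step-size decay to zero over
the epoch budget, and global gradient-norm clipping at 5; the stopping rule
is a fixed epoch count (reference schedule 2000 epochs; the test
configuration uses 200). Dropout is implemented but defaults to 0: at these
widths the pooled-feature MLP underfits rather than overfits, and dropout
only slows convergence. Everything is seeded - weight initialization,
epoch shuffles, dropout masks - so training is bit-reproducible on a single
thread.

The cosine decay and clipping are not cosmetic: with a constant step size
the optimizer occasionally destabilizes in the last epochs after having
converged, which is exactly the failure mode a fixed-epoch stopping rule
cannot absorb.

Accuracy is reported as the mean per-joint position error (MPJPE), the
Euclidean distance between predicted and true joints converted to mm via
the pixel spacing. Because published summaries are sometimes quoted per
axis, `mpjpe()` also reports the mean and sd of the absolute S-I (row) and
L-R (column) coordinate errors separately; the Euclidean mean always
dominates either per-axis mean.

The learning sanity check uses a constructed toy set: a Gaussian dot whose
position determines all three labels through fixed affine maps. Any
functioning regressor must drive validation MPJPE below 2 px there; the
default backbone reaches ~0.3-0.7 px in 200 epochs on 1000 samples across
seeds. This validates the training loop, not breast anatomy.

## Geometry details and numerical choices

* **Chest width** is the lateral extent (outer pixel edges) of the
  silhouette at the midline row; on contiguous rows this equals pixel count
  times spacing.
* **Laterality** is handled by sign-symmetric formulas (the ipsilateral
  edge is the +x silhouette edge for left-sided, -x for right-sided
  patients). Because mirroring is pure negation, laterality-flipped inputs
  produce exactly mirrored polygons, which the tests assert bit-exactly.
* **Chamfer** (corner curation): a straight cut between the two points
  80 mm along the superior and ipsilateral edges, removing a right triangle
  (area retraction^2/2). A straight chamfer rather than a rectangular notch:
  a notch would reintroduce a concave corner near the armpit. A rounded
  curve would be a plausible alternative; the chamfer was chosen as the
  simplest shape with the intended effect. If the retraction exceeds either
  edge, the construction falls back to the plain rectangle with a warning.
* **Rasterization** uses the even-odd rule on pixel centers with boundary
  points counted inside. The closed rule matters: it is mirror-symmetric,
  so the laterality property above survives rasterization even when an edge
  lies exactly on a pixel-center line. Mask area times pixel area converges
  to the polygon's shoelace area as spacing shrinks.
* **DSC** comparisons run on a common 1 mm/px grid covering the union
  bounding box; sub-millimeter differences are below clinical relevance.
  Two empty masks are defined as DSC 1 (with a warning) so degenerate
  comparisons fail loudly but consistently.
* **Degenerate inputs** raise classed conditions
  (`sgroi_invalid_input`, `sgroi_degenerate_geometry`), which the CLI maps
  to exit codes 2 and 3.

## The synthetic cohort

`makeCohort` builds complete evaluation cases: body, silhouette,
ground-truth joints, breast contour, and a *pseudo-clinical* ROI. The
pseudo-clinical ROI is the construction at the true shifts with independent
Gaussian jitter applied to each of its four boundary positions, mimicking
inter-planner variability (planners eyeball distances; they do not use a
ruler). The breast contour is placed consistently with the per-category
extension constants - its superior boundary sits exactly 27 mm (breast-only)
or -24 mm (PTV) below/above the true ROI's upper boundary, and likewise
inferiorly - so a single cohort supports both the shift-tuning recovery and
the boundary-distance round-trip exactly at zero noise. Category mix
defaults to 30:9 (breast-only : PTV), the proportions of the cohort the
method was developed on; tuning uses 24 cases.

With zero noise, `tuneShifts` must recover (10, 30) exactly and
`meanBoundaryDistance` must return (27, 12) and (-24, 17) with signs; with
5 mm boundary jitter the tuned optimum stays within one 5 mm grid step.
These are the package's acceptance properties; the clinical endpoints of
the underlying study (DSC against hand-drawn ROIs, expert ratings) require
real patients and are out of scope.

## Problem sizes used by the test suite and acceptance script

The suite regenerates everything from code: the full 3000-image dataset
(about two minutes), 24-patient tuning cohorts at 1 mm DSC grids, 100
random polygon pairs for the Dice oracle, and the 1000-sample toy
regression. The acceptance script (`scripts/acceptance.R`) recomputes the
same quantities from scratch under a caller-supplied seed.

## Known limitations

* The body model is procedural; its silhouettes are smooth and symmetric
  compared to real patients, so real-world MPJPE will be larger than the
  synthetic validation error.
* The breast-contour input accepts the package's JSON dialect (explicit S-I
  extent or a 3-D point list); DICOM-RT structure sets must be converted
  upstream.
* The ROI is constructed and evaluated in the 2-D coronal plane; lifting it
  onto the 3-D camera surface is vendor-side functionality.
* `chestWidth` measures the full lateral extent at the midline row; a
  silhouette with severe concavities at that row (e.g., arms crossing the
  midline band) would inflate the width estimate.
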