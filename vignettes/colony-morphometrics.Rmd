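---
title: "Quantifying macrocolony deformation under one-sided antimicrobial exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying macrocolony deformation under one-sided antimicrobial exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonymorph)
```

## The measurement problem

A bacterial macrocolony growing on agar next to an antimicrobial droplet
does not stop growing — it grows *asymmetrically*. The side facing the
source (the **exposed** half) expands less and fluoresces less than the
side facing away (the **unexposed** half). `colonymorph` turns top-down,
single-channel fluorescence images of such colonies into a handful of
per-colony scalars that capture this asymmetry, and compares treatment
groups (source at different distances) against unexposed controls.

The pipeline has four measuring stages, each usable on its own:

1. **Segmentation** — colony periphery and core contours from the image.
2. **Deformation morphometrics** — mirrored-half ellipse ratios.
3. **Intensity analysis** — exposed/unexposed mean-intensity ratios and
   the leading-edge intensity-versus-distance regression.
4. **Group statistics** — two-sided Student's *t*-tests of every treated
   group against control, per metric and day.

All coordinates are 1-based `(row, col)` pixel centers, origin top-left —
the natural indexing of an R matrix.

## Segmentation

The image (intensities normalized to $[0,1]$) is eroded with a flat
$5\times5$ structuring element (each pixel replaced by the window minimum,
borders replicated), thresholded with Otsu's method on a 256-bin histogram
(the threshold $t^*$ maximizes the between-class variance
$\omega_0\omega_1(\mu_0-\mu_1)^2$), and binarized with `intensity > t*`.
Contours are then extracted by Moore border following, *including hole
boundaries*: in a mature colony the core region binarizes differently from
the surrounding periphery lawn, so the core boundary appears as an interior
transition in the mask. Contours are ranked by enclosed pixel area; the
largest is the **periphery**, the second largest is the **core**.

Two numerical choices matter here:

* **Erosion-bias compensation.** A windowed minimum shifts every
  bright-to-dark boundary inward by half the kernel, i.e. 2 px at the
  default kernel. At a colony radius of ~110 px that alone biases the
  enclosed area by ~4% and the core hole by ~8% — more than the effect
  sizes of interest. The binary mask is therefore dilated with the same
  element after thresholding (the pair acts as a morphological opening):
  speckle suppression is kept, and on clean step edges the boundary shift
  cancels exactly. Disable with `segment_colony(..., compensate = FALSE)`.
* **Core gates.** The second-largest contour is accepted as the core only
  if its centroid lies inside the periphery polygon and its area is between
  1% and 90% of the periphery's (both configurable). This keeps dust,
  reflections and plate edges from being mislabeled as the core; a colony
  without interior structure simply reports no core.

## Deformation morphometrics

The separating line passes through the colony *seeding point* (from the
layout file, not the fitted shape center), perpendicular to the
center-to-source direction; for controls it defaults to the image-vertical
line. Each contour is split at the line, each half is mirrored across it
(producing a closed, line-symmetric contour), and each mirrored contour is
fitted to an ellipse by the direct least-squares conic fit constrained to
an ellipse (the numerically stable partitioned formulation, with centered
and scaled coordinates).

The reported quantities are the unexposed/exposed ratios of ellipse
*extents*:

$$\text{horiz\_ratio} = \frac{w_u(\hat{n})}{w_e(\hat{n})}, \qquad
  \text{vert\_ratio} = \frac{w_u(\hat{t})}{w_e(\hat{t})},$$

where $w(\hat{d}) = \sqrt{a^2\cos^2\alpha + b^2\sin^2\alpha}$ is the
ellipse half-width along direction $\hat{d}$ ($\alpha$ the angle between
$\hat{d}$ and the major axis), $\hat{n}$ the center-to-source axis and
$\hat{t}$ its perpendicular. Using axis-projected extents rather than the
raw semi-axes makes the measure exact for rotated fits and generalizes to
off-axis source placements; for axis-aligned fits the two definitions
coincide. The numerator order is chosen so that **inhibition on the
exposed side gives ratios above 1**; a line-symmetric colony gives exactly
1.

## Intensity analysis

For intensity purposes the "periphery" is the annulus
$\text{periphery} \setminus \text{core}$, so the two regions are disjoint.
Each region is split by the separating line and the exposed/unexposed
ratio of mean intensities is reported. Controls have no preferred axis, so
their ratio is augmented: the half-vs-half ratio is computed under three
partitions about the seeding point — left/right, top/bottom, and
upper-left + bottom-right vs upper-right + bottom-left — and the
arithmetic mean of the three is reported (the caption-level definition
does not fix the mean type; the arithmetic mean is used and documented).

The **leading edge** is the outermost band of the periphery on the exposed
side: pixels whose Euclidean distance transform to the colony exterior is
at most the band width (20 px by default), intersected with the exposed
half-plane, with core pixels excluded — in strongly deformed colonies the
core can come within a band width of the rim, and a periphery measurement
must not average core intensities. Over the band pixels, ordinary
least-squares regression of intensity on Euclidean distance from the
source gives the slope (intensity per pixel of distance), intercept and
$R^2$. Distances are in pixels; multiply by the pixel size for physical
units. Fits are per colony; aggregation happens at the statistics layer.

## Group statistics

Every non-control group is compared to control within each (metric, day)
cell with the classic pooled-variance two-sided Student's *t*-test
(`welch = TRUE` switches to the unequal-variance variant). Group sizes may
be unbalanced. **No multiple-testing correction is applied** — each cell
is reported raw, and significance is called at $p < 0.05$; interpret
many-cell tables accordingly. Metric/day cells the control group cannot
supply (edge-regression metrics exist only for exposed colonies) are
skipped. Degenerate cells where both samples are constant and equal report
$t = 0, p = 1$; constant but different samples are an error rather than a
fake infinity.

## The synthetic colony generator

Real images of this kind are not redistributable, so the package ships a
forward model with exact ground truth; every quantitative claim in the
test suite is a recovery statement about it.

* **Footprint**: union of two half-ellipses sharing the vertical semi-axis
  $R_v$ — unexposed horizontal semi-axis $R_u$, exposed $R_e = f R_u$ with
  $f \le 1$ the asymmetry factor. The mirrored-half ellipse metric has the
  exact answer $R_u/R_e = 1/f$ on this family, which is why it was chosen.
* **Core**: a scaled copy (factor 0.45 by default), symmetric unless a
  core asymmetry factor is given. Its base intensity (0.18) is *below* the
  periphery lawn (0.72) on a 0.05 background, so after thresholding the
  core is an interior hole and the ranked-contour rule finds it — the
  configuration the segmentation stage is designed around.
* **Intensity gradient**: on colony pixels only,
  $g\,(d(p,\text{source}) - \bar d)$ with $\bar d$ the mean source
  distance over the footprint, emulating stronger inhibition (lower GFP
  signal) nearer the source. Centering keeps the region levels
  interpretable; the background is agar and carries no signal structure.
* **Noise**: i.i.d. Gaussian (sd 0.02 by default), clipped to $[0,1]$;
  levels are chosen so clipping is a tail event. Each image is
  deterministic given its seed, and cohort seeds derive from a master seed
  so cohorts rerun bit-identically.

The demo cohort (`study_cohort_specs()`) mirrors the study conditions:
group sizes 12/11/9/12 for sources at 1/1.5/2 cm and control, 20 µm/px
(so 1 cm = 500 px), colony semi-axes 110 px, asymmetry factors
0.60/0.75/0.90/1.0 and gradients $3\times10^{-4}$ / $1\times10^{-4}$ /
$3\times10^{-5}$ / 0 per pixel, chosen as a graded dose-response of the
kind the imaging shows. Per-colony biological variability is a 3%
log-normal jitter on the footprint semi-axes.

What the generator does **not** emulate: wrinkle texture, crescent
(concave) morphologies at very close source distances, agar artifacts,
uneven illumination, or any coupling between deformation and intensity
beyond the imposed gradient. Passing tests demonstrate that the *pipeline
arithmetic* is correct and well-calibrated, not that segmentation is
robust to every real-world imaging artifact.

## Problem sizes and tolerances used in the tests

Recovery tests run the default 320×320 geometry where precision is the
point (area recovery within 3%, asymmetry factors recovered within
±0.05 of $1/f$), and a half-resolution geometry (160×160, all lengths
halved) for cohort-level replications where sample counts matter more
than per-colony precision: 50 replicate cohorts of 12 treated vs 12
control colonies for the core-preservation check, 100 near/far colony
pairs for the slope-ordering check, and the 44-image demo cohort for the
end-to-end determinism check. Discretization bias grows as colonies
shrink — at half resolution the recovered ratio for $f = 0.5$ is biased
by about +0.024, at full resolution by +0.004 — which is why the
tight-tolerance tests use the full geometry.

On these synthetic cohorts the pipeline reproduces the two qualitative
findings it exists to measure: cohorts generated with an asymmetric
periphery and a symmetric core show significant treated-vs-control
deformation at the periphery and none at the core, and colonies generated
with a ten-fold weaker intensity gradient (emulating a farther source)
show correspondingly shallower leading-edge slopes.

## Known limitations

* One colony per image; no multi-colony scene splitting.
* ND2 microscope files are not read; convert to TIFF/PNG upstream.
* Pixel calibration (µm/px) must be supplied by the user; nothing in the
  image states it.
* Concave ("crescent") colonies violate the two-half-ellipse model; the
  ellipse fit will average away the concavity rather than flag it.
* Raw p-values only; with 10 metrics × 3 days × 3 groups a correction is
  advisable when screening rather than confirming.
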