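---
title: "Measuring and grading rice kernels from flatbed-scanner images"
author: "grainscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and grading rice kernels from flatbed-scanner images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainscan)
```

## The measurement problem

Commercial rice is priced on a handful of per-kernel traits: length and
width, the broken fraction (by weight, not by count), yellowing, chalkiness,
insect/heat damage, and residual unhulled (paddy) kernels. Manual grading
with calipers and visual sorting is slow and inconsistent. A flatbed scanner
gives a flat, evenly lit, geometrically stable image of a sample spread in a
single layer under a black cover sheet - ideal conditions for image
analysis.

grainscan turns one such scan into a per-kernel assessment table and a
sample-level quality report. Every stage is testable against a synthetic
scene generator that renders scanner-like images with exact ground truth.

## Calibration: pixels per metric

All physical measurements hang off one scale factor, the pixels-per-mm
(ppm) of the scanner setup:

$$\mathrm{ppm} = \frac{\text{reference object width (px)}}{\text{known width (mm)}}$$

A circular reference disk of known diameter (conventionally a 22.5 mm coin)
is placed near the left edge of the bed. `detect_reference_disk()` finds
the most circular bright object in the left quarter of the image
(circularity $4\pi A / P^2 \ge 0.8$ by default; an elongated rice kernel
sits near 0.65, a rasterised disk above 0.9) and measures its Feret
diameter. A manual ppm override exists because production lines re-calibrate
rarely. Scan resolution is treated as free - the package calibrates per
image and never parses DPI metadata.

The disk is binarised with plain Otsu thresholding, *without* the
hysteresis growth used for kernels (below): growth would add the blur halo
to a shape whose exact diameter is the whole point.

## Segmentation and morphometry

The measurement chain is: luminance grayscale → Gaussian smoothing (kernel
size 7 px by default, $\sigma$ from the usual size heuristic) → binary
threshold → connected components → per-component boundary contour →
minimum-area rotated rectangle → the Euclidean distances between midpoints
of opposite rectangle edges, divided by ppm. The larger distance is the
kernel length, the smaller its width. A Sobel-magnitude edge map with
double-threshold hysteresis is retained for diagnostics, but contours are
traced on the threshold mask - with bright convex kernels on a black sheet
the mask boundary and the edge map coincide, and the mask gives closed
regions for free.

Two numerical details matter at this image scale (a long-grain kernel is
only ~80 × 25 px at 12.5 px/mm):

* **Intensity hysteresis.** Otsu's threshold separates the bright kernel
  mode from the dark background mode, but a heat-damaged kernel end can be
  darker than that global split while remaining far brighter than the black
  sheet. Components are therefore seeded at the Otsu threshold and grown
  down to 0.4× it (`hysteresis_ratio`), keeping partially darkened kernels
  in one piece. Set the ratio to 1 to disable.
* **Subpixel refinement.** A rectangle fitted to pixel-centre boundary
  points is quantised to roughly one pixel, which is 4% of a kernel width,
  and the quantisation error depends on how the kernel happens to align
  with the raster. `measure_kernel()` therefore uses the rectangle only to
  fix the kernel's centre and axes, then re-measures each dimension as the
  integral of edge *coverage* along the midpoint-connecting chord. Coverage
  is 1 on interior pixels (the mask eroded by 2 px, inside any blur/
  hysteresis halo) and, in the boundary band, the gray level normalised
  between the local background and the nearest interior brightness. Local
  normalisation is what keeps a dark damage patch from biasing its own edge
  position. For a capsule-shaped kernel the chord through the centre equals
  the true length/width exactly, so this estimator is unbiased up to noise.

Corners are ordered top-left, top-right, bottom-right, bottom-left - a
consistent cyclic order is required for midpoint pairing. Coordinates are
0-based pixels, origin top-left, x rightward, y downward. Touching kernels
are not split (single-layer placement is the operating assumption);
a merged blob measures longer than any real kernel and is excluded by the
`sanity_length_mm` bound (default 15 mm) with its count reported, so an
operator sees that the tray needs re-spreading.

## Colour scoring

Yellowing and chalk are scored in HSV, which separates colour from the
brightness variation scanners produce. **Hue is on the 0-179 half-degree
scale and saturation/value on 0-255** - the 8-bit convention of mainstream
imaging software; configured ranges must use it. A kernel's yellow
(chalky) score is the fraction of its pixels inside the configured HSV box,
and the kernel is flagged when the fraction passes a threshold (default
0.30 for both traits). Both boxes and both thresholds are per-rice-type
configuration: the shipped defaults (yellow hue 20-35 with saturation and
value ≥ 80; chalk saturation ≤ 40 at value ≥ 200) are starting points for
interactive tuning, not standards. Hue wraparound (red) is deliberately
unsupported - neither target needs it - and rejected with a clear message.

Scoring uses the kernel's *core* mask (`kernel_core_mask()`, the
segmentation mask eroded by 2 px). The rim of a segmented kernel is a band
of mixed kernel/background colour; counting it would dilute every fraction
by the perimeter-to-area ratio. Scoring is per kernel, because reports
count grains per trait.

## Weight prediction

The trade limits broken content as a percent by weight, so each kernel
needs a weight even though only whole samples are ever on a scale. A random
forest (100 trees, other hyperparameters at library defaults) regresses
weight in grams on `(length_mm, width_mm)`, trained on a manually weighed
reference set and evaluated on a shuffled 80/20 holdout with

$$\mathrm{RMSE} = \sqrt{\tfrac1n \sum_i (A_i - B_i)^2}, \qquad
\mathrm{MAPE} = \tfrac{100}{n} \sum_i \left|\tfrac{A_i - B_i}{A_i}\right|$$

for actuals $A$ and predictions $B$. Percent-by-weight shares downstream
are invariant to any global rescaling of predictions, which makes the
report robust to calibration drift in the weight model.

## Damaged and paddy classification

Damaged (darkened) and paddy (hull still on) detection are two
independently trained binary classifiers over square kernel crops.
`prepare_crop()` extracts the kernel's bounding box padded 10%, masks
everything outside the kernel's convex outline to the background colour
(so a crop looks the same whether the kernel sat alone or in a crowd),
pads to a square and resizes. Three backbones share one
train/evaluate/predict contract:

* `hsv_texture_features` - mean/sd of RGB and HSV channels with a
  ridge-regularised logistic head; fast and dependency-light.
* `small_cnn` (default) - a fixed analytic convolutional filter bank
  (Sobel pair, Laplacian, four oriented ridge filters matched to hull
  striation) pooled at two scales, plus the colour statistics, feeding the
  same logistic head. Only the head is trained, in closed form; `epochs`
  and `batch_size` are recorded as schedule metadata but not consumed.
* `vgg19_transfer` - the VGG19 transfer pipeline: the canonical 19-layer
  architecture (`vgg19_architecture()` reproduces the exact filter counts
  and 224 → 7 shape flow), a frozen convolutional stack, and a trainable
  binary head. Pre-trained ImageNet weights are not shipped; the frozen
  stack is seeded He-initialised and exercised at reduced width and input
  size, which validates the structural path (layer shapes, freezing, head
  attachment, determinism) at desk scale. For accuracy-bearing work use
  `small_cnn`.

The logistic heads use ridge regularisation (glmnet, fixed small lambda)
because cleanly separable classes make unpenalised logistic fits diverge.

## Grading and the report

A kernel is **broken** when its length is strictly below the configured
threshold; a kernel exactly at the threshold counts as unbroken (the
convention is documented since "shorter than" and "above" leave equality
open). **Head rice** is strictly longer than the threshold. The threshold
is commercial, per rice type; the shipped presets mark 75% of a type's
nominal kernel length (4.8 mm for 6.4 mm IRRI-6) as an illustration only.

The report gives totals, average grain length/width (unweighted means),
head-rice AGL, whole/broken counts, per-trait counts and summed predicted
weights (traits are independent flags - a kernel can be both yellow and
broken), and a length histogram over unit bins [1,2) ... [9,10) mm with
per-bin count, mean length and percent by weight. Percent columns are
rounded to one decimal for display, so a printed column may sum slightly
under 100; the unrounded column always sums to 100 and both are reported.
Kernels outside 1-10 mm go to a flagged overflow row. Deviations between a
manual and a software AGL are reported as
`100 * (manual - software) / software`, rounded to two decimals. Percent
by weight uses predicted weights by default; `weight_basis = "count"`
switches to count-based shares for diagnostics.

## The synthetic scene generator

The generator renders the acquisition conditions the pipeline assumes:
near-black background (gray level 15/255, Gaussian sensor noise sd 3),
kernels in a single non-touching layer, a known render scale, and an
optional reference disk. Choices that matter:

* **Capsule kernels.** A capsule's minimum-area enclosing rectangle is
  exactly length × width, so dimensional ground truth is unambiguous -
  an ellipse would make the "true" box depend on rasterisation.
* **Population.** The IRRI-6-like sample draws lengths from
  N(6.4, 0.5²) mm truncated to [3, 8] and widths from N(2.0, 0.15²)
  truncated to [1.5, 2.6]; the weighed dataset for the weight model uses
  the same population, as a weighed reference set would.
* **Weight law.** True weight is $c \cdot L \cdot W^\alpha (1+\varepsilon)$
  with $\alpha = 2$ (volume-like), $c = 8\times10^{-4}$ g/mm³ putting a
  nominal kernel near 0.02 g, and multiplicative noise (sd 5% by default)
  truncated above −0.9.
* **Paint classes.** Plain, yellow, chalky-patch, damaged-patch and
  hull-textured paddy, with an 8-bit palette chosen to sit unambiguously
  inside/outside the default HSV boxes. Patches are painted to an exact
  area fraction of the rasterised kernel; the default patch range starts at
  0.35 so that no class sits exactly on the 0.30 flag threshold - class
  labels stay well-defined under ±2-point measurement error.
* **Placement.** Rejection sampling with true capsule-capsule
  (segment-segment) distances and an 8 px clearance. The clearance models
  operators spreading kernels and keeps blur halos of neighbouring kernels
  from merging under hysteresis; failure after bounded retries raises a
  scene-too-crowded error rather than silently overlapping.

Everything is deterministic under the spec seed.

What the generator does *not* emulate - translucency gradients, specular
highlights, real hull texture, dust, uneven illumination, touching kernels
- bounds what green tests mean: they demonstrate that the algorithms are
correct under the stated acquisition assumptions, not that the shipped HSV
defaults or classifiers transfer to any particular scanner without the
per-rice-type tuning the configuration system exists for.

## Problem sizes and numerical conventions

The test-suite and acceptance computations use scenes of 24-64 kernels at
12.5 px/mm, 2,500-sample weight datasets, and 120-200-crop classifier
datasets - sizes at which every stage's behaviour is already asymptotic
while a full run stays comfortably interactive on one CPU. Other fixed
conventions: Otsu threshold on the smoothed luminance; hysteresis ratio
0.4; minimum kernel area (1 mm × ppm)²; crop padding colour = scene median;
ties at the broken threshold count as unbroken; empty histogram bins report
a mean length of 0; an erosion that would empty a mask returns the mask
unchanged.

## Known limitations

* Touching kernels are excluded, not split; heavy clumping degrades counts.
* No illumination-field correction beyond the HSV representation; strongly
  non-uniform lighting would need flat-fielding upstream.
* The weight model does not extrapolate sensibly far outside its training
  hull (random forests predict constants beyond the data range).
* `vgg19_transfer` without pre-trained weights is a structural validation
  path, not a production classifier.
* Hue-wraparound colour targets (reds) are unsupported by design.
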