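---
title: "Interobserver consensus and preprocessing for endoscopic UC severity grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interobserver consensus and preprocessing for endoscopic UC severity grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uceisr)
```

## The problem

Endoscopic severity of ulcerative colitis (UC) is commonly graded with the
Ulcerative Colitis Endoscopic Index of Severity (UCEIS): three ordinal
descriptors — vascular pattern (0–2), bleeding (0–3), erosions/ulcers (0–3)
— whose sum spans 0–8. Even trained experts disagree on individual frames,
both at the score level and, more consequentially for treatment decisions,
at the level of severity categories (remission, mild, moderate, severe).
This package provides the building blocks of a multi-expert grading
workflow: quantifying interobserver agreement, forming consensus labels by
majority vote, removing imaging artifacts that confound downstream models,
and training/evaluating a desk-scale image classifier — all exercisable on
a bundled synthetic generator, so every stage is testable without clinical
data.

Subscores are encoded 0-based throughout. Descriptor levels are sometimes
listed 1-based in the clinical literature, which would shift the sum to
3–11; the 0–8 total is the published UCEIS convention and the one used
here.

## Severity bands

The mapping from totals to categories is controlled by three cutpoints
(`severity_cutpoints()`). The defaults — remission 0–1, mild 2–4, moderate
5–6, severe 7–8 — are the conventional UCEIS bands; they are explicit
arguments everywhere because grading conventions differ between centres.
The three-class scale merges remission and mild, reflecting that neither is
a target for aggressive therapy.

## Consensus voting

`consensus_vote()` retains an image when at least `threshold` raters assign
the same label; the default threshold is a strict majority
(`floor(k/2) + 1`, i.e. 3 of 5), under which the qualifying label is
provably unique, so no tie-breaking policy is ever exercised for retained
images. Ties below threshold are irrelevant: the image is discarded either
way. `retention_curve()` reports retention at every threshold; it is
monotone non-increasing by construction. Consensus is computed separately
for total-score panels and severity panels, since coarsening to categories
merges disagreements and typically retains more images.

## Agreement statistics

Both statistics are implemented from first principles and cross-checked in
the test suite against independent double-loop oracles and established
library implementations.

**ICC.** For score panels the package reports ICC(2,1): two-way random
effects, absolute agreement, single measurement,

$$\mathrm{ICC}(2,1) = \frac{MS_B - MS_E}{MS_B + (k-1)\,MS_E + \tfrac{k}{n}(MS_R - MS_E)},$$

with $n$ images, $k$ raters, and $MS_B$, $MS_R$, $MS_E$ the between-image,
between-rater and residual mean squares. This form was chosen because the
same fixed panel of raters scores every image and single ratings (not rater
averages) are the unit of analysis; the consistency form ICC(3,1) is
available via the `form` argument for sensitivity analysis. An all-constant
panel has no defined ICC and raises an error rather than returning a
misleading 1.0; negative estimates are reported as computed, not truncated.

**Fleiss' kappa.** For categorical panels, with $n_{ij}$ the raters placing
image $i$ in category $j$: $P_i = (\sum_j n_{ij}^2 - k)/(k(k-1))$,
$\bar P = \mathrm{mean}(P_i)$, $p_j = \sum_i n_{ij}/(nk)$,
$\bar P_e = \sum_j p_j^2$, and
$\kappa = (\bar P - \bar P_e)/(1 - \bar P_e)$. The degenerate case
$\bar P_e = 1$ (every rating in one category) is an error.

**Interpretation bands** follow the conventional tables (ICC: Poor /
Moderate / Good / Excellent at 0.5, 0.75, 0.9; kappa: Slight through
Perfect). Published versions of these tables print overlapping endpoints;
here a shared boundary value is assigned to the upper band. Negative kappa
is labelled "Below chance", which sits outside the conventional scale.

## Artifact removal

Endoscopic frames carry two stereotyped artifacts: specular reflections
from the light source (bright, desaturated) and unlit regions (dark). The
detector converts RGB to HSV — hue in degrees, saturation and value
rescaled to 0–255 — and marks as artifact every pixel outside the valid
tissue ranges, by default H (0, 360), S (90, 255), V (65, 236) with
inclusive endpoints. The printed ranges define *valid* pixels and the mask
is their complement: reflections fail the S lower bound or the V upper
bound, dark zones fail the V lower bound. A per-channel RGB baseline
(`rgb_artifact_mask()`, valid (0, 210) per channel) is retained for
comparison: it flags bright-red ulcer and erosion tissue along with the
highlights, the failure mode that motivates working in HSV, where lesion
tissue is saturated and of moderate value and therefore survives.

Masked pixels are filled by `apply_mask_and_inpaint()`. The default
backend is iterative diffusion — Jacobi relaxation of the Laplace equation
over the hole with valid pixels as boundary, run to a maximum update of
0.1 intensity units or 500 sweeps. By the maximum principle every filled
value lies within the range of the surrounding valid pixels. A
nearest-valid-pixel backend is available where speed matters more than
smoothness. Unmasked pixels are bit-identical in the output; frames more
than half covered by artifacts are refused rather than invented. The
0.1/500 stopping rule makes the residual Laplacian visually negligible for
hole radii up to a few dozen pixels; very large holes hit the sweep cap
first and come out smoother than real tissue, which is one reason the
generator's artifact radii are kept modest.

## Augmentation

`augment_image()` applies one draw of a conventional endoscopy training
recipe: rotation uniform in ±360°, zoom factor uniform in [0.85, 1.15],
shear factor uniform in ±0.15, shifts uniform in ±20% of each dimension, a
fair-coin horizontal flip, and mirror ("reflect") border filling. All
components are composed into a single affine about the image centre and
resampled bilinearly once, avoiding double interpolation. Zoom is
interpreted as a symmetric scale range and shear as a shear factor, the
usual semantics of image-generator pipelines in deep-learning frameworks.
Augmentation is purely geometric: the severity label attached to a sample
is never altered, and outputs keep the input's dimensions and 0–255 range.

## Desk-scale classifier

No deep-learning framework is assumed: the classifier is a deliberately
small convolutional network written directly in R — a single 3×3
convolution (8 filters, ReLU), 8×8 block average pooling, and a softmax
layer — trained with Adam on categorical cross-entropy. Two initialisation
choices matter at this scale: convolution biases are drawn uniformly in
±0.3 so the ReLU units act as soft colour thresholds from the first step
(block averages then expose "fraction of pixels beyond a threshold"
features), and the softmax layer starts at zero. Inputs are resized to
`target_size` (default 96×96) and centred to [−0.5, 0.5]. The default Adam
step is 1e-2, appropriate for a tiny randomly initialised network trained
for a handful of epochs; a clinical-scale recipe for large pretrained
backbones (learning rate 1e-4, 543×475 inputs, 30 epochs) can be requested
through `train_config()` but is not part of the test surface. Training is
deterministic for a fixed `seed`; divergence (non-finite loss) aborts with
a diagnostic rather than returning a broken model.

`split_dataset()` stratifies by the three-class label, rounding
`train_fraction` within each class, so an 80/20 split of a 269/192/60 mix
yields 417 training and 104 test samples. `eval_report()` reports the
confusion matrix and accuracy, precision, recall and F1 in both
support-weighted and macro averages — both, because published tables are
often ambiguous about the convention; support-weighted recall is
algebraically identical to accuracy and that identity is asserted in the
tests.

## The synthetic generator

The generator produces everything the pipeline consumes, with ground truth
attached. It emulates three properties of clinical material and makes no
claim beyond them:

- **Tissue**: a smooth pink-red HSV field (coarse random grid, bilinearly
  upsampled, plus fine noise) sampled strictly inside the valid artifact
  ranges, with a 5-unit margin so 8-bit quantisation cannot push a tissue
  pixel across a threshold.
- **Lesions** per class, all strictly inside the valid ranges: thin dark-red
  vessel curves (remission/mild), many small bright-red erosion blobs
  (moderate), and large irregular dark-red ulcer regions (severe). The
  classes are constructed to be separable from pixel statistics — the
  suite verifies a linear probe exceeds 0.9 accuracy — because the
  classifier harness is meant to be exercised on an easy task; lesion
  palettes were calibrated once against that probe criterion.
- **Artifacts**: specular highlights (S ≤ 60, V ≥ 240) and dark discs with
  irregular boundaries (V ≤ 40), strictly outside the valid ranges, so the
  ground-truth mask is *exactly* the set of out-of-range pixels and mask
  recovery can be asserted pixel-for-pixel.

What it does **not** emulate: vignetting and specular blooming, motion
blur, fluid and debris, perspective distortion of a tubular lumen,
inter-patient tissue variation, or any correlation between artifact load
and severity. Passing tests therefore demonstrate the pipeline's internal
correctness and its behaviour under controlled conditions — not clinical
performance.

The rater simulation draws, per image, a latent class from a configurable
prior (default proportional to a 269:192:60 mix, the combined-cohort class
distribution; the rectal-cohort 204:42:8 mix can be passed instead) and a
latent total uniform within that class's cutpoint band. Each rater
observes the latent total plus an integer error in {−2…+2}: zero with
probability `p_agree`, the remainder split symmetrically with 80% of each
side's mass on ±1 and 20% on ±2, clipped to 0–8. Errors act on the
*total*, not on the category, so category disagreement emerges only near
band boundaries — which is why simulated score-level agreement (ICC)
systematically exceeds category-level agreement (kappa), the same ordering
reported for real expert panels. `retention_probability()` gives the exact
enumeration counterpart of the simulated consensus retention rate, used as
an oracle in the tests.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale on
one CPU: 1000 random panels for the kappa oracle, 200 for the ICC oracle,
50 seeds for null calibration, 20 replicates for the ICC-versus-kappa
ordering, 100 frames at 160×140 for mask exactness, full-size 543×475
frames for the inpainting contract, and a 300-image end-to-end run at
96×96 with 10 epochs and two augmented copies per training frame. Panel
simulations default to 254 images and 5 raters, the size of a typical
single-centre reading study. Convergence and tolerance choices (diffusion
0.1/500; oracle agreement 1e-12 and 1e-10; retention within ±0.02 of exact
enumeration) are stated alongside the corresponding tests.

## Known limitations

- The HSV thresholds are global constants; frames with atypical white
  balance would need recalibrated ranges.
- Diffusion inpainting over-smooths large holes; a structure-propagating
  method would be preferable for artifact fractions beyond a few percent.
- The desk CNN is a harness, not a clinical model: no pretraining, one
  convolutional layer, and accuracy claims only on the synthetic task.
- Consensus is majority voting only; probabilistic label-fusion models
  (e.g. Dawid–Skene) are out of scope.
- Agreement statistics come without confidence intervals; bootstrap
  resampling would be a natural extension.
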