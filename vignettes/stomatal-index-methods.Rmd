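---
title: "Measuring the stomatal index from epidermis micrographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the stomatal index from epidermis micrographs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The trait and the measurement problem

The stomatal index of a leaf surface is

$$ SI = 100 \cdot \frac{s}{s + c} \ \%, $$

where $s$ is the number of stomata and $c$ the number of epidermal pavement
cells in a field of view. Unlike stomatal density (stomata per mm²), the
index is largely insensitive to cell expansion, which makes it a diagnostic
trait of a genotype or species — provided both counts come from the same
magnification, since the index shifts systematically with the field of view.
Counting both classes by hand is the bottleneck: a micrograph of a grass
epidermis holds on the order of a hundred tightly packed, thin, transparent
pavement cells.

`stomx` automates the measurement with two models and a morphological
post-processing chain:

1. an **anchor-based convolutional detector** finds stomata and a detection
   counts as a stoma when its confidence exceeds 0.9 (strictly);
2. a **U-Net-style encoder–decoder** classifies every pixel as cell wall
   (black) or intracellular (white), reproducing the annotation convention
   in which subsidiary cells flanking the guard cells are painted black and
   therefore never counted as epidermal cells, and trichomes are painted
   white so they do not interfere;
3. the predicted cell network is **bilaterally filtered, binarized, opened,
   and labeled**; connected domains are epidermal cells, after domains
   smaller than 1/10 of the mean domain area are discarded as incomplete
   edge fragments;
4. the index follows from the two counts. When both counts are zero the
   index is reported as missing, never as zero.

## Detector

The detector follows the two-term objective

$$ L = \frac{1}{N_{cls}} \sum_i L_{cls}(p_i, p_i^*) +
   \lambda \frac{1}{N_{reg}} \sum_i p_i^* \, \mathrm{smooth}_{L1}(t_i - t_i^*), $$

with $\lambda = 10$, a softmax cross-entropy classification term over
sampled anchors, and a smooth-L1 box-regression term over positive anchors
($N_{reg}$ is guarded: with no positives the term is zero). Anchors use
scales $\{4, 8, 16\}$ (side = scale × stride) and aspect ratios
$\{0.5, 1, 2\}$ at the backbone stride. The full-scale protocol — inputs
resized to 800 × 600, batch 16, cosine annealing of the learning rate from
5e-4 to 5e-5 over 20 epochs — is the constructor default of
`detector_config()`.

Two genuinely open design points and how they are resolved:

* **Backbone.** The reference protocol uses a deep ImageNet-pretrained
  residual backbone. No pretrained weights ship with this package; the
  default is a small residual network (blocks of two 3×3 convolutions with
  an identity connection, widths 16/32/64, stride 8) trained from scratch,
  which is what a single CPU can fit. `widths` and `pretrained` expose the
  scaling path.
* **Anchor sampling.** Per image a balanced minibatch of anchors is labeled
  (IoU ≥ 0.5 positive plus the best anchor of each box; IoU < 0.4
  negative). Half of the negative budget is drawn from the near-object ring
  (IoU in [0.1, 0.4)). Without this hard-negative emphasis, almost-aligned
  anchors are essentially never sampled as negatives, fire with high
  confidence at test time, and inflate the count with shifted duplicates
  that survive non-maximum suppression; with it, duplicate suppression is
  handled where it belongs, in the classifier.

NMS uses IoU 0.5 by default (the reference protocol does not state one),
with exact score ties broken lexicographically by box coordinates so
detection is order-independent. Counting applies the strict `score > 0.9`
rule.

## Segmenter

Images are standardized per channel before training:

$$ \hat I = \frac{I - \mu}{\max(\sigma, 1/\sqrt{N})}, $$

where $\mu, \sigma$ are per-channel statistics over all training-set pixels
(frozen into the model so prediction standardizes identically; a per-image
mode is available, as the reference description is ambiguous about the
population), and $N$ is the pixel count of the image — the guarded divisor
keeps constant images finite. The loss is pixelwise binary cross-entropy
with predictions clipped to $[10^{-7}, 1 - 10^{-7}]$; weights use Kaiming
initialization; the full-scale schedule is 512 × 512 inputs, batch 8,
cosine annealing 1e-4 → 1e-5 over 200 epochs. Online augmentation applies a
small random affine perturbation with probability 0.2 (±10° rotation/shear,
±5% scale/translation — the reference states only the probability) and a
90° rotation with probability 0.5, identically to image and mask.

The architecture is the classic contracting/expanding scheme with skip
concatenations and nearest-neighbour upsampling; the desk-scale default is
3 levels at base width 8. Probability maps are bilinearly resized back to
the input dimensions; masks always travel under nearest-neighbour
interpolation so no intermediate values appear.

Inference is **mirror-padded**: the image is reflected outward by 16 px,
the network runs on the padded canvas, and the prediction is cropped back.
Zero padding inside the convolutions makes predictions least reliable
exactly at the frame, where walls between border cells must reach the
image edge; without the mirror trick a single missed border wall merges a
whole column of edge cells into one connected domain. Reflection is the
same remedy the original encoder–decoder segmentation literature uses for
tiled inference.

The semi-automatic annotation loop is `generate_pseudo_labels()`: a model
trained on a small manually annotated seed subset predicts masks for the
remaining images, written as 0/255 PNGs for human correction.

## Post-processing chain

* **Bilateral filter** (radius 4, range sigma 0.3 on the probability scale,
  spatial sigma 4 — unstated in the reference, chosen once as standard
  edge-preserving values): removes prediction noise without moving wall
  edges.
* **Binarization** at 0.5 (`>=` maps to intracellular).
* **Morphological opening of the intracellular class** (3×3 square element,
  1 iteration). A break in a predicted wall is a thin white channel;
  opening removes white structures too thin to contain the element, so
  breaks close while cells are merely smoothed. (Opening the *wall* class
  instead cannot close breaks — opening is anti-extensive — and erodes thin
  walls entirely; this is why the operator acts on the white class.)
* **Connected-domain labeling** under 4-connectivity by default, so
  diagonal wall contacts still separate cells; 8-connectivity is available.
* **Area filter**: the mean domain area is computed once over all domains
  and domains strictly below 1/10 of it are removed in a single pass (the
  strict `<` follows the stated rule; equality survives).

## Synthetic micrographs

`generate_scene()` renders the study's desk-scale data: a jittered
anisotropic grid of seed points partitioned by nearest-seed assignment
under an axis-scaled metric (elongation 3 stretches cells along x, the way
grass pavement cells run along the leaf axis), boundaries become dark walls
(3 px), a seeded subset of regions becomes stomata — a dark dumbbell
guard-cell pair drawn along the cell axis, flanking region painted in
subsidiary tone and, like the guard cells, wall-class in the truth mask —
plus occasional bright trichomes confined to single cell interiors, an
illumination gradient, and Gaussian intensity noise (σ = 8 of 255).
Defaults: 256 × 256 px, 48 target cells, target index 15% (within the
range observed for wheat abaxial epidermis at ×10), trichome rate 0.5 per
image. These values were fixed once as the study conditions; the truth
record is derived from the rendered mask itself (epidermal cells = white
connected domains; wall rasterization slivers below a tenth of the mean
domain area are reassigned to wall before the truth is read off) and from
the placed stomata under the half-at-edge visibility rule (a stoma
straddling the border is annotated only when more than half of its length
lies inside). Noise never changes the truth.

What the generator does *not* emulate: staining chemistry and real optical
texture, cell-size distributions calibrated to any particular cultivar,
out-of-focus blur, overlapping tissue layers, or 3-D cell shape. Passing
tests therefore demonstrate that the pipeline's machinery — training,
inference, counting, and every metric — is correct and learns this class
of imagery; they do not certify accuracy figures on real micrographs.

## Evaluation metrics

All of the study's statistics are implemented: IoU; average precision as
the area under the all-point-interpolated precision–recall curve with
greedy one-to-one matching by descending score and a strict IoU > 0.6
true-positive rule; Dice $2TP/(2TP+FP+FN)$; counting accuracy
$1 - |a - m|/m$ (undefined at $m = 0$); counting precision
$\log_{10}(m/a)$ — negative means overcounting — undefined when either
count is zero, with a natural-log switch since the reference does not fix
the base; the same two forms applied to index values; identity-line
agreement $R^2 = 1 - \sum(x_i - y_i)^2 / \sum(x_i - \bar x)^2$ (the
denominator uses the mean of the *manual* values; the reference's symbol
is ambiguous between the two series, and the manual series is the natural
total-sum-of-squares baseline for a $y = x$ fit) and
$RMSE = \sqrt{\sum(x_i - y_i)^2/N}$; coefficient of variation; Pearson
correlation; and a paired two-sided t-test with $n - 1$ degrees of freedom
for magnification comparisons, flagged rather than reported when the
differences are constant. Average running time is
$(T_{stoma} + T_{cell} + T_{SI})/N$; it is hardware-dependent and is
reported, never asserted.

## Numerical and scale choices

Problem sizes in the shipped tests and the acceptance script were chosen as
the package's desk-scale study: 40 training and 10 held-out 256 × 256
scenes. In the acceptance study each scene additionally draws its own cell
target (40–60) and index target (10–20%) — real micrographs differ from
leaf to leaf, and a constant-count evaluation set would make the
identity-regression $R^2$ degenerate (zero total sum of squares). The
segmenter is trained 15 epochs at batch 1 with the initial rate raised
to 3e-4 (annealed to a tenth) because the desk run takes two orders of
magnitude fewer optimizer steps than the 200-epoch full protocol; detector
trained 40 epochs at batch 4 with a 256-anchor minibatch. The full-scale
protocol values remain the constructor defaults throughout. Cubic
interpolation (Keys, a = −0.5) implements the ×20 magnification simulation
(680 × 512 crop, ×2 enlargement); 45° offline-rotation canvases are
expanded and filled white, and rotated boxes become the axis-aligned
circumscribed rectangles of their corners, keeping annotations valid at
the cost of looseness. Convolutions run in single precision via
im2col + GEMM; training is seeded end to end and bit-reproducible on a
fixed platform.

## Known limitations

* The detector is single-stage (dense anchors over a small residual
  backbone). The configuration contract — anchors, loss, schedule,
  counting rule — matches the reference two-stage design, but no region
  proposal refinement stage exists, and no pretrained deep backbone ships.
* Merged cells are not split (no watershed); subsidiary cells are excluded
  at annotation time, not re-identified.
* Counting accuracy can exceed the metric's intent when manual counts are
  tiny: one miss among three objects costs 33 points. The synthetic study
  keeps object counts in the realistic range so the metric behaves as
  published.
* Few-shot transfer of the detector adapts its loss and localization to a
  new image family, but ten fine-tuning images are not enough to push its
  softmax confidence back over the strict 0.9 counting threshold; reliable
  counting on a new family needs a larger fine-tuning set. The segmenter
  adapts fully under the same budget.
* The timing report measures this machine; it is not comparable across
  hardware.
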