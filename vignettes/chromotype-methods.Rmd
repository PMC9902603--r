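---
title: "Methods: classifying sister-chromatid cohesion morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying sister-chromatid cohesion morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Sister-chromatid cohesion (SCC) — the holding-together of replicated
chromatids by the cohesin complex — is routinely assayed by classifying
Giemsa-stained metaphase chromosomes into three morphology types: tightly
cohered (A), arms separated but centromere joined (B), and fully separated
chromatids (C). A cohesion defect shifts the type distribution of a sample
away from A toward B and C. Because the type boundaries are continuous,
human scoring varies between observers; an automatic classifier provides a
fixed standard. `chromotype` implements such a classifier together with the
evaluation protocol, saliency maps, a genotype-contrast readout, and a
synthetic image generator that makes the whole pipeline self-contained.

## Preprocessing

Each cropped single-chromosome image passes through five stages, all
recorded in `preprocess_config()`:

1. **White-out.** Pixels marked by an exclusion mask (bystander chromosomes,
   debris) are replaced with white (255, 255, 255), the background
   convention of a bright-field crop.
2. **Resize** to 224 × 224 (bilinear by default; nearest-neighbour and
   exact area averaging are available). Aspect ratio is not preserved —
   crops are stretched to square.
3. **Contrast/brightness** `dst = α·src + β` with α = 3.0, β = 80.0,
   clipped to [0, 255]. With these constants any input above ≈ 58 intensity
   units saturates to white; the recipe assumes dark chromatin
   (well-stained spreads) and deliberately flattens the background.
4. **Gamma correction** `y = (x/255)^γ · 255` with γ = 3.0, which darkens
   midtones and further increases chromatin/background separation. The
   endpoints 0 and 255 are fixed points and the map is monotone.
5. **Per-channel standardization**: each RGB channel is affinely rescaled
   to sample mean 64 and sample standard deviation 16, removing
   image-to-image staining-shade differences.

Three choices here were genuinely open and are recorded as package
decisions:

- **Stage order.** White-out precedes resizing so that interpolation cannot
  bleed removed objects back into the image; the pointwise stages follow in
  the order contrast → gamma → standardization. The order is a
  `preprocess_config()` field and can be permuted for experiments.
- **Clipping.** The contrast stage clips to [0, 255]; gamma needs no clip on
  that range. The standardized output is handed to the model as unclipped
  real numbers — clipping would destroy the fixed mean/SD that the stage
  exists to guarantee. PNG previews clip for display only.
- **Standardization scope** is per image (not per dataset), because the
  stage's purpose is to cancel per-image staining differences.

Grayscale sources are replicated to three identical channels. Resampling is
implemented as separable row/column weight matrices with the half-pixel
centre alignment convention, so that nearest-neighbour resizing at equal
size is the exact identity and area averaging preserves the image mean.

## Backbones and the transfer contract

The classifier follows the frozen-feature-extractor recipe: a
convolutional backbone with fixed weights feeds global average pooling
(GAP) and a trainable 3-way linear head. Freezing is a tested contract —
features extracted before and after head training are bitwise identical.

Three reduced-depth families are built in (all work without any downloaded
weights; hooks accept externally supplied pretrained weights):

- `fire_module`: 7×7/stride-4 conv → max-pool → fire block (squeeze 1×1 to
  8 channels, parallel expand 1×1/3×3 to 16 + 16, concatenated) →
  max-pool. The squeeze/expand/concatenate motif of lightweight
  classification networks.
- `residual_block`: 7×7/stride-4 conv → max-pool → two 3×3 convs with an
  identity shortcut → max-pool → 1×1 conv. The shortcut motif of residual
  networks.
- `small_scratch` (default): a **polar-resampling stem** followed by
  circular convolutions. The stem bilinearly resamples the image on a
  32 × 64 (radius × angle) grid centred on the chromatin centroid (the
  darkness-weighted centre of mass); two 32/64-channel convolutions with
  wrap-around padding in the angle axis and 2×2 max-pooling follow.

The `small_scratch` design is the package's answer to a structural problem
of desk-scale transfer learning on chromosome crops: cropped chromosomes
carry uniform random orientation, and GAP over conventional random
convolutional features is not rotation invariant, so a linear head trained
on tens of images per type cannot average the orientation nuisance away
(in our experiments such stacks plateau far below the accuracy of
interest regardless of width or depth). On the polar grid an image
rotation becomes a circular shift of the angle axis, which circular
convolution preserves and GAP cancels; translation is absorbed by the
centroid. The feature vector is thus approximately invariant to the two
dominant nuisances while remaining sensitive to the radial/angular
signatures that define the types — type C, for instance, has background at
the centroid (the inter-chromatid slit) where A and B have chromatin.
Weight initialization for all families is seeded He-normal; biases are
zero.

## Head training

The head is multinomial logistic regression on the standardized GAP
features (training-set mean/SD, stored in the model), fitted by mini-batch
SGD: 30 epochs, batch 32, fixed step size 0.1, seeded small-magnitude
initialization and per-epoch shuffling. After every epoch the model is
scored on a held-out validation set, and the checkpoint with the highest
validation concordance is returned (earliest epoch on ties) — model
selection is per epoch, one of the protocol's open points that the package
resolves explicitly. The loss, optimizer and schedule are unremarkable by
design; the tested contracts (freezing, reproducibility, capacity on
separable data) do not depend on them.

Prediction preprocesses the raw image with the model's stored
configuration, extracts features, and takes the argmax of the three class
scores; exact ties break to the lowest label index (A < B < C).

## Evaluation protocol

`split_spec()` encodes the full-scale protocol: a 654-image test set, a
pool that can be augmented (e.g. +221 type C images for class balance),
repeated selection of 400 validation and 1,275 training images, balanced
subsets of 231 images per type (693 total), and 3 selections × 10 training
cycles = 30 trials whose scores are averaged.

Two subtleties are worth recording:

- **Validation and training are both sampled.** 400 + 1,275 = 1,675 of the
  1,711-image pool; 36 images go unused in each selection. The operation
  therefore takes an optional `training_size`; the default (`NULL`) uses
  the whole remainder.
- **Test selection is cell-level by default** (no cell contributes images
  to both test and pool), while validation/training selection is
  image-level. With whole cells of roughly 14 images an exact image count
  is generally unreachable, so the cell-level splitter accumulates shuffled
  cells until the requested count is first reached (the result can exceed
  the request by at most one cell). `test_unit = "image"` gives exact
  counts.

Per-trial sub-seeds derive from the base seed and the (selection, repeat)
indices through a documented polynomial hash (`derive_seed()`), so any
single trial can be rerun in isolation. Reports carry the per-trial values
next to the averages; display rounds to one decimal place, raw values are
kept.

## Grad-CAM

For target class c and a chosen convolutional activation A with channels
k, the saliency map is ReLU(Σₖ αₖ Aₖ), with αₖ the spatial mean of
∂(class score)/∂Aₖ. The gradient is taken on the pre-softmax score, flows
through the head and GAP analytically, and backpropagates through any
layers between the network output and the target activation (max-pool
routing, ReLU gating, convolution transposes — including circular ones).
The map is normalized by its maximum when positive and rendered at input
resolution: bilinear upsampling for Cartesian backbones, inverse polar
lookup around the stem's centroid for `small_scratch`. The default target
is the last convolutional activation.

## The synthetic generator

`synth_config()` draws one chromosome per image: two mirror-image
chromatids, each a thickened bent rod (two arms meeting at the centromere),
rasterized with a 1-px anti-aliased edge and quantized to 8 bits, dark on a
light background. The label is realized geometrically:

| Parameter | A | B | C |
|---|---|---|---|
| arm half-opening (deg) | 0–6 | 18–40 | 4–20 |
| centromere gap (px) | 0 | 0 | 12–26 |

The A and B angle ranges are disjoint, so every label is recoverable from
the draw by a rule-based classifier (`classify_geometry()`), which is
tested exactly. For A and B the chromatid centres sit 0.35 widths apart so
the bodies merge into one connected component (B splays the arms while the
centromere region stays joined); for C the bodies are disjoint with an
edge-to-edge gap of at least 12 px. Remaining defaults: tip-to-tip length
80–124 px and width 10–16 px on the 224-px canvas; whole-chromosome
rotation uniform in 0–360°; centromere position 0.38–0.62 of the length
(metacentric to submetacentric); chromatin shade 15–50 intensity units with
4–12 units of texture (dark enough that staining survives the contrast
stage's saturation point, as the preprocessing recipe assumes of real
Giemsa spreads) under a purple-tinted channel profile; background 244;
sensor noise SD 5; and a 10% chance of a small elliptical "photobombing"
fragment near the border, a known confounder of real crops. Images are
grouped round-robin into synthetic cells of ~14 images (≈ 2,144/150), so
cell-level splitting is exercised without modelling spatial cell structure.

What the generator does **not** emulate: chromosome banding, bent or
twisted chromatids, overlapping chromosomes, intensity vignetting, and the
ambiguous boundary cases that make human scoring hard — the A/B angle
ranges are deliberately disjoint, sidestepping the continuum. Passing the
synthetic recovery tests therefore shows that the pipeline's mechanics are
correct and that the model family can learn cleanly separated geometry; it
does not certify accuracy on real spreads, where both automated and human
concordance with a reference annotator are far lower (broadly the 50–80%
range).

## Numerical choices and degenerate inputs

- Standardization refuses constant channels (zero SD) with an error naming
  the channel; a fully masked (all-white) image is therefore rejected
  rather than silently producing NaNs.
- Feature standardization in the head maps zero-variance features to scale
  1 instead of dividing by zero.
- Max-pool backward routes gradients to the first maximum on ties.
- The chi-squared independence test in `contrast_genotypes()` drops type
  columns absent from both samples (the statistic is undefined otherwise)
  and is labelled supplementary output — the protocol itself reports only
  distributions and deltas.
- Genotype distributions quoted as rounded percentages may sum to slightly
  off 1; `generate_genotype_pair()` accepts a 0.005 tolerance and
  renormalizes.

## Problem sizes used by the tests and the acceptance script

Unit tests run the full pipeline on 96-px images with proportionally scaled
geometry (the generator, pipeline and polar backbone are size-agnostic).
The end-to-end recovery checks use the full 224-px study conditions with
130 images per type, a reduced protocol of 2 selections × 3 repeats at 60
training images per label (plus a 5-per-label point for the learning-curve
comparison), and 300 images per genotype for the defect-recovery contrast;
the full-scale splitting arithmetic runs on a 2,144-image synthetic dataset
at 96 px. These sizes were chosen as the smallest that leave the checked
properties comfortably away from their thresholds.

## Known limitations

- The backbones are reduced-depth stand-ins; no claim is made that their
  accuracy on real data matches full-scale pretrained networks, and the
  package does not ship pretrained weights.
- Masks for white-out must be supplied (or come from the generator's
  ground truth); the package does not infer them.
- Only PNG images are read.
- No automatic detection/cropping of chromosomes from whole spreads; inputs
  are single-chromosome crops.
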