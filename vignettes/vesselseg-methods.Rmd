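---
title: "Methods: residual U-Net vessel segmentation in vesselseg"
author: "vesselseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residual U-Net vessel segmentation in vesselseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselseg)
```

## Scope and model

`vesselseg` segments retinal vasculature in 2-D images with an improved
U-Net. The network is built from three components:

* **Residual encoder/decoder blocks.** Each block is conv3×3 → batch-norm
  → ReLU → conv3×3 → batch-norm, plus a shortcut from the block input
  added before a final ReLU. The shortcut is the identity when input and
  output channel counts match and a 1×1 convolution otherwise (a plain
  projection, without normalization — the projection only matches
  dimensions, it is not a feature extractor).
* **Inception bottleneck.** The deepest encoder map passes through three
  parallel convolution branches with kernels 1, 3 and 5 (each followed by
  batch-norm and ReLU, all at the same width), concatenated and projected
  by a 1×1 convolution back to the bottleneck width.
* **Full-scale skip connections.** Decoder stage $t$ of a depth-$L$
  network consumes exactly $L$ sources: encoder levels $1..t$, max-pooled
  by $2^{t-l}$, and the decoder chain below (stages $t{+}1..L{-}1$ and the
  bottleneck at level $L$), bilinearly upsampled by $2^{l-t}$. Each source
  is brought to a common `fusionChannels` width by conv3×3 + batch-norm +
  ReLU; the concatenation is fused by a residual block into the stage's
  channel count. This is the aggregation topology in which deeper decoder
  outputs reach shallower stages both directly and through the chain; we
  adopted it because it is the only reading under which every decoder
  stage sees all $L$ scales (the "full-scale" property) and the shallowest
  stage of a depth-4 network exercises all of the 2×/4×/8× upsampling
  paths.

A 1×1 convolution head plus sigmoid yields per-pixel vessel probabilities.
The assumptions are those of the architecture family: a single foreground
class, roughly translation-equivariant appearance, and informative context
at multiple scales (vessel caliber decays along the tree, so thin-vessel
evidence lives at full resolution while topology lives deeper).

## Parameters and defaults

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `depth` | 4 | levels | standard U-Net sizing; demo/tests use 3 |
| `baseChannels` | 32 | channels | doubled per level, as in U-Net |
| `bottleneckChannels` | deepest width | channels | keeps the latent width unchanged |
| `fusionChannels` | 32 | channels | uniform per-source fusion width |
| bilateral diameter / $\sigma_{color}$ / $\sigma_{space}$ | 9 / 0.1 / 5 | px / intensity / px | common fundus-enhancement settings |
| CLAHE clip / tiles | 2 / 8×8 | — | classic contrast-limited defaults |
| `gamma` | 1.2 | exponent | mild detail-preserving darkening |
| rotation / shift / flips | ±30° / ±10% / on | — | modest topology-preserving transforms |
| `epochs` × `stepsPerEpoch` | 100 × 100 | steps | the full training protocol; scaled down at desk scale |
| optimizer / learning rate | Adam / 1e-3 | — | standard for U-Net variants |
| `loss` | `bce` | — | binary cross-entropy per pixel; `bce_plus_dice` offered for class imbalance |
| `threshold` | 0.5 | probability | binarization cutoff (≥ convention) |

None of the filter, augmentation or optimization constants are dictated by
the architecture; all are config slots, logged in every run's provenance
record, so ablations are re-runnable.

## Synthetic data: what it does and does not emulate

The generator grows `nTrees` recursive binary trees of polyline strokes:
each branch is a short, angle-jittered polyline; children leave at
±`branchAngleDeg` (scaled by a uniform factor) with half-width multiplied
by `widthDecay`, down to `branchDepth` levels. Strokes are rendered by
distance with a 1-pixel anti-aliased edge; the binary mask is the soft
rendering thresholded at 0.5, which keeps mask and image geometrically
aligned by construction. The image is a smooth illumination field (linear
ramp plus radial vignette, rescaled to span `illuminationGradient`
peak-to-trough around a 0.6 base level), darkened by `vesselContrast`
under the soft strokes, plus Gaussian noise, clipped to [0, 1].

This reproduces the properties the architecture targets — dark,
curvilinear, bifurcating vessels of decaying caliber on a nonuniform
background with sensor noise — and the (seed, index) pair fully determines
each sample. It deliberately does **not** model the optic disc, fovea,
lesions, vessel crossings of distinct trees with coherent shading, or
OCT-A speckle. Passing tests on synthetic data therefore demonstrate that
the implementation learns and segments this class of structures
correctly; they do not certify clinical-grade performance on real fundus
images.

Default generator conditions (128×128, 2 trees, 4 levels, root half-width
3 px, decay 0.7) give a vessel fraction of about 7 ± 2 % (mean ± sd over
100 seeds), comparable to fundus annotations; the Monte-Carlo band frozen
in the tests comes from that measurement.

## Numerical choices

* **Batch norm**: per-channel batch statistics during training
  (ε = 1e-5), exponential running statistics (momentum 0.1, unbiased
  variance) for evaluation.
* **Initialization**: fan-in-scaled Gaussian weights
  (sd = $\sqrt{2/(k^2 C_{in})}$), zero biases, unit batch-norm scale; all
  drawn from R's RNG under a recorded seed.
* **Adam**: $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$, with
  bias correction.
* **Bilinear upsampling** uses the half-pixel-center convention with
  clamped edges; transposed convolutions were avoided (checkerboard
  artifacts). **Max pooling** ties break to the first (top-left) maximum.
* **Padding**: images whose sides are not divisible by $2^{depth-1}$ are
  reflect-padded and predictions cropped back; during training a validity
  mask removes padded pixels from the loss, and during evaluation the
  crop happens before counting, so padding never changes a metric.
* **Degenerate inputs**: constant images are fixed points of the bilateral
  filter (convex window average) and are returned unchanged by CLAHE (a
  single-bin histogram has no meaningful equalization); metrics with a
  zero denominator are reported as 0 and flagged `undefined` rather than
  erroring, so batch evaluation stays total.
* **Binarization** uses the ≥ convention at the threshold.
* **CLAHE** delegates to the classic clipped-histogram implementation in
  EBImage with the raw equalized mapping (not rescaled back into the
  input's original range, which would undo the contrast gain on
  low-contrast images).

## Open design decisions

* The decoder aggregation topology (above) was chosen over a
  chain-only variant; the structural test pins sources-per-stage $= L$.
* Whether augmentation targets include the originals is a convention; we
  include them (`augmentToCount(20, 2000)` returns 20 originals + 1980
  transforms), recorded in sample ids.
* "Steps per epoch" is an explicit config field; an epoch is
  `stepsPerEpoch` optimizer steps over shuffled batches, independent of
  dataset size.
* Aggregation over images defaults to micro (pooled counts), with macro
  (per-image average) available — the two differ when image sizes or
  prevalences differ, and published tables rarely say which was used.
* Metrics are restricted to the field-of-view ROI when one exists
  (pixels outside the imaged disc carry no information); switchable by
  simply not passing the ROI.
* The per-pixel loss is binary cross-entropy by default — consistent with
  per-pixel training accuracies near 0.998 and losses near 0.003 reported
  for this family of models — with `bce_plus_dice` as the imbalance-robust
  alternative.

## Problem sizes

The test suite and the acceptance script run everything at desk scale, a
deliberate choice so the full pipeline is verifiable on one CPU: 64×64
synthetic images, a depth-3 / 8-channel network (~89k parameters), 300
optimizer steps for the capacity check (8 images memorized to F1 ≥ 0.95)
and for the held-out run (16 train / 8 test, F1 ≈ 0.92), and a 16-image
demo pipeline for the determinism check. Full-scale training (depth 4,
base 32, thousands of augmented images, 10⁴ steps) uses exactly the same
code paths through the same configuration objects.

## Known limitations

* CPU-only; wall-clock makes full benchmark-scale training impractical
  (the kernels are single-image im2col + GEMM, not vectorized across a
  large batch dimension).
* Whole-image training only — no patch sampling, so very large images
  cost memory proportional to their area.
* GIF masks (as shipped by some legacy datasets) are not decoded; convert
  to PNG/TIFF first. Layout pairing for such datasets still works.
* The synthetic generator's realism limits (above) mean reported synthetic
  metrics should not be compared numerically against results on real
  fundus benchmarks.
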