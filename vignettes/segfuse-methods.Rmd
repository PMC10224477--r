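---
title: "Sigmoid-averaged ensemble fusion: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sigmoid-averaged ensemble fusion: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segfuse)
```

## The fusion model

A deep segmentation network with intermediate supervision emits $n$
pre-sigmoid grids $P_1, \dots, P_n$ per image ($n = 1$ for a
HarDNet-MSEG-style head, 2 for Polyp-PVT-style, 4 for HSNet-style). The
conventional single-network output is
$\mathrm{minmax}\!\left(\sigma\!\left(\sum_i P_i\right)\right)$, and an
ensemble averages such outputs over its members. `segfuse` implements
the alternative head rule
$$\frac{1}{n}\sum_{i=1}^{n} \sigma(P_i),$$
with no normalization layer, and fusion by the (weighted) pixelwise mean
of member masks.

The argument is quantitative, and the package's diagnostics make it
measurable. Write $\tau = 6.9$; since $\sigma(6.9)$ rounds to $0.999$, a
pixel whose driving logit exceeds $\tau$ in magnitude retains less than
$10^{-3}$ of graded confidence — it is *saturated*. Real supervision
heads produce per-image logit extrema anywhere from a few units to the
hundreds, so $\sigma(\sum_i P_i)$ saturates essentially everywhere and
pixelwise averaging of such masks reduces to majority voting. Averaging
the per-head sigmoids instead bounds every term in $(0,1)$: where heads
of different sharpness disagree, or near boundaries where the softer
heads are undecided, the fused value stays interior. The min-max layer
is removed because it forces each mask to attain both 0 and 1, i.e.
asserts a foreground object on every frame; an objectless colonoscopy
frame then *must* produce a spurious detection. `minmax_normalize()`
raises an error on a constant mask for exactly this reason — the
degenerate case is the motivation, so it surfaces rather than being
patched over.

Two saturation rates are reported by `nonsaturation_rate()`. For the sum
rule a pixel is non-saturated when $|\sum_i P_i| < \tau$. The averaged
mask has no single pre-sigmoid logit, so for the averaging rule the
definition moves to the probability domain: non-saturated when the
averaged probability lies strictly inside
$(\sigma(-\tau), \sigma(\tau))$. This choice makes the two rules
coincide exactly at $n = 1$, which is the behaviour a single-head model
must show (its averaged and summed outputs are the same grid). Rates are
pooled over all pixels of all images — one rate per model over a test
set, not a mean of per-image rates.

### Ensemble weighting

With methods of unequal member counts (say 8 CNN members next to 4 + 4
transformer members), equal per-member weights would let the largest
method dominate. `equal_method_weights()` assigns a member of method $m$
the weight $1/(M \cdot n_m)$, so each method's total is $1/M$ and the
weights sum to 1. The underlying English statement ("each method
weighted so that its weight in the fusion is equal to the other
methods") admits more than one reading; the equal-per-method-total
reading is the only one consistent with ensembles of unequal member
counts, and is adopted as a design decision. `fuse()` normalizes
whatever weights it receives, so spec files may carry plain integers.

## Metrics and the evaluation protocol

Dice and IoU are computed per image on binary masks and averaged over
the set. Both are defined as 1 when prediction and truth are both empty:
scoring a correct "no polyp" call as 0 would penalise precisely the
behaviour the removed normalization layer makes possible. Binarization
uses strict `>` at 0.5 by default — the sigmoid decision boundary; the
tie at exactly 0.5 goes to background.

The resolution protocol mirrors training practice for these networks:
images are resized to 352 × 352 (bilinear) for inference, and predicted
probability masks are scaled back to the ground truth's native size
before thresholding and scoring. Bilinear interpolation is used for
probability masks (values stay in $[0,1]$ up to rounding, which is
clipped), nearest-neighbor for binary masks (preserves binarity). The
interpolation kernel for restoration is not pinned down by the protocol
description; bilinear is the package's choice and the round-trip error
against a smooth analytic field is bounded in the test suite.

## The structure-loss family

Training losses are included as pure functions so an external trainer
can lift them; no gradients are provided. The pixel weights are
$$w = 1 + \lambda\,\bigl|\mathrm{avgpool}_{31\times31}(T) - T\bigr|,
\qquad \lambda = 5,$$
computed with stride 1, same-size output and replicated edges. The
pooled mask equals the mask away from the boundary, so $w = 1$ there and
$w > 1$ exactly where the window straddles the boundary: the loss
concentrates on edges. The $31\times31$/$\lambda=5$ convention is the
one used by the structure-loss lineage of the base networks; both are
arguments (`kernel`, `lam`). The pooling is implemented with a
summed-area table, which is exact for binary inputs and remains
well-defined when the kernel exceeds the grid (small test fixtures).

The weighted BCE is printed in the two-class form
$-\sum_i \sum_k w_{ik} T_{ik} \log P_{ik}$; with $K = 2$ and the
background class as the complement ($P_{i,\mathrm{bg}} = 1 - P_{i,\mathrm{fg}}$,
both classes sharing the pixel weight) this equals full weighted binary
cross-entropy, and that is how it is implemented. With two classes
softmax and sigmoid coincide, so sigmoid is used throughout. The
weighted IoU loss
$$1 - \frac{1 + \sum_{i,k} w_{ik} T_{ik} Y_{ik}}
          {1 + \sum_{i,k} w_{ik} (T_{ik} + Y_{ik} - T_{ik} Y_{ik})}$$
keeps the $+1$ smoothing in numerator and denominator, so an empty truth
predicted empty scores exactly 0 rather than $0/0$. Reductions: the IoU
term is a ratio and needs none; the BCE term is reported as a mean over
pixels so values are resolution-independent. Predictions are clipped to
$[10^{-7}, 1 - 10^{-7}]$ before the logarithm.

## Augmentation strategies

DA1 produces exactly 3 synthetic pairs — up/down flip, left/right flip,
90° counterclockwise rotation — as index permutations (no resampling),
applied identically to image and mask. DA2 produces exactly 13. The
authoritative 13-transform inventory lives in the lineage's prior work
and is not enumerated in full anywhere this package can cite, so the
set here is fixed as: the two flips, both quarter turns, a random
rotation within ±35°, a shear (±0.2), a scale (0.8–1.2 with crop/pad),
an elastic warp, motion blur, Gaussian blur, a shadow polygon overlay,
brightness/contrast jitter, and Gaussian noise — honouring the printed
count and the named examples (motion blur, shadows). Geometric members
transform the mask with nearest-neighbor interpolation and background
fill; photometric members leave the mask untouched. All stochastic
parameters come from one private RNG stream per call, so
`da2(image, mask, seed)` is a pure function.

## What the synthetic generators emulate — and what they do not

`gen_scene()` renders elliptical blobs (axis jitter ±20%, random
orientation, fully inside the frame) with a radial intensity bump on a
textured, mucosa-tinted background; the truth is the union of blob
supports. `gen_head_stack()` turns a truth into $n$ heads via
$$\mathrm{head}_i = g_i \tanh(d / s_i) + b + \varepsilon,$$
where $d$ is the signed distance to the mask boundary in pixels
(positive inside; computed from two distance transforms). The $\tanh$
squashing gives heads the smooth, blurred boundary that real deeper
supervision heads visibly have; `boundary_softness` $s_i$ (pixels) sets
the width of that band and `logit_gain` $g_i$ the saturation plateau.
Gains of 25–160 with softness 6–20 reproduce the realistic regime:
per-image extrema from tens to hundreds of logits, near-total saturation
under the sum rule, and a small boundary band that only the averaging
rule keeps non-saturated. `gen_member_predictions()` degrades a truth
with a random translation, random false-positive/negative blobs and
smooth confidence noise, independently per member — the structure that
makes fusion provably useful, since independent errors dilute under
averaging.

These generators target *statistical* structure only: logit magnitudes,
boundary softness, member diversity, objectless frames. They do not
attempt photorealistic endoscopy (specularities, instruments,
picture-in-picture insets), correlated member errors from shared
training data, or the domain shift between acquisition devices. Passing
tests therefore demonstrate that the fusion algebra, diagnostics and
protocol behave as specified — not that any particular Dice level
transfers to real colonoscopy data, which requires trained networks and
is out of scope here.

## Numerical choices and degenerate inputs

* Logit stacks are stored as uncompressed multi-page float32 TIFF
  (read via libtiff); one write–read pass is lossless to float32
  precision and idempotent thereafter. PNG masks are 8-bit; probability
  masks are quantized only on export.
* Grayscale PNGs binarize at the 8-bit midpoint (`> 127`), matching
  nominally $\{0, 255\}$ ground truths.
* `minmax_normalize()` on a constant mask raises; `fuse()` rejects
  all-zero weights; `evaluate()` errors on empty or unpaired
  directories rather than returning a silent 0.
* Ellipse blobs are placed with a margin so they fit entirely in the
  frame; a requested object larger than the frame is an error.
* All generators save and restore the caller's RNG state; nothing in
  the package touches the global stream.

## Problem sizes

The test suite and the acceptance script run on 64–150 px synthetic
frames, stacks of up to 4 heads, 8-member ensembles, 50-scene
Monte-Carlo comparisons, and 1,000 random 5 × 5 mask pairs for the
Dice–IoU identity — sizes at which every property asserted (algebraic
identities, Jensen ordering of the head rules, rate directions,
ensemble benefit, end-to-end Dice) is already stable across seeds.

## Known limitations

* No trained networks, checkpoints or GPU inference: the package
  consumes logits, it does not produce them. Absolute benchmark scores
  on the public polyp datasets are consequently not reproducible here.
* The DA2 transform inventory is a faithful stand-in for a count-13
  strategy, not a bit-exact reimplementation of the original.
* Losses are evaluation-only (no autodiff).
* Per-pixel weighted voting and test-time augmentation are deliberately
  absent; they belong to other ensemble designs.
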