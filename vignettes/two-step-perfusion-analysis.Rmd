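---
title: "Two-step analysis of microvascular perfusion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step analysis of microvascular perfusion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Intravital video microscopy (IVM) records transilluminated living tissue at
video rate; red blood cells (RBCs) absorb light, so a perfused capillary
appears as a tube of moving dark blobs and a non-perfused one as a static
dark tube, a faint structure, or nothing at all. Quantifying how many
vessel segments actually carry flow is the core readout for microvascular
dysfunction studies, and doing it by eye — frame by frame, video by video —
is slow and error-prone.

`microflow` automates the two discrete judgements a human analyst makes:

1. **Where are the vessels?** (step 1, geometry) — segment vessel-like
   curvilinear structures from a motion-stabilized, contrast-enhanced
   temporal sum-of-absolute-differences (SAD) image.
2. **Does each one flow?** (step 2, function) — classify every
   intersection between a vessel and a superimposed reference grid with a
   small spatio-temporal 3D convolutional network (3D-CNN), then decide
   per crossing by majority over its cross-section pixels.

## Preprocessing

The SAD image collects, per pixel, the absolute intensity differences
between consecutive frames over the recording:

$$\mathrm{SAD}(r,c) = \sum_{i\ge 2} \left| I_i(r,c) - I_{i-1}(r,c) \right|.$$

Pixels crossed by moving RBCs flicker and accumulate large sums; static
tissue accumulates only noise. Differences are taken in double precision,
so integer camera counts cannot wrap.

Before summation, frames with tissue motion are rejected. A block-matching
estimator compares every frame against the first: blocks (default 32 px,
tiled with 50% overlap) search exhaustively over integer shifts within
±8 px for the minimum mean absolute difference, and the per-frame global
displacement is the median over blocks — the median deliberately ignores
local RBC motion, which must not count as tissue motion. The *motion
velocity* of a frame is defined here as the frame-to-frame change of that
global displacement times the frame rate (px/s); frames above the
threshold (default 0.3 px/s) are dropped, and the difference across a
splice is taken between the two surviving neighbors. Two remarks on this
definition are recorded rather than asserted as the original authors'
intent: the velocity baseline is not stated in the source description, and
at 32.5 frames/s a 0.3 px/s gate corresponds to inter-frame shifts below
the resolution of integer block matching, so the gate acts as a reject
filter for frames whose displacement estimate jumps by a whole pixel. The
threshold is a config value (`velocity_threshold_px_per_s`).

The stabilized SAD image is then contrast-enhanced with CLAHE
(contrast-limited adaptive histogram equalization) after rescaling to the
unit range. The clip limit is expressed as a fraction of the per-tile
histogram mass (default 0.01, i.e. 2.56× the mean bin content at 256
bins) on an 8×8 tile grid; both are configurable because no values are
prescribed in the source.

## Step 1: curvilinear segmentation

Vessels are extracted with a Steger-style unbiased curvilinear detector:
Gaussian-derivative filters at scale $\sigma$ give the gradient and
Hessian at every pixel; the ridge normal is the eigenvector of the
largest-magnitude Hessian eigenvalue; and a pixel emits a (sub-pixel)
ridge point when the directional derivative along the normal has its
second-order Taylor zero within half a pixel of the center and the
eigenvalue is negative (bright line) with magnitude above threshold.
Hysteresis keeps weak candidate pixels only when 8-connected to a strong
one.

Numerical choices worth noting:

* **Discrete derivative kernels are moment-normalized**: the sampled
  first-derivative kernel is scaled to unit response on a ramp, the
  second-derivative kernel to zero response on constants and response 2 on
  $x^2$. Without this, truncation error produces a small spurious Hessian
  on flat images and a constant image yields thousands of "ridges".
* **Isotropic acceptance** $|t| \le 0.5$: the separate per-axis test
  accepts pixels up to $0.7$ px off-crest for diagonal lines, doubling
  the point count at 45°; the isotropic rule makes detection density
  orientation-independent. A hair of slack ($10^{-6}$) lets a crest lying
  exactly between two pixel rows be claimed by both neighbors instead of
  neither.
* **Scale from width**: $\sigma = w/(2\sqrt{3})$ from the classical
  width–scale relation, with the expected vessel width `width_px`
  (default 4 px) exposed rather than $\sigma$ itself.
* **Quantile thresholds**: SAD dynamic range varies per video, so the
  hysteresis thresholds default to quantiles of the full per-pixel
  ridge-strength distribution (zeros included), `low_q = 0.90`,
  `high_q = 0.97`. Quantiles over only the positive strengths were tried
  first and rejected: when vessels occupy a few percent of the image,
  conditioning on positivity discards most true ridge pixels. Absolute
  thresholds can be passed instead.

The binary map is then closed morphologically (radius 1, i.e. the full
3×3 neighborhood — exactly what is needed to bridge the 1-px
discontinuities this step is meant to repair) and every 8-connected
component with fewer than 4 pixels is removed. "Shorter than 4 pixels" is
read as component pixel count < 4; whether the original rule measured
skeleton length or area is unstated, so the boundary is exposed as
`min_segment_px`. Post-processing is idempotent, closing never removes
pixels, and pruning never adds them — all asserted in the test suite.

## Sampling: the reference grid

Three equidistant horizontal and three vertical lines (configurable) are
placed at `round(k·H/(n+1))`. Each maximal run of mask-true pixels along a
line is one *crossing* — the cross-section of a vessel where it meets the
line — and every cross-section pixel contributes one data block: a
16×16 px window over the first 200 surviving frames. The even window has
no center pixel; the convention (fixed for reproducibility) puts the
target pixel at offset (8, 8), spanning `p−8 … p+7`. Pixels closer than
8 px to the border are skipped, not padded: padding would fabricate
temporal signal for the classifier.

## Step 2: the 3D-CNN

The block classifier is a small spatio-temporal CNN: eight 7×7×7 filters,
eight 5×5×5 filters (both valid, stride 1, ReLU), one 2×2×2 max-pool, a
flatten — exactly 6840 long for a 16×16×200 block, the arithmetic anchor
of the architecture — a 128-unit ReLU hidden layer, and a 2-way soft-max
read as the flow probability. Valid/stride-1/pool-2 is the only padding
combination that reproduces the 6840 figure, so it is forced; the hidden
width and dense channel mixing of the second convolution are conventional
choices recorded here, not claims about the original implementation.

Per-pixel probabilities are thresholded at 0.5 (a probability of exactly
0.5 counts as flowing) and the crossing is declared flowing when strictly
more than 50% of its cross-section pixels are flowing — an exactly-half
split is non-flowing.

Training minimizes the categorical cross-entropy with Adadelta
($\rho = 0.95$, $\epsilon = 10^{-6}$, no learning-rate tuning) in batches
of 30 for up to 100 epochs, stopping early when the training loss changes
by less than $10^{-4}$ for 3 consecutive epochs — the operational reading
of "until the weights converge". Two numerical details matter at small
problem sizes:

* **Input centering.** Blocks are min-max normalized to $[0,1]$ per block
  (a constant block maps to zeros); the network then subtracts 0.5 as its
  first fixed operation. Uncentered inputs give every neuron a large
  common-mode response that dwarfs the per-sample differences, and
  gradient descent stalls in the "predict the base rate" plateau.
* **He initialization** for the ReLU layers (uniform with limit
  $\sqrt{6/\mathrm{fan_{in}}}$), Glorot for the soft-max head. With
  Glorot everywhere, activations shrink layer by layer and the same
  plateau appears.

Both effects were found the hard way: gradients verified correct by finite
differences (that check is a permanent test) while training sat at
chance. All randomness — weight draws and batch shuffling — derives from
one config seed, so training is reproducible on one platform.

The convolutions are evaluated as im2col + single-precision GEMM in
C++ (RcppArmadillo); no deep-learning framework is involved. The
logistic-regression baseline flattens the same normalized blocks
(51,200 features at full temporal depth) into an L2-regularized logistic
model (glmnet, fixed ridge penalty), sharing the prediction and decision
interface.

Ten-fold cross-validation for architecture selection is available as
`cross_validate_cnn()` but is not run by any default — it multiplies the
training cost by the fold count, and the architecture here is fixed to
the published one.

## The synthetic phantom

The generator emulates what the SAD pipeline actually consumes:

* vessels are smooth random splines with width 3–6 px, rendered as
  Gaussian-profile absorbing tubes on a bright field (background 0.85 on
  the unit scale);
* perfused vessels carry dark blobs 2–6 px long with exponential gap
  spacing scaled by an RBC density in 0.3–0.7, advected at 0.5–3 px/frame;
  absorption saturates (per-pixel maximum over overlapping blobs, not the
  sum — summation drives intensities into the clamp and inverts the SAD
  contrast, a defect found during development);
* non-perfused vessels are static tubes at full contrast (a stagnant RBC
  column), optionally with low-amplitude temporal flicker
  (`static_jitter_sd`, default 0.05) emulating the Brownian jiggle of a
  stagnant column — this is what makes non-flowing vessels faintly
  visible in real SAD images, and it is the designed source of step-1
  "artifacts" that step 2 must reject;
* sensor noise is additive Gaussian (default sd 0.01) with an optional
  intensity-proportional shot-noise term; global drift is a sub-pixel
  translation; a few static dark artifact spots complete the scene.

With *all* stochastic terms zero (sensor noise, shot noise, stagnant
jitter, drift), temporal change is exactly confined to perfused tubes —
asserted bit-exactly in the tests. The phantom does **not** model
hemodynamics, oxygen transport, leukocytes, vessel walls, focus drift, or
the depth-dependent blur of real tissue; a classifier that separates
phantom crossings demonstrates that the pipeline wiring, geometry and
learning machinery work, not that the trained weights transfer to animal
data.

Default geometry is 256×256 px at 32.5 frames/s — a quarter-scale desk
version of the nominal 1000×1000 px field of view.

## The built-in benchmark

`synthetic_benchmark()` is the package's end-to-end study: 16 phantom
videos (215 frames each, so the motion gate may drop a few and 200
survive), every video pushed through preprocessing and segmentation, all
grid crossings labeled from ground truth (crossings with no true vessel
nearby are labeled non-flowing — they are artifacts, the very thing the
classifier must reject), the 3D-CNN trained on 12 videos (≤12 epochs)
and evaluated on the held-out 4, against the logistic baseline on the
same split. Videos are never shared between splits, mirroring the
original train/test design. This yields on the order of 300 labeled
crossings. The suite asserts vessel-level CNN accuracy ≥ 0.9, CNN ≥
baseline (the published ordering), and completion within the stated
runtime envelope; the acceptance script recomputes the same quantities
plus the pooled end-to-end detection and error rates.

The published real-data figures (90% test accuracy, 83% end-to-end
detection, 3.5% error) require the original animal videos and labels and
are out of scope here; the benchmark numbers are properties of the
phantom, not reproductions of those values.

## Known limitations

* Integer-only block matching: sub-pixel drift below ~1 px/frame is
  treated as noise, consistent with the gate's reject-filter role.
* The ridge detector marks pixels (no explicit sub-pixel polyline
  linking); downstream stages only consume the binary map.
* Crossing-level decisions are independent; no vessel tracking between
  grid lines, no diameter or velocity estimation.
* The logistic baseline is fit at a single fixed ridge penalty, not
  cross-validated; it is a reference point, not a tuned competitor.
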