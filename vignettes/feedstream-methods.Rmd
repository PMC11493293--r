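---
title: "Three-stream feeding-intensity discrimination: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-stream feeding-intensity discrimination: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`feedstream` classifies the feeding intensity of a farmed-fish school from
overhead surface video into `none`, `weak` and `strong`. This vignette
documents the models it implements, the assumptions behind them, the tunable
parameters, and the design choices made where the method leaves the design
open. Nothing here reports an empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

## The three streams

The premise of the architecture is that feeding intensity expresses itself
through three loosely coupled channels — motion, splash area, and surface
texture — and that a classifier per channel, fused late at the decision
level, is more robust than any single view.

### Temporal stream: optical flow

A moving surface point is assumed to keep its brightness between consecutive
frames (brightness constancy). First-order expansion of that assumption gives
the flow constraint

$$I_x u + I_y v + I_t = 0,$$

one equation for the two unknown velocity components $(u, v)$ per pixel. The
constraint alone is under-determined (the aperture problem), so the field is
regularized with a quadratic smoothness penalty and the global energy

$$E(u, v) = \sum \left(I_x u + I_y v + I_t\right)^2
  + \alpha^2 \sum \left(\|\nabla u\|^2 + \|\nabla v\|^2\right)$$

is minimized — the classical global-smoothness (Horn–Schunck-type)
formulation, chosen because it adds the fewest assumptions beyond the
constraint itself. Discrete gradients: $I_x, I_y$ are central differences
averaged over the two frames (replicated borders), $I_t$ is the plain frame
difference. RGB frames are reduced to gray by the Rec. 601 luma weights.

**Solver.** Each Gauss–Seidel sweep solves every pixel's 2×2 normal-equation
system exactly given its neighbors — coordinate descent on $E$ — so the
energy is non-increasing by construction (a property the tests assert; a
Jacobi sweep would not guarantee it). Defaults: $\alpha = 15$, 100 sweeps,
zero initialization. These defaults recover synthetic translations of up to
3 px with mean endpoint error below 0.5 px on smooth textures. Two
limitations are documented rather than "fixed": the linearized constraint is
only valid for displacements of a few pixels at the image's spatial
frequency (no coarse-to-fine pyramid is implemented — out of scope), and
uniform brightness changes violate constancy, so no robustness to them is
claimed. More sweeps are not automatically better for large shifts: full
convergence of the quadratic energy slightly increases the bias that early
stopping masks, which is why the default stays at 100.

**Rendering.** A flow field becomes an RGB image by the standard color-wheel
convention: hue encodes `atan2(v, u)` over the full wheel, saturation encodes
magnitude relative to `max_magnitude`, value stays at 1. Zero flow is
therefore white, and opposite directions sit 180° apart. The pipeline fixes
`max_magnitude = 5` px/frame rather than per-image auto-scaling so that
intensity is comparable across frames — with auto-scaling, a calm scene's
noise-driven flow would be amplified to full saturation and the class signal
in overall color intensity would be destroyed.

### Spatial stream: splash binarization

Feeding splashes read as bright, unsaturated (white) specular regions. The
default rule marks a pixel foreground iff its saturation is strictly below
$T_S$ and its value strictly above $T_V$ in the HSV representation
(defaults $T_S = 60$, $T_V = 200$ on the 0–255 scale, which isolate the
generator's near-255 splash disks against a mid-gray background). The method
is also described in terms of mean-gray thresholding, so a `mean_gray` mode
(foreground where gray ≥ image mean, ties to foreground) is provided as an
explicit alternative; the dual-threshold rule is the default because it is
the printed formula. Output is `{0, 255}` rather than `{0, 1}` so binary
frames round-trip through image files. No morphology or adaptive
thresholding is applied — deliberately absent from the method.

### Statistical stream: GLCM texture

The gray-level co-occurrence matrix $P(i, j)$ counts how often gray level
$i$ co-occurs with level $j$ at a fixed pixel offset, here distance 10 at
angles 0°, 45°, 90° and 135° after uniform quantization to 8 levels
(`floor(gray × 8 / 256)`). Counts are normalized to probabilities before the
statistics are computed: energy $\sum P^2$, entropy $-\sum P \log_2 P$ (with
$0\log 0 := 0$), contrast $\sum (i-j)^2 P$, and correlation
$(\sum ijP - \mu_x\mu_y)/(\sigma_x\sigma_y)$ with marginal moments, defined
as 0 for degenerate marginals. Normalization is required for the standard
ranges (energy ≤ 1, entropy bounded by $\log_2 L^2$); raw counts would not
satisfy them. The per-angle statistics concatenate angle-major into the
16-value descriptor.

Conventions chosen where the method is silent: matrices are one-directional
(asymmetric) by default since the counting definition is one-directional,
with a symmetric mode available; entropy defaults to bits (base 2),
configurable; angle offsets follow common image-row-major practice with 45°
pointing up-right, fixed so the descriptor ordering is bit-stable. The
printed correlation formula contains obvious typographical slips (a doubled
$\mu_x$ and misplaced bracket); the standard marginal-moment correlation is
implemented, matching the formula's described meaning.

## The classifiers

**Residual 2D backbone** (temporal and spatial streams, independent
weights). Stem of one 7×7 stride-2 convolution with batch normalization and
a 3×3 stride-2 max-pool, four stages of bottleneck residual units
(1×1 reduce → 3×3 → 1×1 expand ×4, projection shortcut on shape change),
global average pooling, and a fully connected softmax. At the canonical
block counts (3, 4, 6, 3) this is the familiar 50-layer network:
$1 + 3(3+4+6+3) = 49$ convolutions plus the classifier, and a 224×224×3
input reaches the pool as a 7×7×2048 map. The package asserts these counts
as closed-form structural invariants for any block configuration.

A first-class **reduced profile** — block counts (1,1,1,1), base width 8,
64×64 input, last-stage stride 1 — is the desk-scale variant used by the
test suite and the default pipeline. The last-stage stride of 1 leaves a
4×4 (not 2×2) final feature map so that class activation maps retain usable
spatial resolution at 64×64. The full-width profile keeps the canonical
strides.

**1D convolutional network** (GLCM stream). Convolution runs along the
16-long descriptor only: two blocks of (32 filters, kernel 3, pool 2) and
(64, 3, 2), flatten, dense 64, softmax 3. The exact layer sizes of the
original diagram are not legible, so these defaults were chosen to train in
seconds on 16-long vectors; they are fully configurable, and construction
validates that no kernel or pool is wider than the remaining vector.

**Training.** Mini-batch cross-entropy with the adaptive-moment (Adam)
optimizer, learning rate $10^{-3}$, batch 32, 20 epochs, random (He)
initialization, no augmentation, no pretraining — the method names none of
these, so they are package defaults held in one configuration object.
Training-set loss/accuracy in the history are averages of the mini-batch
forward passes; validation metrics are full inference-mode passes. All
randomness (initialization, shuffling) is seeded; on a fixed-threading BLAS
a fixed seed reproduces the history bit for bit. The layers (im2col
convolution, batch norm, max-pool, dense, softmax) are implemented in the
package with the convolution and pooling kernels in C++ — no deep-learning
framework is involved — and every layer's backward pass is verified against
central finite differences in the test suite.

Classification is **per frame** (each flow image, binary frame or GLCM
vector is one sample); clip-level decisions are formed afterwards by
plurality over the clip's fused frame labels, with ties resolved toward the
stronger class — a deliberate policy choice for feeding control, which
prefers over-reading to under-reading feed demand.

## Fusion and evaluation

The method is described both as score-level fusion and as voting; the
implemented rule honors both readings: majority vote over the three stream
argmax labels, with a three-way disagreement resolved by the largest summed
score triple and exact ties by the fixed class order (none, weak, strong).
Pure summed-score fusion is available as an option and is what two-stream
combinations in the ablation grid use. The voting rule is tested against
exhaustive evaluation of all 27 argmax combinations.

Metrics come from the one-vs-rest confusion-matrix counts: accuracy
$(TP+TN)/(TP+FN+FP+TN)$ pooled over decisions, per-class precision, recall
and F1, macro (unweighted class mean; zero-support classes excluded with a
warning) and micro averages. Micro-precision equals micro-recall equals
accuracy for single-label multiclass — asserted as an identity. The
averaging convention behind the method's single reported F1/recall values is
unstated; macro is the default reading here, micro is provided.

## The synthetic scene generator

No public corpus accompanies the method, so the generator is the package's
study system. It emulates an overhead camera over a tank: a mid-gray water
background (level 120), `n_fish` dark ellipses advected by a
heading-persistent random walk (mean step `motion_scale` px/frame, reflecting
borders), splashes as near-white (≥ 250) disks arriving as a Poisson process
(`splash_rate`/frame, lifetime 2–4 frames, radius jittered ±30%), and i.i.d.
Gaussian surface shimmer, clipped to [0, 255]. Class presets:

| preset | motion_scale | splash_rate | splash_radius | noise σ |
|--------|-------------:|------------:|--------------:|--------:|
| none   | 0            | 0           | 0             | 1       |
| weak   | 1.5          | 0.8         | 3             | 2.5     |
| strong | 4            | 4           | 6             | 5       |

The class definitions fix the ordering and the `none` zeros; the magnitudes
are free parameters chosen once so that the three diagnostics the streams
rely on (inter-frame motion energy, binarized splash fraction, texture
statistics) order none < weak < strong robustly across seeds — properties
the test suite checks over 20 seeds. The noise ordering mirrors the visual
shimmer of agitated water and gives the texture stream its signal.
Everything is driven by one integer seed (per-sequence seeds derive from the
master seed by fixed integer hashing, so datasets are order-independent),
and identical configurations render bit-identical frames.

What the generator deliberately does **not** model: photorealistic water
optics, fish articulation or occlusion, lighting drift, camera shake, or
background structure (tank walls, lamps) — the features that make real
footage hard. Passing the synthetic suite therefore demonstrates that the
implementation is correct and that the architecture can exploit the three
signals; it does not certify field accuracy on real video.

## Problem sizes and numerical choices

The default pipeline configuration is the package's study condition: 20
clips per class of ten 64×64 frames (≈ 540 flow images, 600 binary frames,
600 descriptors), clip-level 70/20/10 stratified split via largest-remainder
quotas with a seeded shuffle, reduced backbone, 20 epochs per stream. The
scale was chosen so a complete run takes a few minutes on one CPU core while
leaving every stage statistically meaningful.

Degenerate inputs are handled explicitly: empty images, mixed frame sizes,
missing classes, all-zero confusion matrices, images smaller than the GLCM
offset and kernels wider than the 1D vector raise classed errors; a constant
activation map normalizes to zeros rather than NaN; flow on identical frames
is exactly zero; correlation of a degenerate GLCM marginal is 0 by
definition. Clip-level splitting is the default split unit because
frame-level splitting of 24 fps video places near-duplicate frames on both
sides of the train/test boundary; frame-level splitting remains available
for faithfulness experiments.

## Known limitations

* The flow solver is single-scale; displacements well beyond ~3 px at the
  texture's spatial frequency are under-estimated.
* Batch-norm running statistics come from small-batch streams; with very few
  batches per epoch, early-epoch validation accuracy can fluctuate before
  settling.
* The voting fusion can score below the best two-stream summed-score
  combination on easy synthetic data (votes discard score confidence); the
  ablation grid makes this visible rather than hiding it.
* Video container decoding is not included; clips enter as PNG frame
  directories.
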