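---
title: "Multi-branch detection of hip-arthroplasty complications: models, phantoms and protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-branch detection of hip-arthroplasty complications: models, phantoms and protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic phantom generator does and does not emulate, and the numerical
and design choices made where the design was genuinely open.

## The problem

Radiographs of failed total hip arthroplasties are read for seven binary
findings at once: aseptic loosening (a radiolucent line at the
bone–implant interface), periprosthetic osteolysis (lytic dark regions
around the implant), periprosthetic fracture, dislocation (head outside
the cup), polyethylene wear (head eccentric within the cup), infection,
and a residual "other" category. Findings co-occur — osteolysis in
particular precedes and accompanies loosening — so the task is multi-label
with correlated labels and strong class imbalance: in a 443-image revision
cohort the per-label positive counts run from 269 (loosening) down to 25
(infection). Inputs are assumed pre-cropped to the periprosthetic region
by an upstream detector; cropping is outside this package's scope.

## Model

The classifier is a backbone plus two optional streams and an optional
scoring head; every ablation subset is a valid `model_config()`.

**Backbone.** A standard convolutional classifier truncated to its
1/32-resolution feature map. All canonical architectures are built from
the package's layer primitives, so one declarative definition yields the
forward pass, the exact trainable-parameter count and the analytic MAC
count. With 7-way heads the counts reproduce the published figures
(ResNet-18 11.18 M, ResNet-50 23.52 M, DenseNet-121 6.96 M, …), which
pins the interpretation that the final fully-connected layer, and only
that layer, is replaced.

**Global feature stream.** `patch_embed` cuts the image into `patch ×
patch` pixels tokens with a strided convolution (zero-padding images that
do not divide evenly), flattens and layer-normalises. Three
`global_feature_block`s follow. Each block applies patch merging (2×2
concatenation, layer norm, bias-free linear `4C → 2C`) and then two
residual sublayers: layer norm + windowed multi-head self-attention, and
layer norm + linear–GELU–linear (hidden width `4C`). The attention
formula is the scaled dot product `softmax(QKᵀ/√d_k)V` restricted to
non-overlapping `M × M` token windows; the middle block uses shifted
windows (cyclic shift by `⌊M/2⌋` with wrap-around pairs masked at −10⁹
logits) so information crosses window boundaries. The published
formulation of the block is compact to the point of ambiguity about
sublayer order; we implement the canonical pre-norm arrangement of the
windowed-attention design the block is stated to mirror, and treat the
printed formula as shorthand. Relative-position bias tables are omitted;
they are a refinement the block description does not mention, and the
parameter budget matches without them. The stream consumes the raw image
(not a backbone stage), which is the reading consistent with the
architecture diagram.

Defaults: patch 4, embedding 96, window 7, heads (3, 6, 12). At 224-pixel
input the grid runs 56² → 28² → 14² → 7² with widths 96 → 192 → 384 →
768, and the stream adds ≈ 10.9 M parameters — near the ≈ 9.5 M delta the
published ablation table implies. The achieved count is reported, never
forced.

**Channel feature stream.** A 7×7 stride-2 convolution to `width`
channels, batch norm, ReLU and a 3×3 stride-2 max-pool, then three stages
of stride-2 3×3 convolution + batch norm + ReLU, each re-scaled by
dual-pool channel attention: average-pool and max-pool channel
descriptors pass through one shared bias-free bottleneck MLP
(`C → C/r → C`, ReLU inside), the two maps are added and squashed by a
sigmoid, and the gates multiply the stage output per channel. The
published equation prints only the average-pool path while the text and
figure describe dual pooling with addition; we implement the dual-pool
form and regard the equation as abridged. Stage width is kept constant at
64 channels: the published parameter delta for this stream (≈ 0.07 M)
rules out widening stages, and a constant-width stride-2 plan is the
simplest layout consistent with it.

**MC-CSRA head.** Final scores are `(GAP(x)·W_fc + b)·Coef`: global
average pooling, a fully-connected layer producing per-label base scores,
then a trainable `K × K` coefficient matrix whose column `k` mixes base
scores into the final score of label `k`. The head equation carries no
explicit bias; we read "the fully-connected layer" as the standard layer
with bias applied before the coefficients, because that makes the
identity-initialised head *exactly* the plain pooled-linear head — an
equivalence the test suite asserts bit-for-bit, and which keeps the
head-on/head-off ablation continuous. Initialisation is identity plus
small Gaussian noise (sd 0.01) by default; `correlation_report()` returns
the learned coefficients with label-named axes and their deviation from
identity. The original class-specific residual-attention design also has
spatial-attention and temperature machinery; the variant implemented here
is the pooling + FC + coefficients form and nothing more, taking the
stated equation literally.

**Fusion.** Enabled streams all emit 1/32-resolution maps (hence
`input_size` must be a multiple of 32) and are concatenated channel-wise
before the head. Concatenation preserves per-stream information and keeps
the head input well-defined; the architecture diagram shows convergence
but not the operator, so this is a design choice of the package.

## Complexity accounting

`count_parameters()` sums trainable array elements (frozen sub-modules
excluded); `nn_trace()` propagates shapes analytically and counts one MAC
per multiply-accumulate: convolutions `out-positions × kernel-volume ×
in-channels/groups × out-channels`, linear layers `in × out`, batch/layer
norm one MAC per element (a fused scale-shift), activations and pooling
zero. Under this convention ResNet-18 at 224 px costs 1.82 GMACs,
matching the published cost table; that table's column is headed ×10⁶ but
its large-network entries are only consistent with ×10⁹ (GMACs), while
its MobileNetV3/EfficientNet entries really are ×10⁶ — we report GMACs
throughout. Inference time is measured as the mean of repeated
single-image forwards after one warm-up and is hardware-bound, so it is
reported but never asserted.

## Training protocol

Per-label binary cross-entropy on sigmoid logits (the loss is not stated
in the source description; per-label BCE is the standard choice consistent
with per-label 0.5 thresholding), optimised by Adam from learning rate
2e-4. "Reduced by 10% after 5 epochs if the validation loss remained the
same" is read as a reduce-on-plateau rule: factor 0.9, patience 5 epochs,
improvement tolerance 1e-4 on the validation loss. Early stopping
(patience unstated; default 10 epochs) restores the best-validation
parameters. Batch order reshuffles each epoch from a derived seed, so
training is bit-reproducible. Two experiment protocols exist side by
side, as described for the two tasks: five-fold cross-validation for the
7-label problem (`run_crossval()`, folds dealt round-robin after a seeded
shuffle — 443 records give test folds of 88–89 and training splits of
354–355; stratification is not applied because the source does not claim
it) and a 6:2:2 train/validation/test split for single-complication
binary tasks (`run_binary_task()`). Paired ablation arms trained with the
same seed share fold plans and batch orders, so metric deltas are
attributable to architecture. No data augmentation is applied (none is
described).

## Metrics

Average precision is non-interpolated: rank by descending score — ties
broken by sample index, a documented convention since AP is tie-sensitive
— and average the precision at the positive ranks. mAP averages over
classes; a class with zero positives in a fold has undefined AP and is
excluded with a warning rather than contributing zero, since the defining
sum is undefined at zero positives and the source is silent. Thresholded
metrics apply a 0.5 cut on sigmoid scores; ratios with empty denominators
report 0 with a warning; weighted variants use class-support weights. The
no-skill mAP baseline is estimated by simulation (random normal scores
against the same label matrix) because the multi-label chance level
depends on prevalences.

## The phantom generator

`phantom_spec()` defaults *are* the study conditions: 443 samples and
marginal label probabilities equal to the reported per-complication
counts (269, 158, 30, 28, 187, 25, 34 of 443). Labels are drawn from an
exact joint over the 2⁷ = 128 label states: independent Bernoulli
marginals re-weighted by symmetric pairwise odds multipliers and
normalised in closed form. The design sketch suggested Gibbs sampling
with the 128-state enumeration as its oracle; since the enumeration is
exact and trivially cheap, the package samples from it directly — the
sampler and the oracle coincide, removing an approximation rather than
adding one. `label_joint()` exposes the closed form for tests.

Rendering places a deterministic implant silhouette (stem wedge, neck,
head disc, cup arc, femoral cortices) on a 64-pixel canvas by default —
a size chosen so that hundreds of samples train in minutes on one CPU
while every primitive stays several pixels wide — and adds one primitive
per positive label: a radiolucent band along the stem border (loosening),
a lytic blob beside the proximal stem (osteolysis), a thin dark line
crossing the lateral cortex (fracture), a head drawn out of the cup
(dislocation), a superiorly shifted eccentric head (wear), mottled
predominantly-bright periosteal speckles (infection), and a corner marker
("other"). Geometry is jittered per sample within documented ranges to
avoid degenerate learnability, but each primitive stays inside a fixed
nominal region (`phantom_regions()`), and the regions are mutually
disjoint — so at zero noise a region-mean statistic separates positive
from negative renders perfectly, which is the generator's testable
fidelity contract. Gaussian pixel noise (sd 0.05 by default) is added
last and intensities are clipped to [0, 1].

What passing tests on phantoms do **not** show: the phantoms have none of
the projection physics, anatomical variability, exposure differences or
annotation noise of clinical radiographs, and their lesion cues are far
more stereotyped. Phantom experiments validate the machinery — data flow,
optimisation, metric computation, and the mechanism of the coefficient
head — not clinical performance. Published performance on the private
clinical dataset is correspondingly out of scope.

## Numerical choices and degenerate inputs

Tensors are plain double arrays (`H × W × C × N`); convolutions lower to
one BLAS product via im2col, and every layer implements an explicit
backward pass — all gradient-checked against central finite differences
at tolerance 1e-6. Batch norm uses biased batch variance in training and
running statistics (unbiased update) in evaluation, eps 1e-5. Windowed
attention shrinks its window to the grid when the grid is smaller and
drops the shift when only one window remains; a grid not divisible by the
effective window is an error, not a silent pad. Sigmoid gates are
mathematically inside (0, 1) but saturate in double precision for inputs
beyond ±37, so range assertions are made at realistic feature scales.
Images with an alpha channel are truncated to RGB; grayscale inputs are
replicated to three channels before ImageNet-style normalisation
(configurable), and the 224-pixel default input size is the one
calibration consistent with the published backbone MAC figure. When both
dislocation and wear are positive, both head displacements apply
(summed); the dislocation offset dominates, matching the clinical reading
that a dislocated joint cannot also be assessed for eccentricity.

## Problem sizes used by the shipped experiments

The test suite and acceptance script run scaled-down study conditions
chosen once for single-CPU tractability: 200–240 phantoms at 64 px with
noise 0.02, a tiny configuration (ResNet stem width 8, GFS embedding 8
with window 4, CFS width 16), learning rate 1e-3 (scaled up from the
full-model 2e-4 as is usual when widths shrink), batch 16, 5–6 epochs,
and 5 seeds with majority voting for the two stochastic checks (held-out
mAP above the simulated no-skill baseline; the injected
osteolysis–loosening coupling exceeding the median off-diagonal
coefficient magnitude).

## Known limitations

* Random initialisation only in practice: pretrained ImageNet weights can
  be loaded from a serialized state file, but no download machinery is
  included.
* The exact stream widths that reproduce the published 20.69/11.25/20.72 M
  totals are not recoverable from the description; the defaults land
  within 15% (22.17 M for the full configuration) and the achieved counts
  are always reported.
* JPEG input requires the optional EBImage dependency; PNG is native.
* The layer stack favours clarity over speed: it is adequate for the
  scaled-down experiments here, not for full-scale training runs.
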