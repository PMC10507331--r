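---
title: "Methods: lightweight prototype-mask segmentation of white blood cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lightweight prototype-mask segmentation of white blood cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Counting and delineating white blood cells (leukocytes) in stained
peripheral-blood smears is a routine step in leukemia work-ups. The hard
cases are touching or overlapping cells, blurred boundaries, and staining
variation between laboratories. Semantic segmentation merges adherent cells
into one region; instance segmentation keeps them apart, which is what this
package implements: a single-stage, prototype-mask detector specialized for
blood-smear images, with a deliberately small parameter budget so that it
remains deployable on modest hardware.

`wbcseg` contains the full pipeline in R: the network and its training loop
(on a small reverse-mode autodiff tape with Rcpp convolution kernels), a
synthetic smear generator that stands in for clinical data, COCO-protocol
mask-AP evaluation, exact parameter/FLOP accounting, and a command-line
front end.

## Architecture

The detector follows the YOLACT single-stage recipe: a backbone extracts
stage features C3-C5; a fusion neck produces five 256-channel pyramid
levels; a *prototype network* emits k full-image mask bases from the
highest-resolution level while a shared *prediction head* emits, per anchor,
class logits, box offsets, and k mask coefficients (tanh-bounded); each kept
detection's mask is `sigmoid(sum_j coef_j * prototype_j)`, cropped to its
box and thresholded strictly above 0.5.

Three design elements depart from the plain baseline:

**Ghost backbone.** Every 1x1 and 3x3 convolution inside the ResNet-50
residual bottlenecks is replaced by a Ghost module: a primary convolution
produces only `m` "intrinsic" channels, and a cheap 3x3 depthwise
convolution generates the remaining `c_out - m` channels from them
(round-robin over intrinsic maps), with channel normalization on each
branch and no convolution biases. The adjustment factor `S` sets
`m = round(c_out / S)` (at least 1), so `S = 1` degenerates exactly to the
standard convolution. The 7x7 stem and the downsample shortcuts stay
standard. We chose nearest-integer rounding for `m` (rather than ceiling)
after calibrating the bookkeeping against the published parameter budgets
of this backbone family; with it the feature extractor (classifier layer
excluded) counts 13.27 M, 8.15 M and 6.45 M parameters at S = 2, 4, 6,
against 25.56 M for standard ResNet-50 with its classifier. Inside a
bottleneck the first two Ghost modules carry ReLU on both branches; the
expansion module is linear so the residual sum stays signed — a necessary
deviation from "ReLU after every sub-convolution" that leaves parameter
counts untouched.

**Dual-stream fusion neck.** On top of the usual top-down pyramid
(`P5 = 1x1(C5)`, `P_k = 1x1(C_k) + up2(P_{k+1})`), a bottom-up path
re-injects shallow detail: `N3 = P3`; for k = 3, 4 a stride-2 3x3
convolution downsamples `N_k` to `M_k`, which is added element-wise to
`P_{k+1}` and smoothed by a 3x3 convolution to give `N_{k+1}`; N6 and N7
follow by further stride-2 convolutions from N5 and N6. (The source text
for N6/N7 contains a circular phrase — "obtained from N5 and N7" — which we
read as a typo for N5 and N6.) Upsampling is nearest-neighbour, resized to
the lateral map's exact size for odd shapes, never cropped. The plain-FPN
baseline remains reachable by `neck$type = "fpn"` (smoothed P3-P5 plus
P6/P7 by stride-2 convolutions); the two necks keep independent extra-level
convolutions.

**Dual-domain attention.** After each of N3-N7 (independent weights per
level, since weight sharing is nowhere claimed), channel attention is
computed in the frequency domain: the unnormalized 2D DCT-II components
Y(0,0), Y(0,1), Y(1,0) of each channel each pass through one shared
two-layer MLP (C -> ceil(C/r) with ReLU -> C, r = 16), are summed, and a
sigmoid gives per-channel weights in (0,1). Y(0,0) equals `H*W` times
global average pooling, which is why plain GAP-based channel attention is
the special case of a single spectral component. A CBAM-style spatial
module follows in series: channel-wise mean and max maps through a 7x7
convolution and sigmoid. Masking order is channel-then-spatial. The
attended levels feed the prediction head only; the prototype network reads
N3 *before* attention, matching the published wiring that routes the
attention block to the mask-coefficient branch. Config toggles reproduce
the published ablations: `cbam` (GAP+GMP), the component subsets
{Y00}, {Y00,Y01}, {Y00,Y01,Y10} (default), {...,Y11}, and `none`.

On a pyramid level smaller than a requested frequency (a 1x1 top level in
the reduced profile) that component does not exist and is skipped; the DC
component is always available.

## Published-table bookkeeping

Two bookkeeping decisions make the parameter table well-posed, and both are
documented rather than silent. First, the lightweight rows count the
*feature extractor without the classification layer* (the detector never
carries one), while the standard-ResNet row includes its 1000-way
classifier; no construction with the classifier attached can reach the
printed lightweight budgets, and the source's own description of the
backbone excludes the fully connected layer. Second, the three lightweight
settings are S = 2, 4 and 6 — the accompanying text states these values
even though one table row is labelled 8; the printed counts are mutually
consistent only for S = 6, and our S = 8 build (5.59 M) confirms the label
cannot be right. FLOPs are counted analytically as multiply-adds
(convolution: `k^2 C_in C_out H_out W_out / groups`; normalization,
activations and pooling excluded) at 550 x 550 input, under which standard
ResNet-50 lands at 25.46 G against the printed 25.66 G and the S = 4
backbone at 8.96 G against 9.19 G.

## Training

Anchors (three aspect ratios 1, 1/2, 2; one scale per level) are matched at
IoU >= 0.5 (positive) / < 0.4 (negative), with each ground truth's argmax
anchor forced positive. The loss is the standard single-stage composite:
softmax cross-entropy with 3:1 online hard-negative mining, smooth-L1 on
SSD-encoded box offsets (variances 0.1/0.2), and per-instance BCE on
assembled prototype masks cropped to the ground-truth box and normalized by
its area, weighted 1 : 1.5 : 6.125. The full-scale optimizer configuration
is SGD, learning rate 0.001, batch 16, 600 epochs; momentum 0.9 and weight
decay 5e-4 are conventional defaults for this family (the source states
only optimizer, rate, batch and epochs), and no learning-rate schedule is
applied since only the initial rate is given.

Normalization layers compute statistics over the spatial extent of the
current image during training (exactly batch norm at batch size one), with
running averages for inference. This makes training deterministic under a
seed and independent of how a batch is split for gradient accumulation; it
is a deliberate simplification of cross-image batch statistics. Two
stabilizers are applied that the source does not discuss but that any
from-scratch training (no ImageNet pre-training is claimed, and none is
used) requires: the final prediction branches are initialized with small
weights so initial logits are near zero, and gradients are clipped to a
global norm of 5.

## Desk-scale profile

The test suite and worked examples use a reduced profile chosen once for
CPU execution: 128 x 128 inputs, 1/8-width backbone with one bottleneck per
stage, 32-channel pyramid, k = 8 prototypes, anchor scales 16-120 px,
learning rate 0.02, batch 4, 30 epochs, and an attention reduction ratio of
4 (r = 16 would collapse a 32-channel MLP to two hidden units). Training 50
synthetic images under this profile takes a few minutes on one CPU and
reaches AP50 above 0.5 on 20 held-out images; the paper-scale profile is
retained in configuration for GPU-scale use.

## The synthetic generator

`generate_smear()` emulates what matters for this detector: large
near-circular leukocytes (radial-Fourier-perturbed discs) with dark lobed
nuclei inside lighter cytoplasm, pale erythrocyte annuli as unannotated
distractors, optional adhering leukocyte pairs placed until their masks
intersect by at least the requested fraction of the smaller cell, smooth
illumination gradients, staining-color jitter and Gaussian noise, all
deterministic under a seed. Annotations are full (amodal) per-cell masks;
adhesion regions are drawn darker, as overlapping stained cytoplasm
appears. It does not attempt photorealism: no chromatin texture, no focus
blur, no platelets, no staining artifacts, and far lower cell density than
a real 2592 x 1944 smear field. Passing the end-to-end test therefore
demonstrates that the pipeline — matching, losses, gradients, decoding,
mask assembly, evaluation — learns and generalizes on smear-like geometry;
it says nothing about clinical performance, which the published work
established on expert-annotated ALL-IDB1/BCCD/Raabin-WBC images that are
not redistributable here.

Preprocessing utilities mirror the published pipeline: sliding-window
512/256 cropping with a final edge-anchored window (a 2592 x 1944 field
yields 10 x 7 tiles), zero-padding to square on the bottom/right, bilinear
image / nearest-neighbour mask resizing to 550 x 550, and a deterministic
7:1:2 split by cumulative-floor boundaries (678 items give 474/68/136).
Instances clipped by a tile boundary are kept when at least 25% of their
area survives — the published count of surviving tiles does not pin down
the rule, so ours is declared, not inferred.

## Numerical choices and degenerate inputs

* Spatial rounding is `floor((n + 2p - k)/s) + 1` everywhere (stem pool
  included); a 550 input traces 69/35/18 and the prototype grid is 138.
* Mask binarization is strictly `> 0.5`, so all-zero coefficients
  (sigmoid = 0.5 exactly) give an empty mask.
* Mask IoU of two empty masks is 0 by convention; AP with zero ground
  truths and zero detections is reported as NaN with a warning.
* AP uses greedy score-ordered matching and 101-point interpolation (the
  COCO convention; the defining integral leaves the discretization open).
* NMS is greedy over decoded boxes at IoU 0.5, score floor 0.05, top-k 200.
* Exp in box decoding is capped (`exp(min(x, 10))`) against early-training
  blow-ups; decoded boxes are clipped to [0,1].
* Ghost `c_out < S` and even cheap kernels are configuration errors;
  frequency indices outside a map raise errors in `dct_component` (the
  attention module skips, as described above).

## Limitations

Training is CPU-bound R + Rcpp: the desk profile trains in minutes, but the
paper-scale profile (550 px, full widths, batch 16, 600 epochs) is
impractical here and is provided as configuration, not as a reproduced
result. The published accuracy tables on clinical datasets are out of reach
without their expert instance labels; what this package reproduces exactly
is the architecture — its parameter budgets, its spectral-attention
identities, and its evaluation protocol — plus a complete, tested training
path at reduced scale.
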