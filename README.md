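# wbcseg

Single-stage instance segmentation of white blood cells (leukocytes) in
stained blood-smear images, for people building or studying lightweight
cell-segmentation pipelines: each detected cell gets its own pixel mask,
including touching and overlapping cells that semantic segmentation would
merge.

The detector is a prototype-mask network (YOLACT family) with three
light-weighting and accuracy elements:

* **Ghost-ResNet-50 backbone** — every convolution inside a residual
  bottleneck produces only `m = round(c_out / S)` channels with a full
  ("primary") convolution; the remaining `c_out − m` channels come from a
  cheap 3×3 depthwise convolution over those intrinsic maps. The adjustment
  factor `S` trades parameters for capacity: the feature extractor counts
  13.27 M / 8.15 M / 6.45 M parameters at `S` = 2 / 4 / 6, versus 25.56 M
  for standard ResNet-50 with its classifier. `S = 1` is exactly a standard
  convolution.
* **Dual-stream fusion neck** — the usual top-down pyramid
  (`P5 = 1×1(C5)`, `P_k = 1×1(C_k) + up₂(P_{k+1})`) plus a bottom-up path:
  `N3 = P3`, `N_{k+1} = 3×3(P_{k+1} + conv↓2(N_k))`, and N6/N7 by further
  stride-2 convolutions, all at one channel width. A plain-FPN baseline is
  one config flag away.
* **Dual-domain attention** — per pyramid level, channel weights
  `M_F = σ(MLP(Y₀,₀) + MLP(Y₀,₁) + MLP(Y₁,₀))` from the unnormalized 2-D
  DCT-II components of each channel (one shared MLP, `C → C/r → C`,
  r = 16; `Y₀,₀ = H·W·GAP`), followed in series by CBAM-style spatial
  attention (mean/max maps → 7×7 conv → sigmoid). Masking order is
  channel-then-spatial; the prototype branch reads the pre-attention level.

Because no deep-learning framework ships with the target environment, the
package carries its own reverse-mode autodiff tape with Rcpp/Armadillo
convolution kernels — every layer's gradient is verified against finite
differences in the test suite. It also provides a synthetic blood-smear
generator with COCO-style annotations (RLE), the published preprocessing
ops (sliding-window 512/256 crop, zero-pad to square, 7:1:2 split),
COCO-protocol mask AP (AP50/AP75 and the 0.5:0.05:0.95 average), exact
parameter and analytic FLOP counting, and a CLI.

## Worked example

Train the reduced ("desk") profile — 128×128 synthetic smears, 1/8-width
backbone, 8 prototypes — on 50 generated images and evaluate on 20 held-out
ones (about 9 minutes on one CPU):

```r
library(wbcseg)
set.seed(205)
cfg  <- default_config("desk")
spec <- smear_spec(width = 128, n_wbc = 3, n_rbc = 12,
                   overlap_prob = 0.3, min_overlap = 0.2)
train_set <- synth_dataset(50, spec, seed = 1000)
test_set  <- synth_dataset(20, spec, seed = 9000)

model <- build_detector(cfg)
hist  <- train_detector(model, train_set)     # SGD, lr 0.02, batch 4, 30 epochs

preds <- lapply(test_set, function(s) {
  d <- predict_image(model, s$image)
  list(masks = d$masks, scores = d$scores)
})
gts <- lapply(test_set, function(s) lapply(s$annotations, `[[`, "mask"))
evaluate_detections(preds, gts)
#> AP 51.64 | AP50 97.03 | AP75 46.49  (60 ground truths)
```

The per-epoch mean loss fell 12.56 → 4.00 over the run; AP50 = 97 means
nearly every leukocyte is recovered with mask IoU above 0.5 at high
precision, while the lower headline AP reflects the stricter thresholds of
the 0.5–0.95 average at this reduced scale.

Architecture accounting without any data:

```r
ghost <- build_backbone("ghost_resnet50", ghost_config(4))
count_parameters(ghost) / 1e6   #> 8.153504
std <- build_backbone("standard_resnet50", include_classifier = TRUE)
count_parameters(std)           #> 25557032  (25.56 M)
count_flops(std, 550) / 1e9     #> 25.46 G multiply-adds at 550x550
```

## Command line

```sh
inst/exec/wbcseg stats --arch ghost_resnet50 --S 4
inst/exec/wbcseg synth --n 20 --seed 7 --out data/ --size 128
inst/exec/wbcseg train --data data/ --out runs/ --profile desk
inst/exec/wbcseg predict --checkpoint runs/checkpoint.rds --image data/img_0001.png
inst/exec/wbcseg eval --gt data/annotations.json --pred results.json
```

## Layout

```
R/                  tape + layers, backbone, neck, attention, heads,
                    training, evaluation, synthetic data, stats, CLI
src/ops.cpp         conv/pool/resize kernels (forward + backward)
tests/testthat/     unit, property and acceptance tests (oracle helpers
                    in helper-oracles.R)
scripts/acceptance.R
vignettes/wbcseg-methods.Rmd   model, assumptions, design decisions
inst/exec/wbcseg    CLI entry point
```
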