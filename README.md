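# amodalgrape

Amodal detection of occluded grape clusters: predicting the *complete*
mask of a partially hidden cluster — visible pixels plus the part
concealed behind an occluder — without ever having amodal annotations.

Occlusion is the main source of underestimation in image-based vineyard
phenotyping: grape clusters hide one another, so berry counts and
projected areas read off a segmentation fall short of the truth. This
package implements a self-supervised treatment of the problem for anyone
working on plant-phenotyping or general amodal-segmentation pipelines in
R:

* **Mask primitives and metrics** — bilinear mask resizing with principled
  binarization, IoU, **boundary IoU** (IoU restricted to distance-*d*
  bands of the two contours, `|(G_d∩G)∩(P_d∩P)| / |(G_d∩G)∪(P_d∩P)|`,
  with *d* defaulting to 2% of the instance diagonal) and **amodal IoU**
  (`|G_a∩P_a| / |G_a∪P_a|` against the true complete mask).
* **Incoherent-region supervision** — the pixels a detector's mask
  size transformations destroy, `M_inc = D(m ⊕ U(D(m)))`, and their
  subset at instance–instance contact (points where ≥ 2 of 3 symmetric
  pixel pairs straddle two distinct instances); assembled per proposal
  into the supervision triple for a dual-decoder segmentation head.
* **Dual-decoder heads** — a 28×28 mask decoder and a 28/56 incoherent
  decoder coupled by a pixel affinity learning module (two-way branch
  softmax + squeeze-and-excitation over a shared representation), trained
  with BCE and dice+BCE losses (local incoherent term weighted λ = 2).
* **Occlusion synthesis** — the *overlapping cover strategy*: 8 directional
  cover cases, overlap ratio β ∈ (0.2, 0.85], a height-match filter
  (0.9 h_occder < h_occ < 1.2 h_occder), an occlusion-rate filter
  (ε = 1 − |visible|/|intact| must exceed 0.1, retried with β + 0.05),
  and reverse synthesis (γ): identity-mapping samples that stop the
  completer from inflating fully visible instances. A random-paste
  baseline is included for comparison.
* **The completion model** — a U-Net–style encoder–decoder over the
  2-channel (visible occludee, occluder) mask pair, trained with a
  region-split BCE (occluder region + λ₂ = 5 × complement), and the
  **cross-prediction rule**: complete both members of a pair, compare the
  relative area growths ΔM = (|M_a| − |M|)/|M|, and order the pair
  (−1 no occlusion, 1 if the first instance is occluded, 0 inverse).
* **Procedural fixtures** — grape-cluster-like instances (unions of
  jittered "berries") and multi-instance scenes with exact amodal masks,
  visible masks and occlusion edges, so everything above is testable with
  no dataset download.

The neural components run on a small reverse-mode autograd engine written
for this package (R tape over Rcpp/RcppArmadillo im2col+GEMM convolution
kernels) — no external deep-learning framework is required.

## Worked example

```r
library(amodalgrape)

# 1. a pool of complete instances and a synthesized training set
pool  <- pool_from_fixtures(24, rng_seed = 101)
train <- synthesize_dataset(pool, 80, strategy = "overlap", rng_seed = 1,
                            out_size = 64)
train[1:3, c("case_alpha", "beta", "gamma", "epsilon")]
#> # A tibble: 3 × 4
#>   case_alpha  beta gamma epsilon
#>        <int> <dbl> <lgl>   <dbl>
#> 1          3 0.618 TRUE    0.612
#> 2          2 0.452 FALSE   0.107
#> 3          8 0.530 FALSE   0.117

# 2. train a scaled completion model (64 px, width 8, 250 iterations)
model <- train_amodal(train, input_size = 64, base = 8, iters = 250,
                      batch = 3, lr = 1e-3, seed = 1)
glance(model)
#> # A tibble: 1 × 7
#>   input_size depth  base n_parameters trained iterations final_loss
#> 1         64     4     8       120753 TRUE           250      0.201

# 3. evaluate on held-out fixture-scene occlusion pairs
pairs <- scene_occlusion_pairs(10, rng_seed = 501, size = 64)
ev    <- evaluate_completion(model, pairs)
mean(ev$iou_before)   # amodal IoU of the visible mask:    0.428
mean(ev$iou_after)    # amodal IoU after completion:       0.501

# 4. decide who occludes whom by cross-prediction
sc  <- make_scene(2, 1, rng_seed = 77)
occlusion_relation(sc$visible[[1]], sc$visible[[2]], model)
#> # A tibble: 1 × 4
#>       o delta_i delta_j ambiguous
#> 1     1  0.0506  0.0197 FALSE
```

The completion lifts mean amodal IoU from 0.428 to 0.501 on held-out
pairs, and the relation rule correctly reports `o = 1`: the first
instance grew more under cross-prediction, so the second one occludes it.

`autoplot()` methods visualize scenes, synthesis samples and training
curves; `tidy()`/`glance()` summarize trained models.

## Command line

A thin CLI wraps the same functions (`inst/scripts/amodalgrape`):

```sh
amodalgrape make-fixtures --out fixtures/ --scenes 5 --seed 1
amodalgrape synthesize    --pool fixtures:24 --n 200 --strategy overlap --seed 1 --out synth/
amodalgrape train-amodal  --manifest synth/ --iters 250 --size 64 --out model.json
amodalgrape predict       --model model.json --occ occ.png --occder occder.png --out pred.png
amodalgrape evaluate      --pred preds/ --gt gt/ --metric amodal_iou
```

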