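---
title: "Amodal detection of occluded grape clusters: models, supervision and synthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amodal detection of occluded grape clusters: models, supervision and synthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Occlusion is the dominant source of error in image-based grape phenotyping:
clusters hide one another, so berry counts and projected areas read off an
instance segmentation systematically underestimate the truth. *Amodal
detection* predicts the full extent of a partially hidden cluster — its
visible pixels plus the part concealed behind the occluder. Two obstacles
make this hard in practice: paired images of the same cluster occluded and
un-occluded essentially cannot be collected at scale, so there are no
amodal annotations to train on; and the quality of amodal completion is
extremely sensitive to how precisely the segmentation separates the
occluder from the occluded instance along their shared boundary.

This package implements a complete, dataset-free treatment of that
pipeline in four parts:

1. **Mask primitives and metrics** — binary-mask resizing, IoU, boundary
   IoU (IoU restricted to distance-`d` bands along the mask contours), and
   amodal IoU (IoU of a predicted completion against the true complete
   mask).
2. **Incoherent-region supervision** — targets for a segmentation head
   that explicitly predicts the pixels most at risk during mask size
   transformations, concentrated at instance boundaries and, crucially, at
   instance-instance contact.
3. **Occlusion synthesis** — the overlapping cover strategy, which
   manufactures (occluded, occluder, intact) training triples from a pool
   of complete instances under directional, size- and rate-filtered
   overlap geometry; plus the conventional random-paste baseline.
4. **The completion model and the ordering rule** — a small U-Net that
   maps the channel-stacked (visible occludee mask, occluder mask) pair to
   the complete occludee mask, and a cross-prediction rule that decides
   which member of an overlapping pair is in front.

A procedural generator of grape-like instances and scenes supplies ground
truth for every stage, so the whole package is testable offline.

## Incoherent regions

Downsampling a binary mask and upsampling it back (both bilinear, with
binarization at 0.5 and ties counted as foreground) does not reproduce the
mask: thin structures, scalloped boundaries and narrow inter-instance gaps
flip. The *incoherent region* of a mask `m` under a size transformation is

```
M_inc = D( m XOR U(D(m)) )
```

where `D` and `U` are the down/up resize operators. These are exactly the
pixels whose value the supervision pipeline of a two-stage detector
destroys when it samples annotation masks down to head resolution, and
they cluster where segmentation errors matter most for later amodal
completion: along boundaries and in overlap regions.

The *local* incoherent region keeps only incoherent points at
instance-instance contact. Around every incoherent point three symmetric
pixel pairs are sampled at offset `r` (default 2, the 2x down-sampling
stride) along the horizontal, vertical and main-diagonal directions; a
pair *straddles* when both members carry distinct non-zero instance ids
(instance-versus-background does not count — the purpose is isolating
overlap, and background edges are already well handled by ordinary mask
supervision). A point qualifies when at least two of its three pairs
straddle. Note a geometric consequence: at the extreme ends of a contact
segment the diagonal pair leaves the instances, so isolated single-pixel
contacts do not qualify — the region genuinely marks extended contact.

Per proposal, three supervision targets are assembled: the cropped
instance mask resized to the mask-decoder output (`mpc`, 28x28); the
incoherent mask of the cropped instance at the incoherent-decoder output
(`mpi`, 56x56 or 28x28); and the proposal-cropped local incoherent region
resized to that output and intersected with `mpi` (`minc_oi`). The
intersection enforces `minc_oi ⊆ mpi` by construction. Two judgment calls
deserve record:

* When a proposal crop is smaller than the incoherent-decoder output, the
  incoherent transform would not be a downsampling; such crops are first
  brought to twice the decoder size so the transform stays genuinely
  lossy.
* Whether the cropped local incoherent mask should itself be passed
  through the incoherent transform (rather than plainly resized) is
  ambiguous; an "incoherent region of an incoherent region" is degenerate,
  so plain resize is the default and the alternative sits behind
  `minc_o_mode = "incoherent"`.

**Scale caveat for synthetic data.** The final `D` in the definition is a
bilinear threshold, so sparse flipped pixels can vanish entirely. Real
manual annotations are jagged and shed incoherent pixels at any scale; the
procedurally smooth fixture silhouettes shed surviving pixels reliably
only at the exact 2x stride. The production default for the full-image
step follows the 60% model-input downscale; the fixture-scene harness and
the overlap-detection tests use the 2x stride. This is a property of the
synthetic data, not of the operator.

## The dual-decoder heads

The segmentation heads consume ROI-aligned features at 14x14 (mask branch)
and 28x28 (incoherent branch), refine each with cascaded 3x3 convolutions
(two per stream by default; the count is configurable), upsample the mask
stream by a 2x2 stride-2 transposed convolution to 28x28, couple the
branches with a pixel affinity learning module, downsample both with a
stride-2 3x3 convolution, couple again at the coarse scale, and deconvolve
to the output resolutions (28 for the mask, 28 or 56 for the incoherent
decoder) with a final 1x1 projection and sigmoid.

The pixel affinity learning module exploits the fact that the incoherent
mask is a subset of the instance mask, so per-pixel predictions of the two
branches are strongly correlated. It concatenates the two c-channel
feature grids, compresses 2c→c→2c through two 3x3 convolution blocks with
ReLU (the nonlinear mapping unit), splits back into two grids, applies a
per-position, per-channel two-way softmax (implemented as the sigmoid of
the difference, which is algebraically identical and keeps the two weights
summing to one), reweights each branch by its weight grid, fuses the
reweighted grids 2c→c, passes the fusion through squeeze-and-excitation
channel attention (reduction ratio 4), and adds the result back to both
branch inputs. The two module sites do not share parameters.

Losses: the mask decoder trains with mean binary cross-entropy against
`mpc` (probabilities clamped to `[1e-7, 1-1e-7]`). The incoherent decoder
trains with a dice-plus-BCE compound: one term against `mpi`, plus a
second term — weighted `lambda_inc = 2` — of the prediction *restricted to
the local incoherent region* (elementwise product with `minc_oi`) against
`minc_oi`. The dice uses +1 smoothing in numerator and denominator. A
boundary-supervision baseline swaps all incoherent targets for 3x3
Laplacian boundary masks under identical tensor contracts.

The full detector scaffold (backbone, FPN, RPN, box head) is deliberately
not reproduced — it is standard machinery orthogonal to what this package
contributes. The heads accept features from any provider; the test harness
uses ground-truth boxes with ±10% jitter and a small trainable
convolutional encoder over proposal crops.

## Overlapping cover synthesis

Training pairs for the completion model are synthesized from a pool of
complete instances. The direction of cover is drawn from eight 45° cases;
the printed geometry of the upper-right case generalizes as follows. The
overlap extents are `w_beta = round(beta * w_occ)` and
`h_beta = round(beta * h_occ)` with `beta` drawn from (0.2, 0.85]. The
four corner cases place the two tight crops so their corners overlap in a
`w_beta x h_beta` rectangle, giving canvases of exactly
`w_s = w_occ + w_occder - w_beta` and `h_s = h_occ + h_occder - h_beta`.
The four cardinal cases overlap along one axis only — `beta` scales the
overlap depth on that axis — with the transverse placement centered plus a
uniform jitter of ±10% of the transverse extent (the transverse geometry
is not printed anywhere; this is the package's extrapolation, recorded
here). Occluders are rejection-sampled until the height filter
`0.9 h_occder < h_occ < 1.2 h_occder` passes; width is unconstrained.

The occluded instance's content under the occluder is erased, and the
occlusion rate `epsilon = 1 - |visible| / |intact|` is checked: samples
with `epsilon <= 0.1` are retried with `beta` increased by 0.05. The
as-printed retry loop can fail forever (two blobs may simply not intersect
more deeply in a corner overlap), so `beta` caps at 0.85 and the pair is
then resampled — the same pair is retried first, a fresh pair drawn after
the cap.

*Reverse synthesis* (`gamma`, drawn Bernoulli(0.5) per sample by default —
the proportion is a free choice, exposed as `gamma_prob`) swaps the roles:
the occluder canvas becomes both the input's first channel and the target,
while the erased occluded instance plays the occluder channel. These are
exact identity mappings; they teach the completer that a fully visible
instance should not grow, which curbs over-prediction when the front
instance of a pair is cross-predicted.

The random-cover baseline pastes the occluder at a uniformly random
integer offset under which the bounding boxes intersect — no size filter,
no rate filter, no directional geometry — with the same output contract.

Masks are recovered from the painted canvases by a grayscale > 0 test
(canvases start black; fixture shading keeps foreground strictly
positive, and pool items built from user imagery are floored at 1/255).
Samples can be letterbox-padded to square and resized to the network
input; at production scale that input is 320x320, the scaled experiments
use 64x64.

## The completion model and the ordering rule

The completer is a U-Net-style encoder-decoder: 4 resolution levels,
channel width doubling from a configurable base (32 at production scale, 8
in the scaled experiments), 2x2 max pooling down, 2x2 stride-2 transposed
convolutions up, skip concatenation, a final 1x1 projection and sigmoid.
It consumes masks only — two channels, (visible occludee, occluder) — not
RGB: the completion problem as posed here is shape completion, and the
loss operates purely on mask rasters.

The loss splits the BCE by region: one term restricted (elementwise
product) to the occluder region — where completion actually happens — and
a second term on the complement, weighted `lambda2 = 5`, anchoring the
prediction to the visible evidence. Optimization is Adam at learning rate
1e-4 with first-moment coefficient 0.9 and weight decay 5e-4 (classic
L2-into-gradient); production schedule 15,000 iterations at batch 16, all
overridable. The scaled experiments in the tests and the acceptance
script run 250-300 iterations at batch 3-4, learning rate 1e-3, on 80
synthesized 64x64 samples — sizes chosen so the full suite replicates the
experiment over three seeds.

Given a segmented scene, instances are paired when their tight bounding
boxes intersect. For a pair, the model cross-predicts both completions —
`f(M_i, M_j)` and `f(M_j, M_i)` — and the relative area growths
`delta = (|amodal| - |visible|) / |visible|` decide the relation: both
growths at or below `tau` means no occlusion (−1); otherwise the instance
that grew more is the occluded one. `tau` defaults to 0.01 because an
exact zero-growth branch is measure-zero for a real network. Exact ties
above `tau` fall outside the rule's three branches; they are reported as
the inverse relation with an `ambiguous` flag rather than silently
resolved. A further caveat the rule inherits from its definition: in
occlusion *chains* (A hides B, C hides A), the front instance of one pair
may itself be occluded and grow under completion, so even oracle
completions can mis-order such pairs; the rule is exact on pairs whose
front member is fully visible, and the tests state it at that strength.

## What the synthetic fixtures do and do not show

Fixture instances are unions of 15-40 jittered circles ("berries") inside
an ellipse, largest connected component kept, shaded per-berry with
strictly positive foreground. Scenes place instances with depth equal to
placement order and record amodal masks, visible masks and the occlusion
edge list exactly. They emulate the *structure* of the problem — irregular
scalloped silhouettes, directional partial overlap, moderate occlusion
rates — which is what the mask-level machinery consumes.

They do not emulate photometric realism (lighting, texture, color
statistics), annotation noise, multi-occluder pile-ups, or the scale of a
real harvest dataset. Passing the scaled experiments therefore
demonstrates that the operators are implemented faithfully and that the
training signal drives the intended behavior (completion recovers hidden
area; realistic cover geometry transfers better than random pasting;
identity mappings curb occluder growth) — it does not certify the absolute
accuracy figures a full-scale model reaches on orchard imagery.

## Numerical choices

* Interpolated masks binarize at 0.5 with ties counted as foreground.
* Boundary IoU bands use the Euclidean distance transform of the mask to
  its within-frame complement (inner bands); a mask with no background has
  an empty band, and two empty bands compare as 1. `d = "auto"` takes 2%
  of the ground-truth instance's box diagonal, floored at 1 px.
* Empty-versus-empty IoU is 1; empty-versus-nonempty is 0.
* Coordinates are 0-based with y down; boxes are half-open.
* Polygon rasterization fills even-odd at pixel centers.
* Completion predictions binarize at 0.5.
* Weight init is He-normal; all training loops are seed-deterministic, and
  every stochastic component takes an explicit seed.
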