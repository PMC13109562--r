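---
title: "Dense leaf detection: progressive pyramid fusion, crowded query refinement, and their evaluation"
author: "DenseLeaf authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dense leaf detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DenseLeaf)
```

## The problem

Canopy images of crops such as kiwifruit contain on the order of fifty
leaves per frame, most of them partially hidden behind their neighbours.
Detecting every leaf — including the ones that are two-thirds occluded — is
the entry point to downstream phenotyping: disease scoring, leaf counting,
growth tracking. Two properties make this harder than generic object
detection. First, overlapping leaves share colour and texture, so feature
maps blur neighbouring instances together. Second, set-based (DETR-family)
detectors supervise each object with exactly one query via one-to-one
Hungarian matching, which starves training of positive samples exactly
where objects are densest, and the matcher itself becomes expensive when
many near-duplicate queries compete for the same crowded region.

DenseLeaf implements the computational components that address these two
failure modes, at desk scale, together with everything needed to exercise
them end-to-end on CPU: a synthetic occluded-canopy generator, COCO-style
metrics, and the dataset-construction arithmetic (tiling, screening,
density statistics).

## Progressive pyramid fusion with adaptive aggregation

Multi-scale backbone features are fused strictly top-down. The coarsest
level passes through a feed-forward transform — position-wise linear, 3x3
convolution, position-wise linear (`topTransform`). Every finer level
`i` is then produced as `AFA(Level_i, Upsample(Level_{i+1}'))`
(`progressiveFuse`), so each output level depends on all levels above it;
the fusion is genuinely sequential, not parallel lateral addition.

The adaptive feature aggregation (AFA) operator is a dual gate:

* a **spatial gate** `Fs = sigmoid(Conv(P1) + Conv(P2))`, where each
  `Conv` is a 1x1, C-to-1 compression — a single-channel map in (0,1)
  marking where leaf structure concentrates;
* a **channel gate**: the inputs are concatenated to 2C channels, globally
  average-pooled, passed through a linear layer and a sigmoid to give 2C
  per-channel weights in (0,1), multiplied back onto the concatenated
  features, and reduced to C channels by a 1x1 convolution
  (`afaChannelGate`);
* the output is the elementwise product of the two paths
  (`afaFuse`), the channel-gated features modulated by the broadcast
  spatial map.

Several choices here were genuinely open and are fixed as follows. The
feed-forward "MLP" stages are read as position-wise (1x1) transforms with
hidden width equal to C, and the convolution as 3x3 with padding 1 — the
standard pyramid-block reading when no kernel sizes are given. The spatial
gate compresses to exactly one channel and the final reduction maps 2C to
C; these are the unique channel counts that make the gating product
well-defined by broadcasting. Upsampling is nearest-neighbour by default
(bilinear available), and always interpolates to the exact height and
width of the receiving level, which absorbs odd-size mismatches. No
normalisation is inserted around the gate sum.

## Crowded query refinement (CQR)

During training the decoder runs two query branches:

* **original queries** are first culled by class-agnostic NMS
  (`classAgnosticNMS`) on their classification scores — near-duplicate
  queries for the same leaf are removed before matching, shrinking the
  Hungarian problem — then matched one-to-one (`hungarianMatch`);
* **extra queries** skip NMS, are ranked by classification score and
  matched one-to-many by **Top-K Hungarian matching**
  (`topkHungarianMatch`): each ground truth is replicated k times, and
  round r solves a fresh one-to-one problem over the predictions not
  assigned in earlier rounds. The pair count is always
  `min(k*G, P)`; with k = 1 the procedure is exactly plain Hungarian
  matching.

`cqrCompose` wires both branches; `combinedLoss` adds the extra branch at
a reduced weight. The extra branch exists only at training time — at
inference the model decodes the original queries alone.

Decisions made here: the matching cost is the DETR-family convention
`2*(1-p) + 5*L1 + 2*(1-GIoU)` (no cost is printed in the source
description); k defaults to 4, the value at which a replica sweep from 1
to 8 peaks; the extra-branch weight defaults to 0.5 ("lower weight" left
unquantified); the extra-query count defaults to the original count; NMS
defaults to IoU 0.7 where no threshold is stated, a common crowded-scene
setting, and culling is applied once to the final decoder stage (a
per-stage reading exists but the single-cull form is the one the output
composition equation states). One-to-one matching is implemented on top of
`clue::solve_LSAP` with zero-padding to square, which forces all
`min(P, G)` real pairs into the solution; the exhaustive-enumeration
equivalence is property-tested rather than assumed.

## Auxiliary-head sample injection

Encoder memory is unflattened back into a pyramid (`adaptMemory`, the
exact inverse of `flattenMemory`) and fed to auxiliary detection heads
whose label assignment is one-to-many by construction. The package ships a
stub head (`stubHead`) that proposes jittered anchors around feature
activation peaks and accepts those with IoU at least 0.5 against some
ground truth; full single/two-stage heads are out of scope and the
interface accepts any head with the same contract. The heads' own
confidences are then **discarded entirely**: `jtahRefine` draws fresh
i.i.d. U(0,1) scores under a seed and suppresses overlaps with
class-agnostic NMS on those randomized scores, so which of two mutually
exclusive samples survives is decided by the draw, never by the head.
Survivors are embedded as sinusoidal position encodings of their
normalized boxes (`encodeAsQueries`) and injected as additional decoder
queries, supervised toward their assigned ground truths at the
extra-branch weight. One stub head is used by default; the NMS threshold
is shared with the CQR configuration (the source leaves it unstated).

## Detection metrics

`evaluateDetections` produces the usual COCO-style summary: AP averaged
over IoU 0.50:0.05:0.95 (and at fixed 0.50/0.75), average recall at
100 and 300 detections per image over the same grid, plus standalone
precision/recall/F1 at IoU 0.5 and score threshold 0.5 (the threshold
behind standalone precision figures is configurable; 0.5 is the default).
AP uses 101-point interpolation — the COCO dialect — because the
evaluation tables being mirrored are COCO-style; the literal
area-under-curve integral is kept as `mode = "auc"` in
`apFromRankedFlags`. Matching follows the COCO convention (greedy by
score, each ground truth matched once). There is a single foreground
class, so the class average is over one class. AR@300 can never fall
below AR@100: the larger budget only adds detections.

## The synthetic canopy generator

`sampleScene` emulates the statistics of the target imagery without
shipping any of it: instance counts are Poisson with mean `lambda`
(default 50 per scene, the density of the emulated canopies); leaves are
ellipses with a midrib line, faint cross-vein striping, per-leaf colour
jitter and a two-sided illumination gradient (one half of the blade
brighter than the other — a known confound of real canopy imagery);
painting is back-to-front so later leaves occlude earlier ones, and
visibility is computed by exact pixel counting on the ownership matrix.
`annotateScene` boxes the **visible** pixel set only and drops leaves
whose visible fraction is below 1/3, mirroring the annotation rule that
blades less than a third visible are not marked. That rule could be read
as area or as blade length; it is implemented as visible-**area**
fraction. Scenes regenerate bit-identically from an identical spec.

What the generator does not emulate: real leaf shapes and venation,
specular highlights, soil clutter, UAV optics, or 61-megapixel scale.
Passing tests therefore demonstrate the correctness of the computational
pipeline on controlled occlusion geometry, not detection accuracy on real
canopies.

Default geometry (256x256 scenes, semi-axes 18–34 by 10–22 px) was chosen
once so that fifty leaves substantially over-fill the frame, giving the
heavy pairwise overlap regime the methods target; roughly a third of
instances then fall below the 1/3 visibility rule, which exercises the
annotation filter.

## Dataset-construction arithmetic

`slidingWindows` tiles a source image with a 9504x6336 window and a
5000-px step, adding a final edge-clamped window per axis so every pixel
is covered. `cropBoxes` clips annotations into a window and keeps a box
only when at least a third of its area survives — the crop-boundary rule
reuses the 1/3 visibility convention, since no explicit rule is stated
for crops. `screenTile` keeps tiles with at least 50 boxes (200 for
whole-image screening). `densityStats` **truncates** boxes/image to two
decimals rather than rounding: 85375/1696 = 50.339 prints as 50.33 only
under truncation (the published table is internally inconsistent on this
point; the headline row's convention wins). Semantic screening criteria
that need human judgement (roads, people, edge distributions) are out of
scope; only the count predicates are automated.

## The miniature detector and its training loop

No automatic-differentiation framework for R is available in this
package's dependency set, so DenseLeaf carries a minimal tape-based
reverse-mode engine over plain arrays (conv2d via im2col, pooling,
resizing, attention, elementwise algebra). All trainable components run
on it, and `checkPfpnGradients` validates the analytic gradients of the
full progressive fusion against central finite differences at randomly
probed coordinates (the tests require agreement within 1e-3 relative
error; observed errors are orders of magnitude smaller).

The miniature model (`buildModel`) is a three-stage convolutional
backbone, the progressive pyramid, a flatten-to-memory encoder stand-in
with fixed 2-D sinusoidal positional encodings and learned level
embeddings, and a small cross-attention decoder whose queries carry
learnable reference boxes in logit space — the box head predicts a delta
to its query's reference, the standard anchor-style stabilisation in
modern set-based detectors, so the query set tiles the image before any
training. Injected auxiliary queries use their own sample boxes as
references. The extra branch shares decoder weights with the original
branch (whether the full-scale design shares them is unstated; sharing is
the lighter choice and is flagged here). Losses are focal sigmoid
classification over all queries plus L1 and (1-GIoU) on matched pairs,
combined across branches at the extra weight; the loss terms are the
DETR-family convention consistent with the baseline the method extends.

Training (`trainModel`) uses AdamW (initial learning rate 2e-4, weight
decay 1e-4), global gradient-norm clipping at 0.1, a 10x learning-rate
step at epoch 11 of 12, and an 8:2 train/validation split — the reference
protocol. Runs are deterministic per seed; non-finite losses abort with an
explicit divergence error.

Problem sizes in the test suite and acceptance script were chosen as the
smallest that still exercise every code path meaningfully: 64x64 scenes
with about ten leaves, 16 channels, 30 (+30 extra) queries, 200
optimisation steps, and a 128x128 crowded scene (about thirty leaves) for
the supervision-coverage comparison. The convergence contract checked is
directional — the final-decile mean loss must fall below the first-decile
mean — not an accuracy target; reproducing full-scale detection accuracy
would require GPU training on the real dataset and is explicitly out of
scope.

## Numerical choices and degenerate inputs

* IoU of boxes with zero union area is 0 by convention; GIoU lies in
  (-1, 1] and equals IoU when the enclosure equals the union.
* NMS breaks score ties by lower original index, making every suppression
  result deterministic and testable.
* Hungarian matching shifts costs to nonnegative before solving (the
  solver requires it) and strips zero-padded dummy pairs afterwards.
* Empty inputs are values, not errors: empty candidate lists, zero ground
  truths (0-column cost matrices), empty scenes and empty datasets all
  flow through.
* GIoU/focal losses are stabilised with small epsilons inside logs and
  divisions; elementwise min/max route gradients to the first argument on
  ties.

## Known limitations

* The scene generator's ellipse leaves cannot probe sensitivity to real
  leaf morphology, and its painter-order depth model has no partial
  transparency or lighting interaction between leaves.
* The stub auxiliary head takes its anchor scale from ground-truth size
  statistics; it is a contract-preserving stand-in, not a trained head.
* The miniature decoder omits layer normalisation and multi-head
  attention; it exists to exercise matching, fusion and injection
  end-to-end, not to be a competitive detector.
* Published full-scale accuracy tables are not reproducible here by
  design; what is reproduced is the in-table arithmetic (density rows)
  and the behavioural contracts of every component.
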