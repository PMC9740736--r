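---
title: "Segmenting plant organs in 3D point clouds with attention separation and position codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting plant organs in 3D point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Plant phenotyping increasingly relies on 3D point clouds of whole plants,
and most phenotypic traits (leaf area, stem architecture, flower counts)
require a per-point *organ segmentation*: every point classified as flower,
leaf or stem.  Plant clouds are harder than most segmentation targets
because organs are thin, small and interwoven — a stem threads through a
canopy of leaves, and points of different organs can be closer to each
other than to most points of their own organ.  Two properties of point
sets make naive feature extraction fragile: they are unordered, and they
are irregularly sampled.

`plantseg3d` implements a segmentation network built around three ideas:

1. **Multi-head attention** over point tokens, so that points of the same
   organ that are far apart in space can still exchange information.
2. **A separation loss on the attention heads.**  Parallel heads waste
   capacity: if all heads attend to the same feature subspace, the
   network extracts the same information several times.  The loss
   penalises the average absolute cosine similarity between the flattened
   per-head output features, pushing heads to specialise.
3. **Position codes.**  Every neighbourhood is described by a
   *relative position code* (RPC — the offsets of each neighbour from its
   centre, passed through a small learnable map and max-pooled) and an
   *absolute position code* (APC — the centre's own coordinates through a
   second map).  The RPC branch is exactly translation invariant and, by
   the symmetry of max-pooling, invariant to neighbour ordering; the APC
   branch anchors tokens in the block frame.

## Architecture

The network consumes a fixed-size block of `n_points` points (2048 by
default), centred and scaled to unit radius.  A shared feature extractor
lifts each point to a `c_high`-dimensional feature from three ingredients:
a pointwise MLP over the coordinates together with classical
local-covariance shape descriptors (linearity, planarity, sphericity,
verticality of the dominant axis and neighbourhood extent, computed at
three neighbourhood scales — 8, `k_feat` and `3 * k_feat` nearest
neighbours; deterministic functions of the coordinates, cached per
block), a max-pooled summary of the neighbours'
features (through a narrow 16-wide projection that keeps the gathered
matrices small), and max-pooled neighbour offsets.  Together these give
each point a local geometric signature: tubes, planes and clusters look
different at organ scale, which is exactly the flower/leaf/stem
distinction.  The covariance descriptors are a deliberate concession to
the desk-scale training budget — they hand the extractor in closed form
what a deeper learned hierarchy would need many more epochs to discover,
while everything downstream (position codes, attention, separation loss)
remains learned.

Two branches then build token sets:

* **Global branch (multi-scale grouping).**  Farthest point sampling picks
  `m_centers` centres; ball queries at three radii (0.1, 0.2, 0.4 of the
  block radius by default) collect neighbourhoods whose position codes and
  pooled point features are mixed per scale and concatenated across
  scales, then passed through a self-attention module.
* **Local branch (learnable top-k selection).**  A pointwise score map
  reduces every feature to one importance scalar; the `k_select` highest
  scoring points (ties broken by lowest index) anchor neighbourhoods that
  are position-coded and concatenated with the score-gated point features
  (the gate keeps scores in the gradient path across the hard,
  non-differentiable selection).

A local–global cross attention enriches the global tokens with the local
set, and the detection head fuses the two streams with a second cross
attention (local tokens as queries).  All three attention modules use the
same prototype — `LayerNorm(S + FFN(S))` with
`S = LayerNorm(X + Multihead(X, Y, Y))` — and expose their per-head output
features to the separation loss.  Fused token features are interpolated
back to all points (inverse-distance weighting over the 3 nearest selected
anchors; nearest-centre propagation is available via
`upsample = "nearest"`), concatenated with the per-point features, the
raw coordinates and the shape descriptors, and classified by a final
pointwise MLP into three class scores; each point's scores are then
blended (equal weights) with the mean scores of its 8 nearest
neighbours, a differentiable consistency step exploiting the local
coherence of organ labels.  Interpolating *features* and classifying per
point, rather than
propagating token *labels*, keeps point-level detail at organ boundaries;
this is the package's choice within the token-to-point upsampling design.

## The separation loss and its sign

With `h` heads whose flattened output features are `f_i`, the loss value
is

$$\mathrm{sep} = -\frac{1}{h^2}\sum_{i \ne j}
  \frac{|\langle f_i, f_j\rangle|}{\lVert f_i\rVert\,\lVert f_j\rVert},$$

a negative quantity in `[-(h-1)/h, 0]`: 0 for pairwise-orthogonal heads,
the lower bound exactly for pairwise-parallel (or anti-parallel — the
absolute value penalises both) heads.  `separation_loss()` returns exactly
this value, and `combined_loss()` reports
`total = cross_entropy + loss_scal * separation`.

One subtlety deserves a direct statement.  Taken literally, *descending*
this signed value rewards parallel heads — the opposite of what a
"separation" term is for.  The trainer therefore applies the term as a
penalty on head similarity: the optimiser descends
`cross_entropy + loss_scal * mean |cosine|`, which is
`cross_entropy - loss_scal * separation`.  This is the only reading under
which the loss does what it is named for, and it is what
`minimize_head_similarity()` demonstrates in isolation: plain gradient
descent on the penalty takes a near-parallel two-head fixture below a mean
absolute cosine of 0.05 within a few dozen steps.  Note the cosine
gradient scales as the inverse squared norm of the heads, so the
demonstration uses unit-norm fixtures; inside the network the attention
head outputs live downstream of layer normalisation and stay at O(1)
scale.

The value of `loss_scal` is 1 by default and exposed in the
configuration.  The separation term is averaged (not summed) across the
three attention modules.

## Cross-entropy and metrics

The default classification objective is the mean categorical cross-entropy
of the row-softmax scores against one-hot targets.  A per-class binary
variant (`mode = "binary_sum"`) is retained for auditability.

Evaluation uses per-class intersection-over-union
`IoU_c = TP_c / (TP_c + FP_c + FN_c)` and their mean (MIoU).  A variant
denominator `TP + FP - FN` is available behind `literal = TRUE`; it is not
a set ratio (it can exceed 1 and divide by zero) and is excluded from the
default path.  Classes with an empty union are excluded from the mean with
a warning.

## Block pipeline

Whole plants are partitioned into blocks before the network sees them:

* `split_into_blocks()` uses a voxel grid whose resolution is tuned so the
  median occupied-voxel population approximates the target block size,
  merges under-populated voxels into adjacent blocks greedily, and splits
  over-populated blocks at the median plane of their longest extent.  The
  result is a deterministic partition with block sizes in
  `[min_points, 2 * target_points]` and spatially contiguous blocks.
* `resample_block()` draws exactly `n_points` per block — without
  replacement when the block is large enough, with replacement otherwise —
  carrying labels with their points.
* `center_block()` subtracts the centroid and scales to unit radius,
  recording the transform; this makes absolute position codes comparable
  across blocks and the forward pass translation invariant end to end.

I/O supports plain `x y z [label]` ASCII (with `#` comments) and PLY
(ascii and binary little-endian; coordinates stored as doubles so round
trips are lossless).  The label encoding is fixed throughout: flower = 0,
leaf = 1, stem = 2.

## Synthetic plants

The package ships a procedural generator rather than a dataset.
`generate_plant()` samples stems on tubes around smooth space curves
(cubic splines through jittered control points), leaves on bent elliptical
patches attached to stems, and flowers as clusters of 5–8 petal patches at
stem tips, with isotropic Gaussian coordinate noise.  The
`interleave_factor` blends rigidly, per organ instance, between the
naturally attached, intertwined layout (1, the default) and a fully
separated grid layout (0) — useful for testing that organ entanglement is
what makes the task hard.  `generate_dataset()` jitters organ counts and
sizes per plant, splits *by whole plant* into train and test partitions
(the 9:2 shape by default), blocks and resamples each plant, and records a
manifest from which `regenerate_dataset()` rebuilds the dataset bitwise.

What the generator emulates: interwoven thin/flat/clustered organ
geometry, class imbalance (leaves dominate), *whole-plant* held-out
evaluation.  What it does not emulate: sensor artefacts (view-dependent
occlusion, range noise, varying density), botanical growth structure,
colour/normal channels.  Passing the held-out experiment below therefore
shows that the architecture can learn transferable organ geometry from
coordinates alone — not that it reaches any particular accuracy on real
scanner data.

## Numerical and design choices

* **Pooling over neighbourhoods** is max-pooling after a pointwise map —
  the standard symmetric-function device; it delivers the neighbour-order
  invariance the position code claims.  Ragged neighbourhoods are padded
  by repeating the centre with a validity mask, so pooling is unaffected.
* **Ball queries use a closed ball** (distance `<= radius`), nearest
  first, ties by lowest index; the centre always belongs to its own
  neighbourhood.
* **Farthest point sampling** starts at an explicit `start_index`
  (default: the first point) and breaks ties by lowest index, making the
  whole forward pass deterministic.
* **Top-k selection** is hard; gradients reach the score map through the
  sigmoid gate multiplying the selected features.
* **The RPC tuple**: whether the centre's absolute coordinates also
  enter the RPC branch is ambiguous in the lineage; the configuration flag
  `include_center_in_rpc` (default off) exposes both readings.
* **Whether the two position-code maps share weights** is similarly open;
  they are independent here (they consume different semantics — offsets
  vs. coordinates), per scale and per branch.
* **Optimiser**: Adam at learning rate 0.001 with batch accumulation 16 —
  the reference protocol — with an optional one-cycle schedule
  (`lr_schedule = "onecycle"`) that short training budgets benefit from.
* **Zero-norm heads** contribute nothing to the separation loss (epsilon
  guard); a fully zero head set is an error.
* **Checkpoints** are single RDS files embedding the full configuration,
  so evaluation and prediction need no side channel.

## Problem sizes used by the tests

The test suite and the acceptance script exercise a reduced configuration
chosen to keep a full run on a single desktop CPU core comfortable: 30
synthetic plants split 25/5 by plant, 512-point blocks, model width 64
with 4 heads (key/value width 16), 64 sampled centres, 64 selected local
anchors, 20 feature neighbours, 30 epochs of Adam under the one-cycle
schedule at peak rate 0.01 with batch accumulation 2, and per-epoch
rotation/mirror augmentation.  The capacity
sanity check overfits one 256-point block for 200 steps at peak rate
0.03.  These sizes are the package's scaled-down study conditions; the
default configuration (2048-point blocks, width 128) is the reference
protocol's.

## Limitations

* The trainer is a pure-R reverse-mode autodiff engine: correct (every op
  is finite-difference tested) but orders of magnitude slower than a GPU
  framework; the reference-scale configuration is usable for inference
  and small studies, not for large-scale training.
* Only X-Y-Z coordinates are consumed; RGB and normals are out of scope.
* Nearest-anchor/IDW upsampling limits boundary sharpness when
  `k_select` is small relative to the block size.
* The literal-form metric and loss variants (`literal = TRUE`,
  `mode = "binary_sum"`) exist for auditability and are not recommended.
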