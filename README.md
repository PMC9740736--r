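# plantseg3d

Per-point organ segmentation of 3D plant point clouds in R: every point of
a whole-plant cloud is classified as **flower**, **leaf** or **stem**.
Plant clouds are a hard segmentation target — organs are thin, small and
interwoven, and point sets are unordered and irregular — so the package
implements a two-branch attention network with two dedicated devices:

* **Position codes.** Each neighbourhood is described by a *relative*
  position code (RPC: centre-minus-neighbour offsets through a learnable
  map, max-pooled — exactly translation invariant and neighbour-order
  invariant) concatenated with an *absolute* position code (APC: the
  centre's coordinates through a second map):
  δ = θ(⋃ᵢ (Pᵢ−Pᵢ₁, …, Pᵢ−Pᵢⱼ)) ⊕ θ(Pᵢ).
* **A multi-head attention separation loss.** With flattened per-head
  output features f₁…f_h,
  sep = −(1/h²) Σ_{i≠j} |⟨fᵢ,fⱼ⟩| / (‖fᵢ‖‖fⱼ‖) ∈ [−(h−1)/h, 0].
  Applied as a penalty on head similarity during training, it keeps the
  attention heads attending to different feature subspaces instead of
  collapsing onto one.

The full objective is `Loss = CrossEntropy + loss_scal × Separation`, and
evaluation uses per-class intersection-over-union
`IoU_c = TP_c/(TP_c+FP_c+FN_c)` and their mean (MIoU).

The network (farthest point sampling, multi-scale ball-query grouping, a
learnable top-k point selector, three multi-head attention modules and a
per-point detection head) is trained with a small reverse-mode autodiff
engine written in base R — no deep-learning framework is required — and
every operator is finite-difference tested.  A procedural generator of
labelled synthetic plants (tubular stems, bent elliptical leaves,
petal-cluster flowers, with controllable organ interleaving) makes the
whole pipeline runnable and testable without any dataset download.

## Worked example

```r
library(plantseg3d)

# a synthetic dataset: 30 plants, split 25/5 by whole plant,
# 512-point blocks
ds <- generate_dataset(30, plant_spec(), seed = 101, n_test = 5,
                       target_points = 512L, n_points = 512L)

cfg <- plantseg_config(n_points = 512L, d_m = 64L, h = 4L,
                       d_k = 16L, d_v = 16L, c_high = 64L,
                       cls_hidden = 128L, k_feat = 20L,
                       m_centers = 64L, k_select = 64L,
                       epochs = 30L, batch_size = 2L,
                       lr = 0.01, lr_schedule = "onecycle",
                       augment = TRUE)

fit <- plantseg_fit(ds$train$blocks, ds$test$blocks, cfg, seed = 7)
fit
#> plantseg_model: attention segmentation network
#>   d_m=64  heads=4  centers=64  top-k=64  points/block=512
#>   epochs run: 30 (best epoch 18, val MIoU 0.702)

ev <- plantseg_evaluate(fit, ds$test$blocks)
round(ev$iou, 3)
#> flower   leaf   stem
#>  0.755  0.763  0.588
ev$miou
#> [1] 0.701738
```

The per-class IoU is the set overlap between predicted and true points of
that organ; the MIoU of ≈0.70 on plants never seen during training means
roughly two thirds to three quarters of each organ's predicted and true
point sets coincide (thin, heavily occluded stems are the hardest class).
Training history (`fit$history`) records the loss breakdown and the mean
pairwise head |cosine| per epoch — with the separation loss active the
cosine falls to ≈0.0004, without it (`ablation_config(cfg, "no_sep")`) it
stays two to three orders of magnitude higher (≈0.24 in the same
experiment).

Whole clouds can be segmented directly from files:

```r
predict(fit, my_cloud)                       # labels for a point_cloud
plantseg_predict_file(fit, "rose.ply", "rose_labelled.ply")
```

A thin command-line interface with `generate`, `split`, `train`,
`evaluate`, `predict` and `ablate` subcommands is installed at
`inst/cli/plantseg3d`.

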