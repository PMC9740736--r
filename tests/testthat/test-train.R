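make_blocks <- function(n_blocks, n = 64L, seed = 1L) {
  lapply(seq_len(n_blocks), function(i) tiny_block(seed = seed + i, n = n))
}

test_that("one epoch on two tiny blocks produces a finite history row", {
  cfg <- tiny_config(epochs = 1L, batch_size = 2L)
  fit <- plantseg_fit(make_blocks(2), config = cfg, seed = 1)
  expect_s3_class(fit, "plantseg_model")
  expect_equal(nrow(fit$history), 1L)
  expect_true(all(is.finite(unlist(
    fit$history[, c("total", "cross_entropy", "separation")]))))
})

test_that("the separation weight does not alter the first-step cross
           entropy", {
  cfg1 <- tiny_config(loss_scal = 1)
  cfg0 <- tiny_config(loss_scal = 0)
  blk <- tiny_block(seed = 9)
  cb <- center_block(blk)
  ns <- asNamespace("plantseg3d")
  w <- init_weights(cfg1, seed = 4)   # loss_scal does not affect the shapes
  r1 <- ns$model_grad_step(cb$coords, cb$labels, w, cfg1)
  r0 <- ns$model_grad_step(cb$coords, cb$labels, w, cfg0)
  expect_identical(r1$ce, r0$ce)
  expect_identical(r1$logits, r0$logits)
  # with loss_scal = 0 the optimised objective is the cross entropy alone
  expect_identical(r0$total, r0$ce)
})

test_that("training is deterministic given config and seed", {
  cfg <- tiny_config(epochs = 2L, batch_size = 2L)
  blocks <- make_blocks(3)
  f1 <- plantseg_fit(blocks, config = cfg, seed = 11)
  f2 <- plantseg_fit(blocks, config = cfg, seed = 11)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights, f2$weights)
})

test_that("the network can overfit one small block", {
  ds <- generate_dataset(3, plant_spec(), seed = 11, n_test = 1,
                         target_points = 256L, n_points = 256L)
  blk <- ds$train$blocks[[1]]
  cfg <- plantseg_config(n_points = 256L, d_m = 64L, d_k = 16L, d_v = 16L,
                         m_centers = 48L, k_select = 48L, c_high = 64L,
                         cls_hidden = 128L, epochs = 200L, batch_size = 1L,
                         patience = 1000L, lr = 0.03,
                         lr_schedule = "onecycle")
  fit <- plantseg_fit(list(blk), config = cfg, seed = 2)
  ev <- plantseg_evaluate(fit, list(blk))
  expect_gte(ev$miou, 0.95)
})

test_that("evaluation is additive over blocks and order free", {
  cfg <- tiny_config(epochs = 1L)
  blocks <- make_blocks(3, seed = 30)
  fit <- plantseg_fit(blocks, config = cfg, seed = 3)
  e1 <- plantseg_evaluate(fit, blocks)
  e2 <- plantseg_evaluate(fit, rev(blocks))
  expect_equal(e1$iou, e2$iou)
  expect_equal(e1$miou, e2$miou)
  # single-block report equals the direct metric computation
  one <- blocks[[1]]
  cb <- center_block(one)
  fw <- model_forward(cb, fit$weights, cfg)
  pred <- max.col(fw$logits, ties.method = "first") - 1L
  direct <- iou_miou(confusion_counts(pred, one$labels))
  es <- plantseg_evaluate(fit, blocks[1])
  expect_equal(es$miou, direct$miou)
  expect_equal(es$iou, direct$iou)
})

test_that("checkpoints embed the config and restore the model", {
  cfg <- tiny_config(epochs = 1L)
  fit <- plantseg_fit(make_blocks(2, seed = 40), config = cfg, seed = 8)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, f)
  back <- load_checkpoint(f)
  expect_identical(back$weights, fit$weights)
  expect_identical(back$config, fit$config)
  expect_error(load_checkpoint(withr::local_tempfile(fileext = ".rds") |>
                                 (\(p) { saveRDS(list(), p); p })()),
               "checkpoint")
})

test_that("prediction covers every input point and matches the forward
           pass on exact-size blocks", {
  cfg <- tiny_config(epochs = 1L)
  fit <- plantseg_fit(make_blocks(2, seed = 50), config = cfg, seed = 5)
  blk <- tiny_block(seed = 60, n = cfg$n_points)
  p1 <- predict(fit, blk)
  expect_length(p1, blk$n)
  expect_true(all(p1 %in% 0:2))
  fw <- model_forward(center_block(blk), fit$weights, cfg)
  expect_identical(p1, max.col(fw$logits, ties.method = "first") - 1L)
  # whole-plant path: every original point labelled, deterministic
  pl <- generate_plant(plant_spec(seed = 3))
  p2 <- predict(fit, pl, seed = 2)
  expect_length(p2, pl$n)
  expect_identical(p2, predict(fit, pl, seed = 2))
})

test_that("file prediction writes a labelled cloud in the input format", {
  cfg <- tiny_config(epochs = 1L)
  fit <- plantseg_fit(make_blocks(2, seed = 70), config = cfg, seed = 6)
  pl <- generate_plant(plant_spec(seed = 8))
  fin <- withr::local_tempfile(fileext = ".ply")
  fout <- withr::local_tempfile(fileext = ".ply")
  write_point_cloud(point_cloud(pl$coords), fin)
  plantseg_predict_file(fit, fin, fout)
  out <- read_point_cloud(fout)
  expect_equal(out$n, pl$n)
  expect_false(is.null(out$labels))
  expect_identical(out$coords, pl$coords)
})

test_that("ablation presets switch the documented components", {
  cfg <- tiny_config()
  expect_false(ablation_config(cfg, "no_rpc")$use_rpc)
  expect_equal(ablation_config(cfg, "no_sep")$loss_scal, 0)
  base <- ablation_config(cfg, "baseline")
  expect_false(base$use_rpc)
  expect_equal(base$loss_scal, 0)
  # the no-rpc network omits the rpc weight blocks entirely
  w <- init_weights(ablation_config(cfg, "no_rpc"), 1L)
  expect_length(grep("\\.rpc\\.", names(w)), 0L)
  blk <- tiny_block(seed = 80)
  fw <- model_forward(blk, w, ablation_config(cfg, "no_rpc"))
  expect_true(all(is.finite(fw$logits)))
})
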