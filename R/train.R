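# Training / evaluation / prediction orchestration.  The fitted model is a
# classed S3 object in the classic R modelling idiom.

prep_block <- function(block) center_block(block)

#' Fit the segmentation network
#'
#' Minimises the combined objective (cross-entropy plus `loss_scal` times
#' the attention-separation loss) with Adam over centred, fixed-size
#' blocks.  Gradients are accumulated over `batch_size` blocks per update.
#' Per-epoch losses and validation MIoU are logged; the weights with the
#' best validation MIoU are kept.  Fully deterministic for a fixed seed.
#'
#' @param train_blocks list of labelled [point_cloud] blocks, each with
#'   `config$n_points` points (see [resample_block()]).
#' @param val_blocks optional validation blocks (same form).
#' @param config a [plantseg_config()].
#' @param seed RNG seed for weight initialisation and block shuffling.
#' @param verbose print one line per epoch.
#' @return an object of class `plantseg_model`: `weights` (best), `config`,
#'   `history` (one row per epoch: losses, separation term, head |cosine|,
#'   validation MIoU), `final_weights`, `epochs_run`, `best_epoch`.
#' @export
plantseg_fit <- function(train_blocks, val_blocks = NULL,
                         config = plantseg_config(), seed = 1L,
                         verbose = FALSE) {
  if (length(train_blocks) == 0L) stop("no training blocks")
  if (!all(vapply(train_blocks, has_labels, logical(1))))
    stop("training blocks must be labelled")
  prep <- lapply(train_blocks, prep_block)
  prep_val <- lapply(val_blocks, prep_block)
  geoms <- lapply(prep, function(b) static_geometry(b$coords, config))
  geoms_val <- lapply(prep_val, function(b)
    static_geometry(b$coords, config))
  weights <- init_weights(config, seed)
  st <- adam_state(weights)
  hist <- list()
  best <- list(miou = -Inf, weights = weights, epoch = 0L)
  wait <- 0L
  order_seeds <- with_local_seed(seed + 1L,
    sample.int(.Machine$integer.max, config$epochs))
  sched_lr <- function(ep) {
    if (identical(config$lr_schedule, "onecycle")) {
      warm <- max(1L, round(0.075 * config$epochs))
      if (ep <= warm) config$lr * ep / warm
      else config$lr * 0.5 *
        (1 + cos(pi * (ep - warm) / max(1L, config$epochs - warm)))
    } else config$lr
  }
  for (ep in seq_len(config$epochs)) {
    plan <- with_local_seed(order_seeds[ep], list(
      ord = sample.int(length(prep)),
      theta = stats::runif(length(prep), 0, 2 * pi),
      mirror = sample(c(1, -1), length(prep), replace = TRUE)))
    ord <- plan$ord
    ce_sum <- sep_sum <- tot_sum <- cos_sum <- 0
    acc <- NULL; acc_n <- 0L
    for (b in ord) {
      blk <- prep[[b]]
      co <- blk$coords
      if (isTRUE(config$augment)) {
        th <- plan$theta[b]
        R <- matrix(c(cos(th), sin(th), 0,
                      -sin(th), cos(th), 0,
                      0, 0, 1), 3L, 3L)
        R[, 1L] <- R[, 1L] * plan$mirror[b]
        co <- co %*% R
      }
      r <- model_grad_step(co, blk$labels, weights, config,
                           geoms[[b]])
      if (!is.finite(r$total))
        stop("non-finite loss on block ", b, " at epoch ", ep,
             " (ce=", r$ce, ", sep=", r$sep, ")")
      ce_sum <- ce_sum + r$ce; sep_sum <- sep_sum + r$sep
      tot_sum <- tot_sum + r$total
      cos_sum <- cos_sum + mean(vapply(r$heads_list, head_cosine_mean,
                                       numeric(1)))
      acc <- if (is.null(acc)) r$grads else
        mapply(`+`, acc, r$grads, SIMPLIFY = FALSE)
      acc_n <- acc_n + 1L
      if (acc_n >= config$batch_size || b == ord[length(ord)]) {
        gm <- lapply(acc, `/`, acc_n)
        up <- adam_step(weights, gm, st, lr = sched_lr(ep),
                        weight_decay = config$weight_decay)
        weights <- up$params; st <- up$state
        acc <- NULL; acc_n <- 0L
      }
    }
    nb <- length(prep)
    val_miou <- NA_real_
    if (length(prep_val)) {
      val_miou <- evaluate_blocks(prep_val, weights, config,
                                  centred = TRUE, geoms = geoms_val)$miou
      if (val_miou > best$miou) {
        best <- list(miou = val_miou, weights = weights, epoch = ep)
        wait <- 0L
      } else wait <- wait + 1L
    }
    hist[[ep]] <- data.frame(epoch = ep, total = tot_sum / nb,
                             cross_entropy = ce_sum / nb,
                             separation = sep_sum / nb,
                             head_cosine = cos_sum / nb,
                             val_miou = val_miou)
    if (verbose)
      cat(sprintf(
        "epoch %3d  loss %.4f  ce %.4f  sep %+.4f  |cos| %.3f  val MIoU %s\n",
        ep, tot_sum / nb, ce_sum / nb, sep_sum / nb, cos_sum / nb,
        ifelse(is.na(val_miou), "-", sprintf("%.3f", val_miou))))
    if (length(prep_val) && wait >= config$patience) break
  }
  if (!length(prep_val)) best <- list(miou = NA_real_, weights = weights,
                                      epoch = length(hist))
  structure(list(weights = best$weights, config = config,
                 history = do.call(rbind, hist),
                 final_weights = weights,
                 epochs_run = length(hist), best_epoch = best$epoch,
                 best_val_miou = best$miou, seed = seed),
            class = "plantseg_model")
}

# Evaluate weights over blocks; blocks must be labelled.
evaluate_blocks <- function(blocks, weights, config, centred = FALSE,
                            geoms = NULL) {
  counts <- NULL
  for (i in seq_along(blocks)) {
    blk <- blocks[[i]]
    cb <- if (centred) blk else prep_block(blk)
    fw <- model_forward(cb, weights, config,
                        geom = if (!is.null(geoms)) geoms[[i]])
    pred <- max.col(fw$logits, ties.method = "first") - 1L
    counts <- add_counts(counts, confusion_counts(pred, cb$labels))
  }
  m <- iou_miou(counts)
  list(iou = m$iou, miou = m$miou, counts = counts)
}

#' Evaluate a fitted model on labelled blocks
#'
#' Accumulates per-class confusion counts over all blocks and reports
#' per-class IoU and MIoU.  Classes absent from both prediction and truth
#' are excluded from the mean with a warning.
#'
#' @param model a `plantseg_model`.
#' @param blocks list of labelled [point_cloud] blocks.
#' @return list: `iou` (named per-class), `miou`, `counts`.
#' @export
plantseg_evaluate <- function(model, blocks) {
  stopifnot(inherits(model, "plantseg_model"))
  evaluate_blocks(blocks, model$weights, model$config)
}

#' Mean pairwise head cosine of a weight set over blocks
#'
#' Averages [head_cosine_mean()] over all attention modules and all given
#' blocks — the quantity compared between ablation variants at
#' convergence.
#'
#' @param weights network weights.
#' @param config a [plantseg_config()].
#' @param blocks list of [point_cloud] blocks.
#' @return scalar in `[0, 1]`.
#' @export
model_head_cosine <- function(weights, config, blocks) {
  mean(vapply(blocks, function(blk) {
    fw <- model_forward(prep_block(blk), weights, config)
    mean(vapply(fw$heads_list, head_cosine_mean, numeric(1)))
  }, numeric(1)))
}

#' @export
print.plantseg_model <- function(x, ...) {
  cat("plantseg_model: attention segmentation network\n")
  cat(sprintf("  d_m=%d  heads=%d  centers=%d  top-k=%d  points/block=%d\n",
              x$config$d_m, x$config$h, x$config$m_centers,
              x$config$k_select, x$config$n_points))
  cat(sprintf("  epochs run: %d (best epoch %d%s)\n", x$epochs_run,
              x$best_epoch,
              if (is.na(x$best_val_miou)) "" else
                sprintf(", val MIoU %.3f", x$best_val_miou)))
  invisible(x)
}

#' @export
summary.plantseg_model <- function(object, ...) {
  h <- object$history
  cat("Training history (", nrow(h), " epochs):\n", sep = "")
  print(utils::tail(h, 5L), row.names = FALSE)
  cat(sprintf("\nParameters: %d matrices, %d values\n",
              length(object$weights),
              sum(vapply(object$weights, length, integer(1)))))
  invisible(object)
}

#' @export
coef.plantseg_model <- function(object, ...) object$weights

#' @export
plot.plantseg_model <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$total, type = "l", xlab = "epoch",
                 ylab = "loss", main = "training loss", ...)
  graphics::lines(h$epoch, h$cross_entropy, lty = 2)
  if (any(!is.na(h$val_miou))) {
    graphics::par(new = TRUE)
    graphics::plot(h$epoch, h$val_miou, type = "l", col = "forestgreen",
                   axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
    graphics::axis(4)
  }
  invisible(x)
}

#' Predict organ labels for a point cloud
#'
#' Whole clouds are block-split, resampled to the model's input size,
#' centred and segmented; labels map back to every original point via its
#' nearest resampled point.  A single block of exactly `n_points` points is
#' segmented directly.
#'
#' @param object a `plantseg_model`.
#' @param newdata a [point_cloud] (labelled or not) or a path readable by
#'   [read_point_cloud()].
#' @param seed seed for block resampling.
#' @param ... unused.
#' @return integer vector of predicted labels (0:2), one per input point.
#' @export
predict.plantseg_model <- function(object, newdata, seed = 1L, ...) {
  cloud <- if (is.character(newdata)) read_point_cloud(newdata) else newdata
  stopifnot(inherits(cloud, "point_cloud"))
  cfg <- object$config
  pred <- integer(cloud$n)
  if (cloud$n == cfg$n_points) {
    fw <- model_forward(prep_block(cloud), object$weights, cfg)
    return(max.col(fw$logits, ties.method = "first") - 1L)
  }
  bs <- split_into_blocks(cloud, cfg$n_points)
  for (j in seq_along(bs$blocks)) {
    rb <- resample_block(bs$blocks[[j]], cfg$n_points, seed = seed + j)
    fw <- model_forward(prep_block(rb), object$weights, cfg)
    pb <- max.col(fw$logits, ties.method = "first") - 1L
    # map back: each original block point takes its nearest resampled point
    src <- bs$blocks[[j]]$coords
    nn <- nearest_anchors(src, rb$coords, 1L)
    pred[bs$point_index[[j]]] <- pb[nn$idx[, 1L]]
  }
  pred
}

#' Segment a cloud file and write the labelled result
#'
#' @param model a `plantseg_model` or checkpoint path.
#' @param cloud_path input point-cloud file.
#' @param out_path output file; written in the input's format with the
#'   predicted label column.
#' @param seed resampling seed.
#' @return `out_path`, invisibly.
#' @export
plantseg_predict_file <- function(model, cloud_path, out_path, seed = 1L) {
  if (is.character(model)) model <- load_checkpoint(model)
  cloud <- read_point_cloud(cloud_path)
  pred <- predict(model, cloud, seed = seed)
  write_point_cloud(point_cloud(cloud$coords, pred), out_path)
  invisible(out_path)
}

## ---- checkpoints -----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is one RDS file holding a versioned list with the full
#' weight set, the embedded configuration and the training history, so
#' evaluation and prediction need no side channel.
#'
#' @param model a `plantseg_model`.
#' @param path file path.
#' @return `path` (save) or the restored `plantseg_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "plantseg_model"))
  obj <- list(format = "plantseg3d-checkpoint/1", model = unclass(model))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "plantseg3d-checkpoint/1"))
    stop("not a recognised checkpoint: ", path)
  structure(obj$model, class = "plantseg_model")
}
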