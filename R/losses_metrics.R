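# Training objective (attention-separation loss + cross-entropy) and
# segmentation metrics (per-class IoU, MIoU).

#' Multi-head attention separation loss
#'
#' Penalises attention heads whose output feature spaces point in similar
#' directions.  Each head's output matrix is flattened to a vector `f_i`; the
#' loss is the negative mean absolute cosine similarity over ordered head
#' pairs:
#' \deqn{-\frac{1}{h^2} \sum_{i \ne j}
#'   \frac{|\langle f_i, f_j\rangle|}{\|f_i\|_2 \|f_j\|_2}}
#' The value lies in `[-(h-1)/h, 0]`: 0 when all heads are pairwise
#' orthogonal, the lower bound exactly when all heads are pairwise parallel
#' (or anti-parallel — the absolute value penalises both).  Minimising it
#' (it enters the total objective with a positive weight) drives heads to
#' attend to different feature subspaces.
#'
#' @param heads list of `h >= 2` equally shaped numeric matrices, the
#'   per-head output features.
#' @param eps norm guard: pairs involving a head with norm below `eps`
#'   contribute 0.
#' @return a scalar in `[-(h-1)/h, 0]`.
#' @export
separation_loss <- function(heads, eps = 1e-12) {
  h <- length(heads)
  if (h < 2L) stop("separation loss needs at least 2 heads")
  dims <- unique(lapply(heads, dim))
  if (length(dims) > 1L) stop("head feature matrices must share a shape")
  fs <- lapply(heads, as.vector)
  nrm <- vapply(fs, function(f) sqrt(sum(f^2)), numeric(1))
  if (all(nrm < eps)) stop("all heads have zero norm")
  tot <- 0
  for (i in seq_len(h - 1L)) for (j in (i + 1L):h) {
    if (nrm[i] < eps || nrm[j] < eps) next
    tot <- tot + 2 * abs(sum(fs[[i]] * fs[[j]])) / (nrm[i] * nrm[j])
  }
  -tot / h^2
}

#' Mean pairwise absolute cosine between attention heads
#'
#' The diagnostic the separation loss drives down: the mean over unordered
#' head pairs of the absolute cosine similarity between flattened head
#' features.  Equals `-separation_loss * h / (h - 1)` when no head is
#' degenerate.
#'
#' @param heads list of per-head feature matrices.
#' @param eps norm guard.
#' @return scalar in `[0, 1]`.
#' @export
head_cosine_mean <- function(heads, eps = 1e-12) {
  h <- length(heads)
  fs <- lapply(heads, as.vector)
  nrm <- vapply(fs, function(f) sqrt(sum(f^2)), numeric(1))
  cs <- c()
  for (i in seq_len(h - 1L)) for (j in (i + 1L):h) {
    if (nrm[i] < eps || nrm[j] < eps) { cs <- c(cs, 0); next }
    cs <- c(cs, abs(sum(fs[[i]] * fs[[j]])) / (nrm[i] * nrm[j]))
  }
  mean(cs)
}

#' Drive attention heads apart by gradient descent on the separation term
#'
#' Treats the head feature matrices themselves as free parameters and
#' descends the separation penalty (the magnitude of [separation_loss()])
#' alone — the mechanism demonstration that the loss, used as a penalty on
#' head similarity, diversifies heads.
#'
#' @param heads list of `h >= 2` head matrices (the starting fixture).
#' @param steps maximum descent steps.
#' @param lr step size.
#' @param target stop when mean pairwise |cosine| drops below this.
#' @return list: `heads` (final), `cosine` (trajectory of mean |cosine|),
#'   `steps_to_target` (`NA` if never reached).
#' @export
minimize_head_similarity <- function(heads, steps = 500L, lr = 0.1,
                                     target = 0.05) {
  traj <- numeric(steps)
  hit <- NA_integer_
  for (s in seq_len(steps)) {
    tp <- ad_tape()
    hn <- lapply(seq_along(heads), function(i)
      ad_param(tp, heads[[i]], paste0("f", i)))
    sep <- ad_separation(tp, hn)
    pen <- ad_scale(tp, sep, -1)          # penalty = +mean pairwise |cos|
    gr <- ad_param_grads(tp, ad_backward(tp, pen))
    heads <- lapply(seq_along(heads), function(i)
      heads[[i]] - lr * gr[[paste0("f", i)]])
    traj[s] <- head_cosine_mean(heads)
    if (is.na(hit) && traj[s] < target) hit <- s
  }
  list(heads = heads, cosine = traj, steps_to_target = hit)
}

#' Segmentation cross-entropy
#'
#' Default mode `"categorical"`: mean multi-class cross-entropy of the
#' row-softmax of `logits` against one-hot targets — the standard
#' segmentation objective.  Mode `"binary_sum"` evaluates the per-class
#' binary form \eqn{-\sum_x p\log q + (1-p)\log(1-q)} with one-hot `p`
#' (averaged over points), retained for auditability.
#'
#' @param logits N x 3 matrix of unnormalised class scores (or a
#'   `segmentation_logits` object).
#' @param labels integer vector of true labels in 0:2.
#' @param mode `"categorical"` or `"binary_sum"`.
#' @return non-negative scalar.
#' @export
cross_entropy_loss <- function(logits, labels,
                               mode = c("categorical", "binary_sum")) {
  mode <- match.arg(mode)
  logits <- as.matrix(logits)
  labels <- as.integer(labels)
  if (length(labels) != nrow(logits))
    stop("one label per logit row required")
  if (any(!labels %in% ORGAN_CLASSES))
    stop("label outside the class set {0, 1, 2}")
  q <- row_softmax(logits)
  sel <- cbind(seq_len(nrow(q)), labels + 1L)
  if (mode == "categorical") {
    -mean(log(pmax(q[sel], 1e-12)))
  } else {
    p <- matrix(0, nrow(q), ncol(q))
    p[sel] <- 1
    -mean(rowSums(p * log(pmax(q, 1e-12)) +
                  (1 - p) * log(pmax(1 - q, 1e-12))))
  }
}

#' Combined training objective
#'
#' `total = cross_entropy + loss_scal * separation`, where the separation
#' term is the mean of [separation_loss()] over every attention module's
#' head set.
#'
#' @param logits N x 3 class scores.
#' @param labels integer labels in 0:2.
#' @param heads_list list of head sets, one per attention module (each a
#'   list of per-head matrices).
#' @param loss_scal non-negative weight of the separation term (default 1).
#' @param ce_mode forwarded to [cross_entropy_loss()].
#' @return object of class `loss_breakdown`: `cross_entropy`, `separation`,
#'   `loss_scal`, `total`.
#' @export
combined_loss <- function(logits, labels, heads_list, loss_scal = 1,
                          ce_mode = "categorical") {
  if (length(heads_list) == 0L) stop("heads_list must be non-empty")
  ce <- cross_entropy_loss(logits, labels, ce_mode)
  sep <- mean(vapply(heads_list, separation_loss, numeric(1)))
  structure(list(cross_entropy = ce, separation = sep,
                 loss_scal = loss_scal, total = ce + loss_scal * sep),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss: total %.4f = CE %.4f + %.2g * separation %.4f\n",
              x$total, x$cross_entropy, x$loss_scal, x$separation))
  invisible(x)
}

#' Per-class confusion counts
#'
#' One-vs-rest tallies (TP, FP, FN) per organ class from the full confusion
#' matrix of predicted vs. true labels.
#'
#' @param pred_labels,true_labels equal-length integer vectors in 0:2.
#' @param k number of classes (default 3).
#' @return object of class `confusion_counts` with `tp`, `fp`, `fn` (named
#'   per class), `k`, `n`, and the `k x k` `matrix` (rows = truth).
#' @export
confusion_counts <- function(pred_labels, true_labels, k = 3L) {
  pred_labels <- as.integer(pred_labels)
  true_labels <- as.integer(true_labels)
  if (length(pred_labels) != length(true_labels))
    stop("pred and true label vectors must have equal length")
  lv <- 0:(k - 1L)
  cm <- table(factor(true_labels, levels = lv),
              factor(pred_labels, levels = lv))
  cm <- matrix(as.integer(cm), k, k)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  nms <- names(ORGAN_CLASSES)[seq_len(k)]
  structure(list(tp = stats::setNames(tp, nms),
                 fp = stats::setNames(fp, nms),
                 fn = stats::setNames(fn, nms),
                 k = k, n = length(true_labels), matrix = cm),
            class = "confusion_counts")
}

# Elementwise sum of two count objects (evaluation over many blocks).
add_counts <- function(a, b) {
  if (is.null(a)) return(b)
  a$tp <- a$tp + b$tp; a$fp <- a$fp + b$fp; a$fn <- a$fn + b$fn
  a$n <- a$n + b$n; a$matrix <- a$matrix + b$matrix
  a
}

#' Per-class IoU and mean IoU
#'
#' IoU of class c is the ratio of intersection to union of the predicted and
#' true point sets: `TP / (TP + FP + FN)`.  Classes with an empty union are
#' undefined and excluded from the mean with a warning.  Setting
#' `literal = TRUE` evaluates the variant denominator `TP + FP - FN`
#' (kept for auditability; it is not a set ratio and can exceed 1 or divide
#' by zero).
#'
#' @param counts a [confusion_counts] object.
#' @param literal use the variant denominator (default `FALSE`).
#' @return list with `iou` (named per-class vector, `NA` where undefined)
#'   and `miou`.
#' @export
iou_miou <- function(counts, literal = FALSE) {
  stopifnot(inherits(counts, "confusion_counts"))
  denom <- if (literal) counts$tp + counts$fp - counts$fn
           else counts$tp + counts$fp + counts$fn
  iou <- ifelse(denom > 0, counts$tp / denom, NA_real_)
  undef <- counts$tp + counts$fp + counts$fn == 0
  iou[undef] <- NA_real_
  if (any(undef))
    warning("class(es) with empty union excluded from MIoU: ",
            paste(names(iou)[undef], collapse = ", "))
  if (all(is.na(iou))) stop("IoU undefined for every class")
  list(iou = iou, miou = mean(iou, na.rm = TRUE))
}
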