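test_that("separation loss reproduces its analytic fixtures", {
  f <- matrix(c(1, 2, -1, 0.5), 2, 2)
  expect_equal(separation_loss(list(f, f)), -0.5)            # identical pair
  expect_equal(separation_loss(list(f, 2.5 * f)), -0.5)      # scale invariant
  o1 <- matrix(c(1, 0), 1, 2); o2 <- matrix(c(0, 1), 1, 2)
  expect_equal(separation_loss(list(o1, o2)), 0)             # orthogonal
  # three heads with hand-computed pairwise cosines (1/sqrt(2) twice, 0)
  f1 <- matrix(c(1, 0), 1); f2 <- matrix(c(1, 1) / sqrt(2), 1)
  f3 <- matrix(c(0, 1), 1)
  expect_equal(separation_loss(list(f1, f2, f3)), -4 / (9 * sqrt(2)),
               tolerance = 1e-12)
  expect_equal(round(separation_loss(list(f1, f2, f3)), 4), -0.3143)
})

test_that("separation loss equals a double-loop oracle and obeys bounds", {
  for (seed in 1:50) {
    set.seed(seed)
    h <- sample(2:5, 1)
    heads <- replicate(h, matrix(rnorm(12), 3, 4), simplify = FALSE)
    # independent oracle: explicit double loop over ordered pairs
    or <- 0
    for (i in seq_len(h)) for (j in seq_len(h)) if (i != j) {
      fi <- as.vector(heads[[i]]); fj <- as.vector(heads[[j]])
      or <- or + abs(sum(fi * fj)) / sqrt(sum(fi^2) * sum(fj^2))
    }
    or <- -or / h^2
    got <- separation_loss(heads)
    expect_equal(got, or, tolerance = 1e-12)
    expect_lte(got, 0)
    expect_gte(got, -(h - 1) / h)
  }
  # lower bound attained exactly when all heads pairwise parallel
  base <- matrix(rnorm(8), 2, 4)
  par4 <- lapply(c(1, -2, 0.5, 3), function(s) s * base)
  expect_equal(separation_loss(par4), -3 / 4)
})

test_that("degenerate heads are guarded", {
  z <- matrix(0, 2, 2); f <- matrix(1, 2, 2)
  expect_equal(separation_loss(list(z, f)), 0)   # zero-norm pair term is 0
  expect_error(separation_loss(list(z, z)), "zero norm")
  expect_error(separation_loss(list(f)), "at least 2")
  expect_error(separation_loss(list(f, matrix(1, 3, 2))), "share a shape")
})

test_that("separation gradient matches finite differences", {
  ns <- asNamespace("plantseg3d")
  for (seed in 1:5) {
    set.seed(seed)
    heads <- replicate(3, matrix(rnorm(10), 2, 5), simplify = FALSE)
    tp <- ns$ad_tape()
    hn <- lapply(1:3, function(i) ns$ad_param(tp, heads[[i]], paste0("f", i)))
    sep <- ns$ad_separation(tp, hn)
    gr <- ns$ad_param_grads(tp, ns$ad_backward(tp, sep))
    for (i in 1:3) {
      fd <- fd_grad(function(x) {
        hs <- heads; hs[[i]] <- x
        separation_loss(hs)
      }, heads[[i]])
      expect_equal(gr[[paste0("f", i)]], fd, tolerance = 1e-4)
    }
  }
})

test_that("descending the separation penalty diversifies a near-parallel
           pair within 500 steps", {
  set.seed(5)
  f1 <- matrix(rnorm(24), 4, 6); f1 <- f1 / sqrt(sum(f1^2))
  f2 <- f1 + 0.05 * matrix(rnorm(24), 4, 6); f2 <- f2 / sqrt(sum(f2^2))
  expect_gt(head_cosine_mean(list(f1, f2)), 0.9)
  r <- minimize_head_similarity(list(f1, f2), steps = 500L, lr = 0.1)
  expect_false(is.na(r$steps_to_target))
  expect_lte(r$steps_to_target, 500L)
  expect_lt(tail(r$cosine, 1), 0.05)
})

test_that("cross entropy matches closed forms and a loop oracle", {
  # near-one-hot prediction -> ~0 in both modes
  hot <- matrix(c(50, 0, 0), 1, 3)
  expect_equal(cross_entropy_loss(hot, 0L), 0, tolerance = 1e-12)
  expect_equal(cross_entropy_loss(hot, 0L, mode = "binary_sum"), 0,
               tolerance = 1e-12)
  # uniform prediction -> ln 3 per point
  unif <- matrix(0, 5, 3)
  expect_equal(cross_entropy_loss(unif, c(0L, 1L, 2L, 0L, 1L)), log(3))
  # random logits vs explicit per-point loop
  set.seed(10)
  lg <- matrix(rnorm(30), 10, 3)
  lb <- sample(0:2, 10, replace = TRUE)
  or <- 0
  for (i in 1:10) {
    p <- exp(lg[i, ]) / sum(exp(lg[i, ]))
    or <- or - log(p[lb[i] + 1])
  }
  expect_equal(cross_entropy_loss(lg, lb), or / 10, tolerance = 1e-6)
  expect_error(cross_entropy_loss(lg, c(lb[-1], 7L)), "class set")
  expect_error(cross_entropy_loss(lg, lb[-1]), "one label per")
})

test_that("combined loss decomposes per its contract", {
  set.seed(3)
  lg <- matrix(rnorm(24), 8, 3)
  lb <- sample(0:2, 8, replace = TRUE)
  heads <- list(replicate(3, matrix(rnorm(8), 2, 4), simplify = FALSE),
                replicate(3, matrix(rnorm(8), 2, 4), simplify = FALSE))
  br <- combined_loss(lg, lb, heads, loss_scal = 0.7)
  expect_equal(br$total, br$cross_entropy + 0.7 * br$separation)
  expect_equal(br$separation,
               mean(vapply(heads, separation_loss, numeric(1))))
  # loss_scal = 0 reduces the total to the cross entropy exactly
  expect_equal(combined_loss(lg, lb, heads, loss_scal = 0)$total,
               cross_entropy_loss(lg, lb))
  # mutually orthogonal heads carry no penalty
  ortho <- list(list(matrix(c(1, 0, 0, 0), 1), matrix(c(0, 1, 0, 0), 1),
                     matrix(c(0, 0, 1, 0), 1)))
  br0 <- combined_loss(lg, lb, ortho, loss_scal = 1)
  expect_equal(br0$separation, 0)
  expect_equal(br0$total, br0$cross_entropy)
  # known components: ce 0.9 and separation -0.5 total 0.4
  expect_equal(0.9 + 1 * (-0.5), 0.4)
  expect_error(combined_loss(lg, lb, list(), 1), "non-empty")
})

test_that("confusion counts match the brute-force confusion matrix", {
  t3 <- c(0L, 1L, 2L)
  cc <- confusion_counts(t3, t3)
  expect_true(all(cc$fp == 0) && all(cc$fn == 0))
  expect_equal(unname(cc$tp), c(1L, 1L, 1L))
  # everything predicted flower
  cc2 <- confusion_counts(c(0L, 0L, 0L), t3)
  expect_equal(cc2$tp[["flower"]], 1L)
  expect_equal(cc2$fp[["flower"]], 2L)
  expect_equal(cc2$fn[["leaf"]], 1L)
  expect_equal(cc2$fn[["stem"]], 1L)
  # random pairs vs 9-cell oracle
  set.seed(77)
  pred <- sample(0:2, 1000, replace = TRUE)
  true <- sample(0:2, 1000, replace = TRUE)
  cc3 <- confusion_counts(pred, true)
  for (c in 0:2) {
    expect_equal(cc3$tp[[c + 1]], sum(pred == c & true == c))
    expect_equal(cc3$fp[[c + 1]], sum(pred == c & true != c))
    expect_equal(cc3$fn[[c + 1]], sum(pred != c & true == c))
  }
  expect_equal(sum(cc3$tp) + sum(cc3$fn), 1000L)
  expect_error(confusion_counts(pred, true[-1]), "equal length")
})

test_that("iou/miou equals the set-based intersection over union", {
  # perfect prediction
  m <- iou_miou(confusion_counts(c(0L, 1L, 2L), c(0L, 1L, 2L)))
  expect_true(all(m$iou == 1))
  expect_equal(m$miou, 1)
  # 5-point worked example: TP=3, FP=1, FN=1 -> |A∩B|/|A∪B| = 3/5
  pred <- c(0L, 0L, 0L, 0L, 1L)
  true <- c(0L, 0L, 0L, 1L, 0L)
  cc <- confusion_counts(pred, true)
  A <- which(pred == 0L); B <- which(true == 0L)
  expect_equal(length(intersect(A, B)) / length(union(A, B)), 0.6)
  expect_equal(suppressWarnings(iou_miou(cc))$iou[["flower"]], 0.6)
  # joint label permutation leaves IoU multiset unchanged
  set.seed(12)
  p <- sample(0:2, 300, replace = TRUE); t <- sample(0:2, 300, replace = TRUE)
  perm <- c(2L, 0L, 1L)
  m1 <- iou_miou(confusion_counts(p, t))
  m2 <- iou_miou(confusion_counts(perm[p + 1], perm[t + 1]))
  expect_equal(sort(unname(m1$iou)), sort(unname(m2$iou)))
  expect_equal(m1$miou, m2$miou)
  # literal variant denominator retained behind the flag
  cc2 <- confusion_counts(c(0L, 0L, 1L, 2L), c(0L, 1L, 1L, 2L))
  lit <- iou_miou(cc2, literal = TRUE)
  expect_equal(lit$iou[["flower"]],
               cc2$tp[["flower"]] /
                 (cc2$tp[["flower"]] + cc2$fp[["flower"]] -
                    cc2$fn[["flower"]]))
  # class absent from both sides is excluded with a warning
  expect_warning(m3 <- iou_miou(confusion_counts(c(0L, 1L), c(0L, 1L))),
                 "stem")
  expect_true(is.na(m3$iou[["stem"]]))
  expect_equal(m3$miou, 1)
})
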