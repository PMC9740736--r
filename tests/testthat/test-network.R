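test_that("single-head attention equals an explicit softmax loop oracle", {
  cfg <- plantseg_config(d_m = 8L, h = 1L, d_k = 8L, d_v = 8L)
  set.seed(1)
  X <- matrix(rnorm(32), 4, 8)
  Y <- matrix(rnorm(48), 6, 8)
  w <- attention_init(cfg, seed = 2)
  w$WO <- diag(8)                                   # pass-through projection
  got <- multi_head_attention(X, Y, w, cfg, use_residual = FALSE,
                              use_layernorm = FALSE, use_ffn = FALSE)
  # oracle: plain scaled-dot-product attention, one row at a time
  Q <- X %*% w$WQ1; K <- Y %*% w$WK1; V <- Y %*% w$WV1
  oracle <- matrix(0, 4, 8)
  for (i in 1:4) {
    s <- as.vector(K %*% Q[i, ]) / sqrt(8)
    a <- exp(s - max(s)); a <- a / sum(a)
    oracle[i, ] <- colSums(V * a)
  }
  expect_equal(got$features, oracle, tolerance = 1e-12)
  expect_equal(got$heads[[1]], oracle, tolerance = 1e-12)
})

test_that("attention weights are row-stochastic and symmetric under
           key/value permutation", {
  cfg <- plantseg_config(d_m = 16L, h = 4L, d_k = 8L, d_v = 4L)
  w <- attention_init(cfg, seed = 3)
  set.seed(4)
  X <- matrix(rnorm(8 * 16), 8, 16)
  Y <- matrix(rnorm(5 * 16), 5, 16)
  r <- multi_head_attention(X, Y, w, cfg)
  for (a in r$attn)
    expect_equal(rowSums(a), rep(1, 8), tolerance = 1e-5)
  # permuting keys and values together leaves the output unchanged
  perm <- c(3, 1, 5, 2, 4)
  r2 <- multi_head_attention(X, Y[perm, ], w, cfg)
  expect_equal(r$features, r2$features, tolerance = 1e-12)
  # identical query rows produce identical output rows
  Xc <- matrix(rep(X[1, ], each = 8), 8, 16)
  rc <- multi_head_attention(Xc, Y, w, cfg)
  expect_equal(rc$features, rc$features[rep(1, 8), ], tolerance = 1e-12)
})

test_that("self and cross attention are definitional delegations", {
  cfg <- plantseg_config(d_m = 16L, h = 2L, d_k = 8L, d_v = 8L)
  w <- attention_init(cfg, seed = 5)
  set.seed(6)
  P <- matrix(rnorm(6 * 16), 6, 16)
  Q <- matrix(rnorm(9 * 16), 9, 16)
  expect_identical(attention_self(P, w, cfg),
                   multi_head_attention(P, P, w, cfg))
  expect_identical(attention_cross(P, Q, w, cfg),
                   multi_head_attention(P, Q, w, cfg))
  # single token: weight 1 on itself, finite output
  r1 <- attention_self(P[1, , drop = FALSE], w, cfg)
  expect_equal(r1$attn[[1]], matrix(1, 1, 1))
  expect_true(all(is.finite(r1$features)))
  expect_error(multi_head_attention(P[, 1:8], P[, 1:8], w, cfg), "d_m")
})

test_that("identically initialised heads collapse to identical features", {
  cfg <- plantseg_config(d_m = 16L, h = 3L, d_k = 8L, d_v = 8L)
  w <- attention_init(cfg, seed = 7)
  for (i in 2:3) {
    w[[paste0("WQ", i)]] <- w$WQ1
    w[[paste0("WK", i)]] <- w$WK1
    w[[paste0("WV", i)]] <- w$WV1
  }
  set.seed(8)
  P <- matrix(rnorm(5 * 16), 5, 16)
  r <- attention_self(P, w, cfg)
  expect_identical(r$heads[[1]], r$heads[[2]])
  expect_identical(r$heads[[1]], r$heads[[3]])
  # the degenerate case the separation loss penalises maximally
  expect_equal(separation_loss(r$heads), -(3 - 1) / 3)
})

test_that("global branch produces one token per sampled centre", {
  cfg <- tiny_config()
  blk <- tiny_block(seed = 21)
  w <- init_weights(cfg, 1L)
  hd <- matrix(rnorm(blk$n * cfg$c_high), blk$n, cfg$c_high)
  r <- pc_msg_forward(blk, hd, w, cfg)
  expect_equal(length(r$centers), cfg$m_centers)
  expect_equal(dim(r$tokens), c(cfg$m_centers, cfg$d_m))
  expect_true(all(is.finite(r$tokens)))
  # radii below the nearest-neighbour gap still give finite tokens
  cfg2 <- tiny_config()
  gap <- min(dist(blk$coords))
  cfg2$radii <- gap * c(0.1, 0.2, 0.3)
  w2 <- init_weights(cfg2, 1L)
  r2 <- pc_msg_forward(blk, hd, w2, cfg2)
  expect_true(all(is.finite(r2$tokens)))
  cfg3 <- tiny_config(); cfg3$radii <- c(0.1, 0.2)
  expect_error(plantseg_config(radii = c(0.1, 0.2)), "3 ball-query radii")
})

test_that("top-k selection follows the score ordering with index ties", {
  cfg <- tiny_config()
  blk <- tiny_block(seed = 22)
  w <- init_weights(cfg, 2L)
  feats <- matrix(rnorm(blk$n * cfg$c_high), blk$n, cfg$c_high)
  r <- pc_sortnet_forward(blk, feats, w, cfg)
  # selected set equals the full-sort oracle's top k
  oracle <- order(-r$scores, seq_along(r$scores))[seq_len(cfg$k_select)]
  expect_identical(r$selected, oracle)
  expect_equal(dim(r$tokens), c(cfg$k_select, cfg$d_m))
  # constant score map -> the k lowest indices win by the tie rule
  wz <- w
  wz$sort.score.W1[] <- 0; wz$sort.score.W2[] <- 0
  rz <- pc_sortnet_forward(blk, feats, wz, cfg)
  expect_identical(rz$selected, seq_len(cfg$k_select))
  # k = N is a permutation of all points sorted by score
  cfgN <- tiny_config(); cfgN$k_select <- blk$n
  rN <- pc_sortnet_forward(blk, feats, init_weights(cfgN, 2L), cfgN)
  expect_identical(sort(rN$selected), seq_len(blk$n))
  expect_true(all(diff(rN$scores[rN$selected]) <= 0))
  cfgBig <- tiny_config(); cfgBig$k_select <- blk$n + 1L
  expect_error(pc_sortnet_forward(blk, feats, init_weights(cfgBig, 2L),
                                  cfgBig), "k_select")
})

test_that("detection head is cross attention plus the pointwise stack", {
  cfg <- tiny_config()
  w <- init_weights(cfg, 3L)
  set.seed(9)
  loc <- matrix(rnorm(10 * cfg$d_m), 10, cfg$d_m)
  glo <- matrix(rnorm(12 * cfg$d_m), 12, cfg$d_m)
  r <- detection_head(loc, glo, w, cfg)
  expect_equal(dim(r$features), c(10, cfg$d_m))
  expect_equal(length(r$heads), cfg$h)
  # definitional: equals attention_cross with the same module weights,
  # followed by the head MLP
  sub <- w[grep("^att\\.cross\\.", names(w))]
  names(sub) <- sub("^att\\.cross\\.", "", names(sub))
  ref <- attention_cross(loc, glo, sub, cfg)
  ns <- asNamespace("plantseg3d")
  expect_equal(r$features,
               ns$mlp_apply(w[grep("^head\\.mlp\\.", names(w))] |>
                              stats::setNames(c("W1", "b1")), ref$features),
               tolerance = 1e-12)
  expect_equal(r$heads, ref$heads, tolerance = 1e-12)
})

test_that("model forward yields per-point logits deterministically", {
  cfg <- tiny_config()
  blk <- tiny_block(seed = 23)
  w <- init_weights(cfg, 4L)
  r1 <- model_forward(blk, w, cfg)
  expect_equal(dim(r1$logits), c(blk$n, 3L))
  expect_true(all(is.finite(r1$logits)))
  expect_equal(length(r1$heads_list), 3L)            # self, lg, cross
  expect_true(all(vapply(r1$heads_list, length, integer(1)) == cfg$h))
  r2 <- model_forward(blk, w, cfg)
  expect_identical(r1$logits, r2$logits)             # bitwise repeatable
})

test_that("rigid translation leaves the sampling pattern and relative-code
           branch unchanged", {
  cfg <- tiny_config()
  blk <- tiny_block(seed = 24)
  shift <- point_cloud(sweep(blk$coords, 2, c(3, -2, 7), "+"), blk$labels)
  # the sampling pattern is a function of pairwise distances only
  expect_identical(
    farthest_point_sample(blk, cfg$m_centers, cfg$start_index),
    farthest_point_sample(shift, cfg$m_centers, cfg$start_index))
  # matched centres carry identical relative codes (up to float roundoff)
  fps <- farthest_point_sample(blk, cfg$m_centers, cfg$start_index)
  n1 <- ball_query(blk, fps, cfg$radii[1], cfg$k_max)
  n2 <- ball_query(shift, fps, cfg$radii[1], cfg$k_max)
  expect_identical(n1$neighbor_idx, n2$neighbor_idx)
  expect_equal(relative_codes(blk, n1), relative_codes(shift, n2),
               tolerance = 1e-12)
  # in the pipeline blocks are centred first, making the forward pass
  # exactly translation invariant end to end
  expect_equal(center_block(blk)$coords, center_block(shift)$coords,
               tolerance = 1e-12)
  w <- init_weights(cfg, 5L)
  r1 <- model_forward(center_block(blk), w, cfg)
  r2 <- model_forward(center_block(shift), w, cfg)
  expect_equal(r1$logits, r2$logits, tolerance = 1e-8)
})

test_that("one optimisation step moves every attention module", {
  cfg <- tiny_config()
  blk <- tiny_block(seed = 25)
  w <- init_weights(cfg, 6L)
  ns <- asNamespace("plantseg3d")
  gs <- ns$model_grad_step(blk$coords, blk$labels, w, cfg)
  st <- ns$adam_state(w)
  up <- ns$adam_step(w, gs$grads, st, lr = 1e-3)
  for (mod in c("att.self", "att.lg", "att.cross")) {
    moved <- vapply(grep(paste0("^", mod, "\\."), names(w), value = TRUE),
                    function(nm) any(up$params[[nm]] != w[[nm]]),
                    logical(1))
    expect_true(any(moved), label = paste("gradient reaches", mod))
  }
})
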