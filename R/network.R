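# The segmentation network: a two-branch attention architecture over point
# blocks.  The global branch (multi-scale grouping around farthest-point
# samples) and the local branch (learnable top-k point selection) both use
# the position-code network; their token sets are fused by cross attention
# in the detection head.  Three attention modules ("self", "lg", "cross")
# expose their per-head features to the separation loss.

#' Network and training configuration
#'
#' Defaults follow the reference training protocol where stated (Adam,
#' learning rate 0.001, batch size 16, 2048 input points); architecture
#' hyperparameters the protocol leaves open are exposed here with
#' backbone-lineage defaults.
#'
#' @param n_points points per input block.
#' @param d_m model width of the attention modules.
#' @param h number of attention heads.
#' @param d_k,d_v per-head key/query and value widths.
#' @param c_high width of the shared high-dimensional point feature
#'   extractor.
#' @param c_pos width of each position-code branch (RPC and APC).
#' @param c_scale per-scale feature width in the global branch.
#' @param m_centers number of farthest-point-sampled centres (global
#'   tokens).
#' @param radii the three ball-query radii of the multi-scale grouping, in
#'   units of the normalised (unit-radius) block.
#' @param k_max maximum neighbourhood size per ball (global branch).
#' @param k_select number of points kept by the learnable top-k selection
#'   (local tokens).
#' @param r_local,k_max_local ball-query radius / neighbourhood cap of the
#'   local branch.
#' @param ffn_width hidden width of the feed-forward block inside each
#'   attention module.
#' @param score_hidden hidden width of the importance-score map.
#' @param k_feat neighbour count of the local aggregation step in the
#'   shared feature extractor.
#' @param cls_hidden hidden width of the final per-point classifier.
#' @param start_index first point picked by farthest point sampling.
#' @param upsample `"idw3"` (inverse-distance interpolation over the 3
#'   nearest selected anchors) or `"nearest"` (nearest-anchor propagation).
#' @param include_center_in_rpc also feed centre coordinates to the RPC
#'   branch (default off).
#' @param use_rpc include the relative-position-code branch (ablation
#'   switch).
#' @param loss_scal weight of the separation loss in the total objective.
#' @param ce_mode cross-entropy mode, see [cross_entropy_loss()].
#' @param weight_decay decoupled weight decay applied after each Adam
#'   update (0 disables it).
#' @param class_weights `"none"` (plain mean) or `"balanced"`
#'   (inverse-frequency point weights per block — useful because the
#'   evaluation metric averages classes).
#' @param lr,batch_size,epochs,patience Adam learning rate, gradient
#'   accumulation batch, epoch budget and early-stopping patience.
#' @param augment apply a random rotation about the vertical axis plus a
#'   random horizontal mirror to each block at every epoch during
#'   training.  Both are distance preserving, so the cached block
#'   geometry (neighbourhoods, sampling pattern, shape descriptors)
#'   remains exact.
#' @param lr_schedule `"constant"` (the reference protocol) or
#'   `"onecycle"` (linear warmup to `lr` over ~7.5% of the epochs, then
#'   cosine decay — useful for short training budgets).
#' @return a named list of class `plantseg_config`.
#' @export
plantseg_config <- function(n_points = 2048L, d_m = 128L, h = 4L,
                            d_k = 32L, d_v = 32L, c_high = 32L,
                            c_pos = 16L, c_scale = 32L,
                            m_centers = 128L, radii = c(0.1, 0.2, 0.4),
                            k_max = 16L, k_select = 64L,
                            r_local = 0.2, k_max_local = 16L,
                            ffn_width = d_m, score_hidden = 16L,
                            k_feat = 16L,
                            cls_hidden = 64L,
                            start_index = 1L,
                            upsample = c("idw3", "nearest"),
                            include_center_in_rpc = FALSE,
                            use_rpc = TRUE,
                            loss_scal = 1, ce_mode = "categorical",
                            class_weights = c("none", "balanced"),
                            weight_decay = 0, augment = FALSE,
                            lr = 1e-3, batch_size = 16L, epochs = 100L,
                            patience = 20L,
                            lr_schedule = c("constant", "onecycle")) {
  lr_schedule <- match.arg(lr_schedule)
  class_weights <- match.arg(class_weights)
  upsample <- match.arg(upsample)
  if (length(radii) != 3L)
    stop("exactly 3 ball-query radii are required, got ", length(radii))
  if (anyDuplicated(radii)) stop("the 3 radii must be distinct")
  cfg <- as.list(environment())
  int_fields <- c("n_points", "d_m", "h", "d_k", "d_v", "c_high", "c_pos",
                  "c_scale", "m_centers", "k_max", "k_select",
                  "k_max_local", "ffn_width", "score_hidden", "k_feat",
                  "cls_hidden",
                  "start_index", "batch_size", "epochs", "patience")
  for (f in int_fields) cfg[[f]] <- as.integer(cfg[[f]])
  if (any(unlist(cfg[int_fields]) < 1L)) stop("config counts must be >= 1")
  if (cfg$loss_scal < 0) stop("loss_scal must be >= 0")
  structure(cfg, class = "plantseg_config")
}

#' Apply an ablation preset to a configuration
#'
#' The ablation harness mirrors the design study: the full model, the model
#' without relative position codes (`no_rpc`), the model trained without
#' the separation loss (`no_sep`, i.e. `loss_scal = 0`), and the plain
#' backbone (`baseline`, both switches off).
#'
#' @param config a [plantseg_config()].
#' @param variant one of `"full"`, `"no_rpc"`, `"no_sep"`, `"baseline"`.
#' @return the modified config.
#' @export
ablation_config <- function(config,
                            variant = c("full", "no_rpc", "no_sep",
                                        "baseline")) {
  variant <- match.arg(variant)
  if (variant %in% c("no_rpc", "baseline")) config$use_rpc <- FALSE
  if (variant %in% c("no_sep", "baseline")) config$loss_scal <- 0
  config
}

#' Initialise the weights of one attention module
#'
#' @param config a [plantseg_config()] (only `h`, `d_m`, `d_k`, `d_v`,
#'   `ffn_width` are used).
#' @param seed RNG seed.
#' @return named list: per-head `WQi`/`WKi`/`WVi`, output projection `WO`,
#'   layer-norm gains/offsets `ln1.g` ... and feed-forward weights
#'   `ffn.W1` ...
#' @export
attention_init <- function(config, seed = 1L) {
  with_local_seed(seed, {
    w <- list()
    for (i in seq_len(config$h)) {
      w[[paste0("WQ", i)]] <- rand_mat(config$d_m, config$d_k)
      w[[paste0("WK", i)]] <- rand_mat(config$d_m, config$d_k)
      w[[paste0("WV", i)]] <- rand_mat(config$d_m, config$d_v)
    }
    w$WO <- rand_mat(config$h * config$d_v, config$d_m)
    w[["ln1.g"]] <- matrix(1, 1L, config$d_m)
    w[["ln1.b"]] <- matrix(0, 1L, config$d_m)
    w[["ln2.g"]] <- matrix(1, 1L, config$d_m)
    w[["ln2.b"]] <- matrix(0, 1L, config$d_m)
    ffn <- mlp_init(c(config$d_m, config$ffn_width, config$d_m),
                    seed = seed + 7L)
    for (nm in names(ffn)) w[[paste0("ffn.", nm)]] <- ffn[[nm]]
    w
  })
}

rand_mat <- function(a, b) {
  matrix(stats::rnorm(a * b, sd = sqrt(2 / (a + b))), a, b)
}

#' Initialise all network weights
#'
#' @param config a [plantseg_config()].
#' @param seed RNG seed; deterministic.
#' @return flat named list of parameter matrices.
#' @export
init_weights <- function(config, seed = 1L) {
  add <- function(w, sub, prefix) {
    for (nm in names(sub)) w[[paste0(prefix, ".", nm)]] <- sub[[nm]]
    w
  }
  rpc_in <- if (config$include_center_in_rpc) 6L else 3L
  mix_in <- config$c_pos * (1L + as.integer(config$use_rpc)) + config$c_high
  w <- list()
  w <- add(w, mlp_init(c(18L, 32L, config$c_high), seed), "hd")
  w <- add(w, mlp_init(c(3L, 32L, 16L), seed + 4L), "hdrel")
  w <- add(w, mlp_init(c(config$c_high, 16L), seed + 6L), "hdpool")
  w <- add(w, mlp_init(c(config$c_high + 32L, config$c_high),
                       seed + 5L), "hdmix")
  for (s in 1:3) {
    if (config$use_rpc)
      w <- add(w, mlp_init(c(rpc_in, 32L, config$c_pos), seed + 10L * s),
               paste0("msg.s", s, ".rpc"))
    w <- add(w, mlp_init(c(3L, 32L, config$c_pos), seed + 10L * s + 1L),
             paste0("msg.s", s, ".apc"))
    w <- add(w, mlp_init(c(mix_in, config$c_scale), seed + 10L * s + 2L),
             paste0("msg.s", s, ".mix"))
  }
  w <- add(w, mlp_init(c(3L * config$c_scale, config$d_m), seed + 41L),
           "gproj")
  w <- add(w, attention_init(config, seed + 50L), "att.self")
  w <- add(w, attention_init(config, seed + 51L), "att.lg")
  w <- add(w, attention_init(config, seed + 52L), "att.cross")
  w <- add(w, mlp_init(c(config$c_high, config$score_hidden, 1L),
                       seed + 60L), "sort.score")
  if (config$use_rpc)
    w <- add(w, mlp_init(c(rpc_in, 32L, config$c_pos), seed + 61L),
             "sort.rpc")
  w <- add(w, mlp_init(c(3L, 32L, config$c_pos), seed + 62L), "sort.apc")
  w <- add(w, mlp_init(c(mix_in, config$c_scale), seed + 63L), "sort.mix")
  w <- add(w, mlp_init(c(config$c_high + config$c_scale, config$d_m),
                       seed + 64L), "lproj")
  w <- add(w, mlp_init(c(config$d_m, config$d_m), seed + 70L), "head.mlp")
  w <- add(w, mlp_init(c(config$d_m + config$c_high + 18L,
                         config$cls_hidden, 3L),
                       seed + 71L), "cls")
  w
}

## ---- attention (AD core + numeric surfaces) --------------------------------

# Multi-head attention on the tape.  Returns the fused output node, the
# per-head feature nodes (for the separation loss) and the per-head
# attention weight matrices (values, for diagnostics).
ad_mha <- function(tp, X, Y, weights, prefix, cfg,
                   use_residual = TRUE, use_layernorm = TRUE,
                   use_ffn = TRUE) {
  nm <- function(s) if (nzchar(prefix)) paste0(prefix, ".", s) else s
  P <- function(s) ad_param(tp, weights[[nm(s)]], nm(s))
  heads <- vector("list", cfg$h)
  attn <- vector("list", cfg$h)
  for (i in seq_len(cfg$h)) {
    Q <- ad_matmul(tp, X, P(paste0("WQ", i)))
    K <- ad_matmul(tp, Y, P(paste0("WK", i)))
    V <- ad_matmul(tp, Y, P(paste0("WV", i)))
    Kt <- ad_node(tp, t(K$value), list(K), function(g) list(t(g)))
    S <- ad_scale(tp, ad_matmul(tp, Q, Kt), 1 / sqrt(cfg$d_k))
    A <- ad_row_softmax(tp, S)
    attn[[i]] <- A$value
    heads[[i]] <- ad_matmul(tp, A, V)
  }
  mh <- ad_matmul(tp, ad_cbind(tp, heads), P("WO"))
  s1 <- if (use_residual) ad_add(tp, X, mh) else mh
  if (use_layernorm)
    s1 <- ad_layernorm(tp, s1, P("ln1.g"), P("ln1.b"))
  out <- s1
  if (use_ffn) {
    phi <- ad_mlp(tp, s1, weights, nm("ffn"))
    out <- if (use_residual) ad_add(tp, s1, phi) else phi
  }
  if (use_layernorm)
    out <- ad_layernorm(tp, out, P("ln2.g"), P("ln2.b"))
  list(out = out, heads = heads, attn = attn)
}

#' Multi-head attention between two token sets
#'
#' Computes `LayerNorm(S + FFN(S))` with `S = LayerNorm(X + Multihead(X, Y,
#' Y))`; the per-head output features are returned alongside the fused
#' result because the separation loss consumes them.  The `use_*` switches
#' reduce the module to plain scaled-dot-product attention for testing.
#'
#' @param X queries, `T_x x d_m`.
#' @param Y keys/values, `T_y x d_m`.
#' @param weights module weights from [attention_init()].
#' @param config a [plantseg_config()].
#' @param use_residual,use_layernorm,use_ffn structural switches (all
#'   `TRUE` in the full network).
#' @return list: `features` (`T_x x d_m`), `heads` (list of `h` matrices
#'   `T_x x d_v`), `attn` (list of `h` attention-weight matrices).
#' @export
multi_head_attention <- function(X, Y, weights, config,
                                 use_residual = TRUE, use_layernorm = TRUE,
                                 use_ffn = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != config$d_m || ncol(Y) != config$d_m)
    stop("token width must equal config$d_m = ", config$d_m)
  tp <- ad_tape()
  r <- ad_mha(tp, ad_const(tp, X), ad_const(tp, Y), weights, "", config,
              use_residual, use_layernorm, use_ffn)
  list(features = r$out$value,
       heads = lapply(r$heads, function(h) h$value),
       attn = r$attn)
}

#' Self attention over one token set
#'
#' Delegates to [multi_head_attention()] with `X = Y = P`.
#' @inheritParams multi_head_attention
#' @param P token set, `T x d_m`.
#' @return as [multi_head_attention()].
#' @export
attention_self <- function(P, weights, config, ...) {
  multi_head_attention(P, P, weights, config, ...)
}

#' Cross attention between two token sets
#'
#' Delegates to [multi_head_attention()] with `X = P`, `Y = Q`; used both
#' as the local/global attention of the global branch and as the fusion
#' attention of the detection head.
#' @inheritParams multi_head_attention
#' @param P query token set; `Q` key/value token set.
#' @param Q key/value token set.
#' @return as [multi_head_attention()].
#' @export
attention_cross <- function(P, Q, weights, config, ...) {
  multi_head_attention(P, Q, weights, config, ...)
}

## ---- branches --------------------------------------------------------------

# Position-code + pooled-feature block shared by both branches: given a
# neighbourhood index, produce per-centre [rpc | apc | pooled-high-D]
# features and mix them down to c_scale.
ad_pc_block <- function(tp, co, hd_node, nbr, weights, cfg, prefix) {
  K <- ncol(nbr$neighbor_idx)
  parts <- list()
  if (cfg$use_rpc) {
    rel <- relative_codes_flat(co, nbr, cfg$include_center_in_rpc)
    rf <- ad_mlp(tp, ad_const(tp, rel), weights, paste0(prefix, ".rpc"))
    parts$rpc <- ad_group_maxpool(tp, rf, K)
  }
  parts$apc <- ad_mlp(tp, ad_const(tp, co[nbr$centers, , drop = FALSE]),
                      weights, paste0(prefix, ".apc"))
  gf <- ad_gather_rows(tp, hd_node, nbr_flat_index(nbr))
  parts$hd <- ad_group_maxpool(tp, gf, K)
  ad_mlp(tp, ad_cbind(tp, parts), weights, paste0(prefix, ".mix"),
         final_relu = TRUE)
}

# Geometry that depends only on the block coordinates: computed once per
# block and reused across training epochs.
static_geometry <- function(co, cfg) {
  m <- min(cfg$m_centers, nrow(co))
  fps <- farthest_point_sample(co, m, cfg$start_index)
  kn <- knn_index(co, cfg$k_feat)
  # shape descriptors at three scales: point-local, organ-surface and
  # organ-body; the finest scale stays organ-pure even where organs touch
  kn0 <- knn_index(co, 8L)
  kn2 <- knn_index(co, 3L * cfg$k_feat)
  list(kn = kn, kn_fine = kn0,
       eigf = cbind(eigen_features(co, kn0), eigen_features(co, kn),
                    eigen_features(co, kn2)),
       fps = fps,
       msg_nbr = lapply(1:3, function(s)
         ball_query(co, fps, cfg$radii[s], cfg$k_max)))
}

# Global branch: FPS -> three-radius ball query -> position-coded
# multi-scale features -> global tokens.
ad_msg <- function(tp, co, hd_node, weights, cfg, geom) {
  scales <- lapply(1:3, function(s)
    ad_pc_block(tp, co, hd_node, geom$msg_nbr[[s]], weights, cfg,
                paste0("msg.s", s)))
  tokens <- ad_mlp(tp, ad_cbind(tp, scales), weights, "gproj")
  list(centers = geom$fps, tokens = tokens)
}

# Local branch: learnable importance score -> top-k selection ->
# position-coded neighbourhood features -> local tokens.
ad_sortnet <- function(tp, co, hd_node, weights, cfg) {
  k <- cfg$k_select
  if (k > nrow(co)) stop("k_select exceeds the block point count")
  score <- ad_mlp(tp, hd_node, weights, "sort.score")
  sv <- as.vector(score$value)
  topk <- order(-sv, seq_along(sv))[seq_len(k)]   # ties: lowest index
  nbr <- ball_query(co, topk, cfg$r_local, cfg$k_max_local)
  pcf <- ad_pc_block(tp, co, hd_node, nbr, weights, cfg, "sort")
  gate <- ad_sigmoid(tp, ad_gather_rows(tp, score, topk))
  sel <- ad_mul_colvec(tp, ad_gather_rows(tp, hd_node, topk), gate)
  tokens <- ad_mlp(tp, ad_cbind(tp, list(sel, pcf)), weights, "lproj")
  list(selected = topk, tokens = tokens, score = sv)
}

#' Global branch forward pass (multi-scale grouping)
#'
#' Farthest point sampling, ball query at three radii, position-coded
#' per-scale features concatenated into per-centre global tokens.
#'
#' @param cloud a centred [point_cloud] or N x 3 matrix.
#' @param high_d N x c_high matrix of per-point features (from the shared
#'   extractor; see [model_forward()]).
#' @param weights full network weights from [init_weights()].
#' @param config a [plantseg_config()].
#' @return list: `centers` (FPS indices), `tokens` (m x d_m matrix).
#' @export
pc_msg_forward <- function(cloud, high_d, weights, config) {
  co <- as_coords(cloud)
  tp <- ad_tape()
  r <- ad_msg(tp, co, ad_const(tp, as.matrix(high_d)), weights, config,
              static_geometry(co, config))
  list(centers = r$centers, tokens = r$tokens$value)
}

#' Local branch forward pass (learnable top-k selection)
#'
#' A pointwise score map reduces every point's feature to one importance
#' scalar; the `k_select` highest-scoring points (ties broken by lowest
#' index) anchor ball-query neighbourhoods whose position-coded features,
#' concatenated with the gated point features, become the local tokens.
#'
#' @inheritParams pc_msg_forward
#' @param features N x c_high per-point feature matrix.
#' @return list: `selected` (top-k indices), `tokens` (k x d_m), `scores`
#'   (length-N raw scores).
#' @export
pc_sortnet_forward <- function(cloud, features, weights, config) {
  co <- as_coords(cloud)
  tp <- ad_tape()
  r <- ad_sortnet(tp, co, ad_const(tp, as.matrix(features)), weights,
                  config)
  list(selected = r$selected, tokens = r$tokens$value, scores = r$score)
}

#' Detection head: fuse local and global tokens
#'
#' Cross attention with the local tokens as queries and the global tokens
#' as keys/values, followed by a pointwise feed-forward stack.
#'
#' @param local_tokens k x d_m matrix.
#' @param global_tokens m x d_m matrix.
#' @param weights full network weights.
#' @param config a [plantseg_config()].
#' @return list: `features` (k x d_m fused tokens), `heads` (per-head
#'   feature matrices of the fusion attention).
#' @export
detection_head <- function(local_tokens, global_tokens, weights, config) {
  tp <- ad_tape()
  r <- ad_mha(tp, ad_const(tp, as.matrix(local_tokens)),
              ad_const(tp, as.matrix(global_tokens)),
              weights, "att.cross", config)
  out <- ad_mlp(tp, r$out, weights, "head.mlp")
  list(features = out$value, heads = lapply(r$heads, function(h) h$value))
}

## ---- full forward ----------------------------------------------------------

# Full forward pass on a tape.  `co` must be centred block coordinates;
# `geom` is the cached static_geometry() of the block (computed if NULL).
ad_model_forward <- function(tp, co, weights, cfg, geom = NULL) {
  if (is.null(geom)) geom <- static_geometry(co, cfg)
  # per-point input: coordinates plus local covariance shape descriptors
  hd0 <- ad_mlp(tp, ad_const(tp, cbind(co, geom$eigf)), weights, "hd",
                final_relu = TRUE)
  # local aggregation: each point pools its k nearest neighbours, giving a
  # geometric signature (tube / plane / cluster) beyond its own
  # coordinates; a narrow projection keeps the gathered matrix small
  kn <- geom$kn
  kf <- ncol(kn)
  hp <- ad_mlp(tp, hd0, weights, "hdpool", final_relu = TRUE)
  pooled <- ad_group_maxpool(tp, ad_gather_rows(tp, hp, as.vector(t(kn))),
                             kf)
  rel <- co[rep(seq_len(nrow(co)), each = kf), , drop = FALSE] -
    co[as.vector(t(kn)), , drop = FALSE]
  relf <- ad_group_maxpool(tp, ad_mlp(tp, ad_const(tp, rel), weights,
                                      "hdrel", final_relu = TRUE), kf)
  hd <- ad_mlp(tp, ad_cbind(tp, list(hd0, pooled, relf)), weights, "hdmix",
               final_relu = TRUE)
  g <- ad_msg(tp, co, hd, weights, cfg, geom)
  l <- ad_sortnet(tp, co, hd, weights, cfg)
  a_self <- ad_mha(tp, g$tokens, g$tokens, weights, "att.self", cfg)
  a_lg <- ad_mha(tp, a_self$out, l$tokens, weights, "att.lg", cfg)
  a_cross <- ad_mha(tp, l$tokens, a_lg$out, weights, "att.cross", cfg)
  fused <- ad_mlp(tp, a_cross$out, weights, "head.mlp")
  anchors <- co[l$selected, , drop = FALSE]
  kup <- if (cfg$upsample == "idw3") 3L else 1L
  na <- nearest_anchors(co, anchors, kup)
  up <- ad_weighted_gather(tp, fused, na$idx, na$w)
  # raw coordinates and shape descriptors join the fused and pointwise
  # features as skip inputs to the classifier
  logits0 <- ad_mlp(tp, ad_cbind(tp, list(up, hd,
                                          ad_const(tp,
                                                   cbind(co, geom$eigf)))),
                    weights, "cls")
  # neighbourhood consistency: blend each point's scores with the mean of
  # its finest-scale neighbours (organ labels are locally coherent)
  kf0 <- ncol(geom$kn_fine)
  sm <- ad_group_meanpool(tp,
                          ad_gather_rows(tp, logits0,
                                         as.vector(t(geom$kn_fine))),
                          kf0, rep(TRUE, nrow(co) * kf0))
  logits <- ad_add(tp, ad_scale(tp, logits0, 0.5), ad_scale(tp, sm, 0.5))
  list(logits = logits,
       heads = list(self = a_self$heads, lg = a_lg$heads,
                    cross = a_cross$heads),
       centers = g$centers, selected = l$selected)
}

#' Full network forward pass on one block
#'
#' Runs both branches and the detection head, then maps token-level
#' features back to every input point (inverse-distance interpolation over
#' the 3 nearest selected anchors by default) and classifies each point.
#'
#' @param block a [point_cloud] (centred; see [center_block()]) with
#'   `config$n_points` points in the training pipeline — any size is
#'   accepted here.
#' @param weights network weights from [init_weights()].
#' @param config a [plantseg_config()].
#' @param geom optional cached `static_geometry()` of the block (the
#'   trainer reuses it across epochs); computed when `NULL`.
#' @return list: `logits` (N x 3 class scores), `heads_list` (per-module
#'   per-head feature matrices, for the separation loss), `centers` (FPS
#'   indices), `selected` (top-k indices).
#' @export
model_forward <- function(block, weights, config, geom = NULL) {
  co <- as_coords(block)
  tp <- ad_tape()
  r <- ad_model_forward(tp, co, weights, config, geom)
  list(logits = r$logits$value,
       heads_list = lapply(r$heads, function(hs)
         lapply(hs, function(h) h$value)),
       centers = r$centers, selected = r$selected)
}

# Forward + combined loss + gradients for one block (training step core).
model_grad_step <- function(co, labels, weights, cfg, geom = NULL) {
  tp <- ad_tape()
  r <- ad_model_forward(tp, co, weights, cfg, geom)
  labels <- as.integer(labels)
  w <- NULL
  if (identical(cfg$class_weights, "balanced")) {
    # inverse-frequency weights: the evaluation metric averages classes
    cnt <- tabulate(labels + 1L, 3L)
    wc <- ifelse(cnt > 0, 1 / cnt, 0)
    w <- wc[labels + 1L]
  }
  ce <- ad_softmax_ce(tp, r$logits, labels + 1L, w)
  total <- ce
  sep_val <- mean(vapply(r$heads, function(hs)
    separation_loss(lapply(hs, function(h) h$value)), numeric(1)))
  if (cfg$loss_scal > 0) {
    seps <- lapply(r$heads, function(hs) ad_separation(tp, hs))
    sep <- seps[[1L]]
    for (j in seq_along(seps)[-1L]) sep <- ad_add(tp, sep, seps[[j]])
    sep <- ad_scale(tp, sep, 1 / length(seps))
    # the separation term enters the descent direction as a similarity
    # penalty: minimising ce + loss_scal * (-sep) pushes heads apart
    total <- ad_add(tp, ce, ad_scale(tp, sep, -cfg$loss_scal))
  }
  grads <- ad_backward(tp, total)
  list(grads = ad_param_grads(tp, grads),
       ce = as.numeric(ce$value), sep = sep_val,
       total = as.numeric(total$value),
       heads_list = lapply(r$heads, function(hs)
         lapply(hs, function(h) h$value)),
       logits = r$logits$value)
}
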