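# Position coding: per-neighbourhood relative position codes (RPC) and
# absolute position codes (APC), each passed through a small learnable
# pointwise map and concatenated.  The RPC branch is exactly translation
# invariant; the APC branch deliberately is not.

#' Initialise a pointwise multi-layer perceptron
#'
#' Weights drawn from a scaled normal (Glorot-style), biases zero;
#' deterministic for a fixed seed.
#'
#' @param dims integer vector of layer widths, e.g. `c(3, 32, 16)`.
#' @param seed RNG seed.
#' @return named list of weight (`W1`, `W2`, ...) and bias (`b1`, ...)
#'   matrices.
#' @export
mlp_init <- function(dims, seed = 1L) {
  with_local_seed(seed, {
    out <- list()
    for (l in seq_len(length(dims) - 1L)) {
      sd <- sqrt(2 / (dims[l] + dims[l + 1L]))
      out[[paste0("W", l)]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                                   sd = sd),
                                      dims[l], dims[l + 1L])
      out[[paste0("b", l)]] <- matrix(0, 1L, dims[l + 1L])
    }
    out
  })
}

# Numeric forward through an mlp_init() parameter list; ReLU between layers,
# linear output unless `final_relu`.
mlp_apply <- function(theta, x, final_relu = FALSE) {
  x <- as.matrix(x)
  nl <- length(theta) / 2L
  for (l in seq_len(nl)) {
    x <- sweep(x %*% theta[[paste0("W", l)]], 2L,
               as.vector(theta[[paste0("b", l)]]), "+")
    if (l < nl || final_relu) x <- pmax(x, 0)
  }
  x
}

# AD forward through MLP weights registered under `prefix` on tape `tp`.
ad_mlp <- function(tp, x, weights, prefix, final_relu = FALSE) {
  nl <- sum(grepl(paste0("^", prefix, "\\.W"), names(weights)))
  for (l in seq_len(nl)) {
    W <- ad_param(tp, weights[[paste0(prefix, ".W", l)]],
                  paste0(prefix, ".W", l))
    b <- ad_param(tp, weights[[paste0(prefix, ".b", l)]],
                  paste0(prefix, ".b", l))
    x <- ad_add_bias(tp, ad_matmul(tp, x, W), b)
    if (l < nl || final_relu) x <- ad_relu(tp, x)
  }
  x
}

#' Relative position codes of neighbourhoods
#'
#' `out[m, k, ] = coords[center_m] - coords[neighbor_mk]`: the offset of
#' every neighbour from its centre.  Padded (invalid) slots are zero
#' vectors, as is the centre's own slot.  Translation of the whole cloud
#' leaves the output unchanged.
#'
#' @param cloud a [point_cloud] or N x 3 matrix.
#' @param nbr a `neighborhood_index` from [ball_query()].
#' @return M x K x 3 array of offsets.
#' @export
relative_codes <- function(cloud, nbr) {
  co <- as_coords(cloud)
  idx <- nbr$neighbor_idx
  M <- nrow(idx); K <- ncol(idx)
  cen <- co[nbr$centers, , drop = FALSE]
  rel <- cen[rep(seq_len(M), each = K), , drop = FALSE] -
    co[as.vector(t(idx)), , drop = FALSE]
  rel[!as.vector(t(nbr$valid)), ] <- 0
  arr <- array(0, c(M, K, 3L))
  for (c in 1:3) arr[, , c] <- matrix(rel[, c], M, K, byrow = TRUE)
  arr
}

# Flattened (M*K) x 3 relative-code matrix in the k-fastest layout used by
# the AD grouped pooling ops.
relative_codes_flat <- function(co, nbr, include_center = FALSE) {
  idx <- nbr$neighbor_idx
  M <- nrow(idx); K <- ncol(idx)
  cen_rep <- co[nbr$centers, , drop = FALSE][rep(seq_len(M), each = K), ,
                                             drop = FALSE]
  rel <- cen_rep - co[as.vector(t(idx)), , drop = FALSE]
  rel[!as.vector(t(nbr$valid)), ] <- 0
  if (include_center) cbind(cen_rep, rel) else rel
}

#' Position code of a set of neighbourhoods
#'
#' The per-centre position code is the concatenation of two blocks:
#' \itemize{
#'   \item RPC: the learnable map `theta_rpc` applied pointwise to every
#'     neighbour offset, max-pooled over the neighbourhood (a symmetric
#'     function, so the code is invariant to neighbour ordering);
#'   \item APC: `theta_apc` applied to the centre's own coordinates.
#' }
#'
#' @param cloud a [point_cloud] or N x 3 matrix (block-local, centred
#'   coordinates in the pipeline).
#' @param nbr a `neighborhood_index`.
#' @param theta_rpc,theta_apc parameter lists from [mlp_init()]; input width
#'   3 (6 for `theta_rpc` when `include_center_in_rpc`).
#' @param include_center_in_rpc also feed the centre's absolute coordinates
#'   into the RPC branch (default `FALSE`).
#' @return object of class `position_code`: `rpc_features` (M x C_r),
#'   `apc_features` (M x C_a), `combined` (M x (C_r + C_a)).
#' @export
encode_positions <- function(cloud, nbr, theta_rpc, theta_apc,
                             include_center_in_rpc = FALSE) {
  if (is.null(theta_rpc) || is.null(theta_apc))
    stop("theta maps must be initialised (see mlp_init)")
  co <- as_coords(cloud)
  idx <- nbr$neighbor_idx
  M <- nrow(idx); K <- ncol(idx)
  rel <- relative_codes_flat(co, nbr, include_center_in_rpc)
  ft <- mlp_apply(theta_rpc, rel)                       # (M*K) x C_r
  rpc <- apply_group_max(ft, K)
  apc <- mlp_apply(theta_apc, co[nbr$centers, , drop = FALSE])
  structure(list(rpc_features = rpc, apc_features = apc,
                 combined = cbind(rpc, apc)),
            class = "position_code")
}

# Max over groups of K consecutive rows (k fastest within each group).
apply_group_max <- function(x, K) {
  M <- nrow(x) %/% K
  out <- matrix(0, M, ncol(x))
  for (j in seq_len(ncol(x)))
    out[, j] <- apply(matrix(x[, j], K, M), 2L, max)
  out
}
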