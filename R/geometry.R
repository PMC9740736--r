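# Deterministic geometric primitives shared by all network blocks.
# Brute-force distance computation: exactness and reproducibility matter
# more than asymptotics at the block sizes the network consumes.

as_coords <- function(cloud) {
  if (inherits(cloud, "point_cloud")) cloud$coords else as.matrix(cloud)
}

#' Farthest point sampling
#'
#' Greedy max-min subsampling: the first pick is `start_index`; every
#' subsequent pick maximises the minimum Euclidean distance to the points
#' already selected, ties broken by lowest index.  Fully deterministic.
#'
#' @param cloud a [point_cloud] or N x 3 matrix.
#' @param m number of samples, `1 <= m <= N`.
#' @param start_index index of the first selected point (default 1).
#' @return integer vector of `m` point indices in selection order.
#' @export
farthest_point_sample <- function(cloud, m, start_index = 1L) {
  co <- as_coords(cloud)
  n <- nrow(co)
  if (m < 1L || m > n) stop("m must be in [1, N]; got m=", m, ", N=", n)
  if (start_index < 1L || start_index > n) stop("start_index out of range")
  sel <- integer(m)
  sel[1L] <- as.integer(start_index)
  mind <- rowSums(sweep(co, 2L, co[start_index, ], "-")^2)
  if (m > 1L) for (i in 2:m) {
    nxt <- which.max(mind)          # first max = lowest index on ties
    sel[i] <- nxt
    d <- rowSums(sweep(co, 2L, co[nxt, ], "-")^2)
    mind <- pmin(mind, d)
  }
  sel
}

#' Ball query around centre points
#'
#' For every centre, collects up to `k_max` points within a closed ball of
#' radius `radius`, nearest first, ties by lowest index.  The centre itself
#' is always part of its own neighbourhood.  Neighbourhoods smaller than
#' `k_max` are padded by repeating the centre index with `valid = FALSE`, so
#' symmetric pooling downstream is unaffected by padding.
#'
#' @param cloud a [point_cloud] or N x 3 matrix.
#' @param centers integer vector of centre point indices (length M).
#' @param radius ball radius (> 0).
#' @param k_max maximum neighbourhood size (>= 1).
#' @return a `neighborhood_index`: `centers`, `neighbor_idx` (M x K matrix of
#'   point indices), `valid` (M x K logical mask).
#' @export
ball_query <- function(cloud, centers, radius, k_max) {
  co <- as_coords(cloud)
  if (radius <= 0) stop("radius must be > 0")
  if (k_max < 1L) stop("k_max must be >= 1")
  centers <- as.integer(centers)
  M <- length(centers)
  nbr <- matrix(rep(centers, k_max), M, k_max)
  valid <- matrix(FALSE, M, k_max)
  if (M > 0L) {
    r2 <- radius^2
    D2 <- cross_dist2(co[centers, , drop = FALSE], co)
    for (i in seq_len(M)) {
      d2 <- D2[i, ]
      inside <- which(d2 <= r2)
      inside <- inside[order(d2[inside], inside)]
      if (!centers[i] %in% inside[seq_len(min(k_max, length(inside)))]) {
        inside <- c(centers[i], setdiff(inside, centers[i]))
      }
      k <- min(k_max, length(inside))
      nbr[i, seq_len(k)] <- inside[seq_len(k)]
      valid[i, seq_len(k)] <- TRUE
    }
  }
  structure(list(centers = centers, neighbor_idx = nbr, valid = valid),
            class = "neighborhood_index")
}

#' Gather per-point features into neighbourhoods
#'
#' `out[m, k, ] = features[neighbor_idx[m, k], ]`; padded slots carry the
#' centre's feature row (their index is the centre index).
#'
#' @param features N x C feature matrix.
#' @param nbr a `neighborhood_index` from [ball_query()].
#' @return M x K x C array.
#' @export
group_features <- function(features, nbr) {
  features <- as.matrix(features)
  idx <- nbr$neighbor_idx
  if (max(idx) > nrow(features)) stop("neighborhood index out of range")
  M <- nrow(idx); K <- ncol(idx); C <- ncol(features)
  flat <- features[as.vector(t(idx)), , drop = FALSE]  # (M*K) x C, k fastest
  arr <- array(0, c(M, K, C))
  for (c in seq_len(C)) arr[, , c] <- matrix(flat[, c], M, K, byrow = TRUE)
  arr
}

# Row indices of the flattened (M*K) neighbourhood, k fastest within m —
# the layout ad_group_maxpool() expects.
nbr_flat_index <- function(nbr) as.vector(t(nbr$neighbor_idx))

# Classical local-covariance shape descriptors over a kNN index:
# linearity, planarity, sphericity, verticality of the dominant axis and
# log neighbourhood radius.  Deterministic functions of the coordinates.
eigen_features <- function(co, kn) {
  n <- nrow(co); k <- ncol(kn)
  flat <- co[as.vector(t(kn)), , drop = FALSE]
  grp <- rep(seq_len(n), each = k)
  mu <- rowsum(flat, grp) / k
  cent <- flat - mu[grp, , drop = FALSE]
  # second moments per point
  cxx <- rowsum(cent[, 1] * cent[, 1], grp) / k
  cyy <- rowsum(cent[, 2] * cent[, 2], grp) / k
  czz <- rowsum(cent[, 3] * cent[, 3], grp) / k
  cxy <- rowsum(cent[, 1] * cent[, 2], grp) / k
  cxz <- rowsum(cent[, 1] * cent[, 3], grp) / k
  cyz <- rowsum(cent[, 2] * cent[, 3], grp) / k
  out <- matrix(0, n, 5L)
  for (i in seq_len(n)) {
    C <- matrix(c(cxx[i], cxy[i], cxz[i],
                  cxy[i], cyy[i], cyz[i],
                  cxz[i], cyz[i], czz[i]), 3L, 3L)
    e <- eigen(C, symmetric = TRUE)
    l <- pmax(e$values, 0)
    s <- l[1] + 1e-12
    out[i, ] <- c((l[1] - l[2]) / s,          # linearity
                  (l[2] - l[3]) / s,          # planarity
                  l[3] / s,                   # sphericity
                  abs(e$vectors[3, 1]),       # verticality of main axis
                  log1p(sqrt(sum(l))))        # neighbourhood extent
  }
  out
}

# Squared-distance matrix between the rows of a and b (n x m).
cross_dist2 <- function(a, b) {
  d2 <- matrix(rowSums(a^2), nrow(a), nrow(b)) +
    matrix(rowSums(b^2), nrow(a), nrow(b), byrow = TRUE) -
    2 * a %*% t(b)
  pmax(d2, 0)
}

# k smallest entries per row of D (ascending, ties by lowest column),
# via repeated max.col (C speed).
row_mink <- function(D, k) {
  idx <- matrix(0L, nrow(D), k)
  for (j in seq_len(k)) {
    i <- max.col(-D, ties.method = "first")
    idx[, j] <- i
    D[cbind(seq_len(nrow(D)), i)] <- Inf
  }
  idx
}

# k-nearest-neighbour index (self included, distance then index order);
# n x k matrix of row indices into co.
knn_index <- function(co, k) {
  k <- min(k, nrow(co))
  row_mink(cross_dist2(co, co), k)
}

# For each query point, the `k` nearest rows of `anchors` plus
# inverse-distance weights (rows sum to 1).
nearest_anchors <- function(coords, anchors, k = 3L) {
  k <- min(k, nrow(anchors))
  D2 <- cross_dist2(coords, anchors)
  idx <- row_mink(D2, k)
  d <- sqrt(D2[cbind(rep(seq_len(nrow(coords)), k), as.vector(idx))])
  w <- 1 / (matrix(d, ncol = k) + 1e-8)
  list(idx = idx, w = w / rowSums(w))
}
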