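# Minimal tape-based reverse-mode automatic differentiation over matrices.
# Every network forward pass builds a fresh tape; ad_backward() walks it in
# reverse, accumulating gradients.  Only the ops the segmentation network
# needs are provided; each has a finite-difference test.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp$params <- list()   # name -> node id
  tp
}

ad_node <- function(tp, value, parents = list(), bw = NULL) {
  # force args before reserving an id: nested calls create their nodes first
  force(value); force(parents); force(bw)
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) {
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  }
  nd <- list(
    id = tp$n,
    value = value,
    parents = vapply(parents, function(p) p$id, integer(1)),
    bw = bw
  )
  tp$nodes[[tp$n]] <- nd
  nd
}

ad_const <- function(tp, x) ad_node(tp, as.matrix(x))

ad_param <- function(tp, x, name) {
  nd <- ad_node(tp, x)
  tp$params[[name]] <- nd$id
  nd
}

# Backward pass from a scalar node; returns per-node gradient list.
ad_backward <- function(tp, root) {
  grads <- vector("list", tp$n)
  grads[[root$id]] <- matrix(1, 1, 1)
  for (i in seq(tp$n, 1L)) {
    nd <- tp$nodes[[i]]
    g <- grads[[i]]
    if (is.null(g) || is.null(nd$bw) || length(nd$parents) == 0L) next
    pg <- nd$bw(g)
    for (j in seq_along(nd$parents)) {
      gj <- pg[[j]]
      if (is.null(gj)) next
      pid <- nd$parents[j]
      grads[[pid]] <- if (is.null(grads[[pid]])) gj else grads[[pid]] + gj
    }
    grads[i] <- list(NULL)  # free as we go (keep list length)
  }
  grads
}

# Collect parameter gradients by name after ad_backward().
ad_param_grads <- function(tp, grads) {
  out <- list()
  for (nm in names(tp$params)) {
    id <- tp$params[[nm]]
    g <- grads[[id]]
    if (is.null(g)) g <- array(0, dim(tp$nodes[[id]]$value))
    out[[nm]] <- g
  }
  out
}

## ---- primitive ops ---------------------------------------------------------

ad_matmul <- function(tp, a, b) {
  av <- a$value; bv <- b$value
  ad_node(tp, av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), t(av) %*% g)
  })
}

ad_add <- function(tp, a, b) {
  ad_node(tp, a$value + b$value, list(a, b), function(g) list(g, g))
}

# Add a 1xC bias row to every row of a.
ad_add_bias <- function(tp, a, b) {
  bv <- as.vector(b$value)
  ad_node(tp, a$value + rep(bv, each = nrow(a$value)), list(a, b),
          function(g) {
    list(g, matrix(colSums(g), 1L))
  })
}

ad_scale <- function(tp, a, s) {
  ad_node(tp, a$value * s, list(a), function(g) list(g * s))
}

ad_relu <- function(tp, a) {
  v <- a$value
  mask <- v > 0
  ad_node(tp, v * mask, list(a), function(g) list(g * mask))
}

ad_tanh <- function(tp, a) {
  v <- tanh(a$value)
  ad_node(tp, v, list(a), function(g) list(g * (1 - v^2)))
}

ad_sigmoid <- function(tp, a) {
  v <- 1 / (1 + exp(-a$value))
  ad_node(tp, v, list(a), function(g) list(g * v * (1 - v)))
}

# Row-wise softmax.
ad_row_softmax <- function(tp, a) {
  v <- row_softmax(a$value)
  ad_node(tp, v, list(a), function(g) {
    list((g - rowSums(g * v)) * v)
  })
}

# Row-wise layer normalisation with learnable 1xC gain/offset.
ad_layernorm <- function(tp, x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  C <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  gv <- as.vector(gamma$value)
  v <- sweep(xhat, 2L, gv, "*")
  v <- sweep(v, 2L, as.vector(beta$value), "+")
  ad_node(tp, v, list(x, gamma, beta), function(g) {
    dxhat <- sweep(g, 2L, gv, "*")
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
    list(dx,
         matrix(colSums(g * xhat), 1L),
         matrix(colSums(g), 1L))
  })
}

# Column-wise concatenation of a list of nodes.
ad_cbind <- function(tp, nodes) {
  vals <- lapply(nodes, function(n) n$value)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  ad_node(tp, do.call(cbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

# out[i, ] = x[idx[i], ]
ad_gather_rows <- function(tp, x, idx) {
  idx <- as.integer(idx)
  n <- nrow(x$value)
  ad_node(tp, x$value[idx, , drop = FALSE], list(x), function(g) {
    gx <- matrix(0, n, ncol(g))
    gg <- rowsum(g, idx)
    gx[as.integer(rownames(gg)), ] <- gg
    list(gx)
  })
}

# Max-pool over groups of K consecutive rows: (M*K)xC -> MxC.
ad_group_maxpool <- function(tp, x, K) {
  xv <- x$value
  MK <- nrow(xv); C <- ncol(xv)
  M <- MK %/% K
  stopifnot(M * K == MK)
  mx <- xv[seq.int(1L, MK, K), , drop = FALSE]
  amx <- matrix(1L, M, C)
  if (K > 1L) {
    for (k in 2:K) {
      slab <- xv[seq.int(k, MK, K), , drop = FALSE]
      upd <- slab > mx
      mx[upd] <- slab[upd]
      amx[upd] <- k
    }
  }
  ad_node(tp, mx, list(x), function(g) {
    gx <- matrix(0, MK, C)
    rows <- (rep(seq_len(M), times = C) - 1L) * K + as.vector(amx)
    cols <- rep(seq_len(C), each = M)
    # duplicated (row,col) pairs cannot occur: one argmax per (m, c)
    gx[cbind(rows, cols)] <- as.vector(g)
    list(gx)
  })
}

# Mean-pool over groups of K consecutive rows, with a validity mask:
# masked slots contribute nothing; each group averages over its valid count.
ad_group_meanpool <- function(tp, x, K, valid) {
  xv <- x$value
  MK <- nrow(xv); C <- ncol(xv)
  M <- MK %/% K
  w <- as.numeric(valid)
  cnt <- rowsum(w, rep(seq_len(M), each = K))[, 1L]
  cnt[cnt == 0] <- 1
  wn <- w / rep(cnt, each = K)
  v <- rowsum(xv * wn, rep(seq_len(M), each = K))
  ad_node(tp, v, list(x), function(g) {
    list(g[rep(seq_len(M), each = K), , drop = FALSE] * wn)
  })
}

# Multiply every row i of x by scalar s[i] (s is a kx1 node).
ad_mul_colvec <- function(tp, x, s) {
  sv <- as.vector(s$value)
  xv <- x$value
  ad_node(tp, xv * sv, list(x, s), function(g) {
    list(g * sv, matrix(rowSums(g * xv), ncol = 1L))
  })
}

# out[i, ] = sum_j w[i, j] * x[idx[i, j], ]   (w constant weights)
ad_weighted_gather <- function(tp, x, idx, w) {
  n <- nrow(x$value)
  P <- nrow(idx)
  v <- matrix(0, P, ncol(x$value))
  for (j in seq_len(ncol(idx))) {
    v <- v + x$value[idx[, j], , drop = FALSE] * w[, j]
  }
  ad_node(tp, v, list(x), function(g) {
    gx <- matrix(0, n, ncol(g))
    for (j in seq_len(ncol(idx))) {
      gg <- rowsum(g * w[, j], idx[, j])
      rid <- as.integer(rownames(gg))
      gx[rid, ] <- gx[rid, ] + gg
    }
    list(gx)
  })
}

# Weighted mean categorical cross-entropy of row-softmax(logits) against
# integer class labels (1-based column indices).  `w` are per-point
# weights (default uniform); returns a 1x1 node.
ad_softmax_ce <- function(tp, logits, classes, w = NULL) {
  p <- row_softmax(logits$value)
  n <- nrow(p)
  if (is.null(w)) w <- rep(1, n)
  w <- w / sum(w)
  sel <- cbind(seq_len(n), classes)
  v <- matrix(-sum(w * log(pmax(p[sel], 1e-12))), 1L, 1L)
  ad_node(tp, v, list(logits), function(g) {
    d <- p
    d[sel] <- d[sel] - 1
    list(d * (as.numeric(g) * w))
  })
}

# Separation loss over a list of head-feature nodes (see separation_loss()
# for the numeric definition).  Analytic gradient, finite-difference tested.
ad_separation <- function(tp, heads, eps = 1e-12) {
  h <- length(heads)
  fs <- lapply(heads, function(nd) as.vector(nd$value))
  nrm <- vapply(fs, function(f) sqrt(sum(f^2)), numeric(1))
  L <- 0
  gr <- lapply(fs, function(f) numeric(length(f)))
  for (i in seq_len(h - 1L)) for (j in (i + 1L):h) {
    if (nrm[i] < eps || nrm[j] < eps) next
    dt <- sum(fs[[i]] * fs[[j]])
    cij <- dt / (nrm[i] * nrm[j])
    L <- L + 2 * abs(cij)
    s <- sign(cij)
    gr[[i]] <- gr[[i]] + 2 * s * (fs[[j]] / (nrm[i] * nrm[j]) - cij * fs[[i]] / nrm[i]^2)
    gr[[j]] <- gr[[j]] + 2 * s * (fs[[i]] / (nrm[i] * nrm[j]) - cij * fs[[j]] / nrm[j]^2)
  }
  v <- matrix(-L / h^2, 1L, 1L)
  ad_node(tp, v, heads, function(g) {
    gs <- as.numeric(g) * (-1 / h^2)
    lapply(seq_len(h), function(i) {
      m <- matrix(gr[[i]], nrow(heads[[i]]$value), ncol(heads[[i]]$value))
      m * gs
    })
  })
}

row_softmax <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

## ---- parameter store + Adam ------------------------------------------------

# Parameters live in a named list of matrices between tapes.
adam_state <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) array(0, dim(p))),
       v = lapply(params, function(p) array(0, dim(p))))
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0)
      params[[nm]] <- params[[nm]] * (1 - lr * weight_decay)
  }
  list(params = params, state = state)
}
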