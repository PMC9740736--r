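# Shared fixtures: everything is built in code at test time.

random_cloud <- function(n, seed = 1L, labelled = TRUE) {
  set.seed(seed)
  point_cloud(matrix(runif(n * 3), n, 3),
              if (labelled) sample(0:2, n, replace = TRUE))
}

# A small configuration that exercises every network component quickly.
tiny_config <- function(...) {
  plantseg_config(n_points = 64L, d_m = 16L, h = 2L, d_k = 8L, d_v = 8L,
                  c_high = 8L, c_pos = 4L, c_scale = 8L,
                  m_centers = 12L, k_max = 6L, k_select = 10L,
                  k_max_local = 6L, radii = c(0.15, 0.3, 0.6),
                  r_local = 0.3, ffn_width = 16L, score_hidden = 8L,
                  k_feat = 4L, cls_hidden = 16L, ...)
}

tiny_block <- function(seed = 3L, n = 64L) {
  set.seed(seed)
  co <- matrix(rnorm(n * 3), n, 3)
  co <- co / max(sqrt(rowSums(co^2)))
  point_cloud(co, sample(0:2, n, replace = TRUE))
}

# Central finite difference of f at x (scalar-valued f, matrix x).
fd_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Independent brute-force farthest point sampling oracle.
fps_oracle <- function(co, m, start = 1L) {
  sel <- start
  while (length(sel) < m) {
    best <- -1; bi <- 0L
    for (i in seq_len(nrow(co))) {
      d <- min(vapply(sel, function(s)
        sum((co[i, ] - co[s, ])^2), numeric(1)))
      if (d > best + 1e-15) { best <- d; bi <- i }
    }
    sel <- c(sel, bi)
  }
  sel
}
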