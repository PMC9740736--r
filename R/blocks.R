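# Block splitting of whole-plant clouds into fixed-size training units, and
# per-block resampling / centring.

# Run expr with a private RNG stream; global .Random.seed is untouched.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Split a whole-plant cloud into spatially coherent blocks
#'
#' Whole plants are too large to feed to the network at once, so they are
#' partitioned into blocks whose sizes and point counts are as consistent as
#' possible while keeping local structure intact.  The procedure is a
#' voxel-grid partition at a resolution tuned so the median occupied-voxel
#' population approximates `target_points`, followed by greedy merging of
#' adjacent under-populated voxels and median-plane splitting of
#' over-populated blocks.  Fully deterministic.
#'
#' @param plant a labelled [point_cloud].
#' @param target_points desired points per block (default 2048).
#' @param min_points minimum allowed block size (default `target_points / 4`).
#' @return an object of class `block_set`: `blocks` (list of [point_cloud]),
#'   `point_index` (source indices per block), `provenance` (source plant id,
#'   all 1 here), `voxel_size` (the blocking resolution).
#' @export
split_into_blocks <- function(plant, target_points = 2048,
                              min_points = max(1L, target_points %/% 4L)) {
  stopifnot(inherits(plant, "point_cloud"))
  if (min_points > target_points)
    stop("min_points must not exceed target_points")
  n <- plant$n
  if (n < min_points) {
    warning("plant has fewer than min_points points; returning one block")
    return(new_block_set(plant, list(seq_len(n)), NA_real_))
  }
  co <- plant$coords
  s <- tune_voxel_size(co, target_points)
  key <- voxel_keys(co, s)
  groups <- split(seq_len(n), key$id)            # voxel id -> point indices
  vox <- key$vox[match(names(groups), key$id), , drop = FALSE]

  # greedy merge of under-populated voxels into adjacent blocks
  nb <- length(groups)
  owner <- seq_len(nb)                           # voxel -> block id
  counts <- lengths(groups)
  blk_counts <- counts
  repeat {
    live <- which(blk_counts > 0L)
    small <- live[blk_counts[live] < min_points]
    if (length(small) == 0L || length(live) == 1L) break
    b <- small[which.min(blk_counts[small])]
    vb <- which(owner == b)
    adj <- adjacent_blocks(vox, owner, vb)
    tgt <- if (length(adj)) adj[which.min(blk_counts[adj])]
           else nearest_block(vox, owner, vb, counts)
    owner[vb] <- tgt
    blk_counts[tgt] <- blk_counts[tgt] + blk_counts[b]
    blk_counts[b] <- 0L
  }
  idx_list <- lapply(which(blk_counts > 0L), function(b)
    sort(unlist(groups[owner == b], use.names = FALSE)))

  # median-plane split of over-populated blocks
  out <- list()
  queue <- idx_list
  while (length(queue)) {
    ix <- queue[[1L]]; queue <- queue[-1L]
    if (length(ix) > 2L * target_points) {
      sub <- co[ix, , drop = FALSE]
      ax <- which.max(apply(sub, 2L, function(v) diff(range(v))))
      ord <- order(sub[, ax], ix)
      half <- length(ix) %/% 2L
      queue <- c(queue, list(ix[ord[seq_len(half)]]),
                 list(ix[ord[(half + 1L):length(ix)]]))
    } else {
      out[[length(out) + 1L]] <- ix
    }
  }
  out <- out[order(vapply(out, min, integer(1)))]
  new_block_set(plant, out, s)
}

new_block_set <- function(plant, idx_list, voxel_size) {
  blocks <- lapply(idx_list, function(ix)
    point_cloud(plant$coords[ix, , drop = FALSE],
                if (has_labels(plant)) plant$labels[ix]))
  structure(list(blocks = blocks, point_index = idx_list,
                 provenance = rep(1L, length(blocks)),
                 voxel_size = voxel_size),
            class = "block_set")
}

#' @export
print.block_set <- function(x, ...) {
  sizes <- vapply(x$blocks, function(b) b$n, integer(1))
  cat("block_set:", length(sizes), "blocks, sizes",
      paste(range(sizes), collapse = "-"),
      sprintf("(voxel %.4g)\n", x$voxel_size))
  invisible(x)
}

# Voxel resolution tuned so the median occupied-voxel population is close
# to the target block size.
tune_voxel_size <- function(co, target) {
  ext <- apply(co, 2L, function(v) diff(range(v)))
  ext <- pmax(ext, 1e-9)
  s <- (prod(ext) * target / nrow(co))^(1 / 3)
  for (it in 1:12) {
    med <- stats::median(lengths(split(seq_len(nrow(co)),
                                       voxel_keys(co, s)$id)))
    if (med >= 0.7 * target && med <= 1.5 * target) break
    s <- s * min(max((target / med)^(1 / 3), 0.6), 1.8)
  }
  s
}

voxel_keys <- function(co, s) {
  vox <- floor(sweep(co, 2L, apply(co, 2L, min), "-") / s)
  storage.mode(vox) <- "integer"
  list(vox = vox, id = paste(vox[, 1L], vox[, 2L], vox[, 3L]))
}

# Blocks owning a voxel 26-adjacent to any voxel in `vb`.
adjacent_blocks <- function(vox, owner, vb) {
  sub <- vox[vb, , drop = FALSE]
  hits <- integer()
  for (v in seq_len(nrow(sub))) {
    d <- abs(sweep(vox, 2L, sub[v, ], "-"))
    adj <- which(apply(d, 1L, max) <= 1L)
    hits <- c(hits, owner[adj])
  }
  setdiff(unique(hits), owner[vb[1L]])
}

nearest_block <- function(vox, owner, vb, counts) {
  cen <- colMeans(vox[vb, , drop = FALSE])
  others <- which(!seq_along(owner) %in% vb)
  d <- rowSums(sweep(vox[others, , drop = FALSE], 2L, cen, "-")^2)
  owner[others[which.min(d)]]
}

#' Resample a block to a fixed point count
#'
#' The network consumes fixed-size inputs (2048 points in the reference
#' configuration).  Blocks with at least `n_points` points are uniformly
#' subsampled without replacement; smaller blocks are sampled with
#' replacement.  Labels travel with their points.  Deterministic for a fixed
#' seed.
#'
#' @param block a [point_cloud].
#' @param n_points output point count (default 2048).
#' @param seed RNG seed.
#' @return a [point_cloud] with exactly `n_points` points.
#' @export
resample_block <- function(block, n_points = 2048, seed = 1L) {
  stopifnot(inherits(block, "point_cloud"))
  if (n_points < 1L) stop("n_points must be >= 1")
  idx <- with_local_seed(seed,
    sample.int(block$n, n_points, replace = block$n < n_points))
  point_cloud(block$coords[idx, , drop = FALSE],
              if (has_labels(block)) block$labels[idx])
}

#' Centre a block and scale it to unit radius
#'
#' Subtracts the centroid and divides by the maximum point norm, so absolute
#' position codes are comparable across blocks.  The transform is recorded in
#' attributes `centroid` and `scale` so predictions map back.
#'
#' @param block a [point_cloud].
#' @return the normalised [point_cloud].
#' @export
center_block <- function(block) {
  cen <- colMeans(block$coords)
  co <- sweep(block$coords, 2L, cen, "-")
  sc <- max(sqrt(rowSums(co^2)), 1e-12)
  out <- point_cloud(co / sc, block$labels)
  attr(out, "centroid") <- cen
  attr(out, "scale") <- sc
  out
}
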