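# Procedural generator of labelled plant-like point clouds: interwoven
# tubular stems, bent elliptical leaves and petal-cluster flowers.  The
# geometry is parametric-surface sampling with ground-truth labels, not a
# botanical simulation: its job is to exercise the segmentation pipeline
# with the structural traits (thin / flat / clustered, interleaved organs)
# the task assumes.

#' Specification of a synthetic plant
#'
#' @param n_stems number of stem tubes (the first is the main axis, the
#'   rest branch off it).
#' @param stem_curvature range of lateral control-point jitter (fraction of
#'   stem length).
#' @param stem_radius tube radius, in plant-height units (plant height is
#'   about 1).
#' @param n_leaves number of leaf patches attached to stems.
#' @param leaf_size range of leaf lengths.
#' @param n_flowers number of flower clusters placed at stem tips.
#' @param flower_radius radius of a flower's petal cluster.
#' @param points_per_organ list with `stem`, `leaf`, `flower` ranges of
#'   sampled points per organ instance.
#' @param interleave_factor in `[0, 1]`: 1 keeps organs naturally attached
#'   and intertwined; 0 pulls every organ instance to its own cell of a
#'   separated grid; values between interpolate the two layouts.
#' @param noise_sd standard deviation of isotropic Gaussian coordinate
#'   noise.
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return a `plant_spec` list.
#' @export
plant_spec <- function(n_stems = 3L, stem_curvature = c(0.10, 0.35),
                       stem_radius = 0.02,
                       n_leaves = 6L, leaf_size = c(0.18, 0.30),
                       n_flowers = 3L, flower_radius = 0.08,
                       points_per_organ = list(stem = c(140L, 180L),
                                               leaf = c(100L, 140L),
                                               flower = c(80L, 120L)),
                       interleave_factor = 1, noise_sd = 0.01,
                       seed = 1L) {
  spec <- as.list(environment())
  counts <- c(spec$n_stems, spec$n_leaves, spec$n_flowers)
  if (any(counts < 0L)) stop("organ counts must be >= 0")
  if (sum(counts) == 0L)
    stop("degenerate spec: at least one organ instance is required")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (spec$interleave_factor < 0 || spec$interleave_factor > 1)
    stop("interleave_factor must lie in [0, 1]")
  structure(spec, class = "plant_spec")
}

rint <- function(rg) if (rg[1] == rg[2]) as.integer(rg[1]) else
  sample(seq(as.integer(rg[1]), as.integer(rg[2])), 1L)
runif1 <- function(rg) stats::runif(1L, rg[1], rg[2])

unit <- function(v) v / max(sqrt(sum(v^2)), 1e-12)

# Any unit vector orthogonal to v.
orth <- function(v) {
  u <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(pracma_cross(v, u))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Smooth space curve through jittered control points; returns an
# ne x 3 polyline.
stem_curve <- function(base, dir, len, curv, ne = 120L) {
  tt <- seq(0, 1, length.out = 5L)
  ctrl <- outer(tt * len, dir) +
    matrix(rep(base, each = 5L), 5L, 3L)
  jit <- matrix(stats::rnorm(15L, sd = curv * len), 5L, 3L)
  jit[1L, ] <- 0                       # keep the attachment point exact
  ctrl <- ctrl + jit
  te <- seq(0, 1, length.out = ne)
  vapply(1:3, function(c)
    stats::spline(tt, ctrl[, c], xout = te)$y, numeric(ne))
}

sample_tube <- function(poly, radius, n) {
  ne <- nrow(poly)
  ti <- sample.int(ne, n, replace = TRUE)
  tang <- poly[pmin(ti + 1L, ne), ] - poly[pmax(ti - 1L, 1L), ]
  pts <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    e1 <- orth(unit(tang[i, ]))
    e2 <- pracma_cross(unit(tang[i, ]), e1)
    ang <- stats::runif(1L, 0, 2 * pi)
    r <- radius * sqrt(stats::runif(1L))
    pts[i, ] <- poly[ti[i], ] + r * (cos(ang) * e1 + sin(ang) * e2)
  }
  pts
}

sample_leaf <- function(att, size, n) {
  az <- stats::runif(1L, 0, 2 * pi)
  elev <- stats::runif(1L, -0.3, 0.5)
  e1 <- unit(c(cos(az) * cos(elev), sin(az) * cos(elev), sin(elev)))
  e2 <- unit(pracma_cross(e1, orth(e1)))
  e3 <- pracma_cross(e1, e2)
  a <- size / 2
  b <- 0.6 * a
  bend <- 0.3 * a * sample(c(-1, 1), 1L)
  r <- sqrt(stats::runif(n)); ang <- stats::runif(n, 0, 2 * pi)
  pu <- r * cos(ang); pv <- r * sin(ang)
  sweep_pts <- outer(a * (pu + 1), e1) + outer(b * pv, e2) +
    outer(bend * (pu + 1)^2 / 2, e3)
  sweep(sweep_pts, 2L, att, "+")
}

sample_flower <- function(tip, radius, n) {
  np <- sample(5:8, 1L)
  per <- diff(round(seq(0, n, length.out = np + 1L)))
  out <- matrix(0, 0, 3L)
  for (p in seq_len(np)) {
    if (per[p] == 0L) next
    az <- 2 * pi * p / np + stats::runif(1L, -0.2, 0.2)
    tilt <- stats::runif(1L, 0.5, 1.1)   # petals cup upwards
    e1 <- unit(c(cos(az) * cos(tilt), sin(az) * cos(tilt), sin(tilt)))
    e2 <- unit(pracma_cross(e1, orth(e1)))
    e3 <- pracma_cross(e1, e2)
    a <- radius * 0.8; b <- radius * 0.45
    r <- sqrt(stats::runif(per[p])); ang <- stats::runif(per[p], 0, 2 * pi)
    pu <- r * cos(ang); pv <- r * sin(ang)
    pts <- outer(a * (pu + 1) / 2, e1) + outer(b * pv, e2) +
      outer(0.2 * a * (pu + 1)^2 / 2, e3)
    out <- rbind(out, sweep(pts, 2L, tip, "+"))
  }
  out
}

#' Generate one labelled synthetic plant
#'
#' Stems are sampled on tubes around smooth space curves, leaves on bent
#' elliptical patches attached to stems, flowers on petal clusters at stem
#' tips.  `interleave_factor` blends between the naturally attached layout
#' (1) and a fully separated per-organ grid (0).  Deterministic for a fixed
#' spec.
#'
#' @param spec a [plant_spec()].
#' @return a labelled [point_cloud]; attributes `organ_id` (instance id per
#'   point) and `curves` (the noise-free stem polylines, for validation).
#' @export
generate_plant <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  with_local_seed(spec$seed, {
    polys <- list()
    if (spec$n_stems >= 1L) {
      curv <- runif1(spec$stem_curvature)
      polys[[1L]] <- stem_curve(c(0, 0, 0), c(0, 0, 1), 1, curv)
      if (spec$n_stems > 1L) for (s in 2:spec$n_stems) {
        host <- polys[[sample.int(length(polys), 1L)]]
        u <- stats::runif(1L, 0.25, 0.85)
        att <- host[max(1L, round(u * nrow(host))), ]
        az <- stats::runif(1L, 0, 2 * pi)
        elev <- stats::runif(1L, 0.5, 1.2)
        dir <- unit(c(cos(az) * cos(elev), sin(az) * cos(elev), sin(elev)))
        polys[[s]] <- stem_curve(att, dir, runif1(c(0.45, 0.75)),
                                 runif1(spec$stem_curvature))
      }
    }
    # attachment pool for leaves; flower anchors are stem tips
    pool <- if (length(polys)) do.call(rbind, polys) else
      matrix(stats::rnorm(30L, sd = 0.2), 10L, 3L)
    tips <- if (length(polys))
      do.call(rbind, lapply(polys, function(p) p[nrow(p), ])) else pool

    organs <- list()
    for (s in seq_len(spec$n_stems)) {
      n <- rint(spec$points_per_organ$stem)
      organs[[length(organs) + 1L]] <- list(
        pts = sample_tube(polys[[s]], spec$stem_radius, n),
        label = ORGAN_CLASSES[["stem"]])
    }
    for (l in seq_len(spec$n_leaves)) {
      att <- pool[sample.int(nrow(pool), 1L), ]
      organs[[length(organs) + 1L]] <- list(
        pts = sample_leaf(att, runif1(spec$leaf_size),
                          rint(spec$points_per_organ$leaf)),
        label = ORGAN_CLASSES[["leaf"]])
    }
    for (f in seq_len(spec$n_flowers)) {
      tip <- tips[1L + (f - 1L) %% nrow(tips), ]
      organs[[length(organs) + 1L]] <- list(
        pts = sample_flower(tip, spec$flower_radius,
                            rint(spec$points_per_organ$flower)),
        label = ORGAN_CLASSES[["flower"]])
    }

    # interleave blending: translate instances toward a separated grid
    lam <- spec$interleave_factor
    if (lam < 1) {
      cents <- t(vapply(organs, function(o) colMeans(o$pts), numeric(3)))
      rad <- vapply(seq_along(organs), function(i)
        max(sqrt(rowSums(sweep(organs[[i]]$pts, 2L, cents[i, ], "-")^2))),
        numeric(1))
      margin <- max(0.15, 8 * spec$noise_sd)
      spacing <- 2 * max(rad) + margin
      g <- ceiling(length(organs)^(1 / 3))
      grid <- as.matrix(expand.grid(x = seq_len(g), y = seq_len(g),
                                    z = seq_len(g)))[seq_along(organs), ] *
        spacing
      for (i in seq_along(organs))
        organs[[i]]$pts <- organs[[i]]$pts +
          matrix(rep((1 - lam) * (grid[i, ] - cents[i, ]),
                     each = nrow(organs[[i]]$pts)),
                 ncol = 3L)
    }

    pts <- do.call(rbind, lapply(organs, `[[`, "pts"))
    labels <- unlist(lapply(organs, function(o) rep(o$label, nrow(o$pts))))
    organ_id <- unlist(lapply(seq_along(organs), function(i)
      rep(i, nrow(organs[[i]]$pts))))
    if (spec$noise_sd > 0)
      pts <- pts + matrix(stats::rnorm(length(pts), sd = spec$noise_sd),
                          ncol = 3L)
    out <- point_cloud(pts, labels)
    attr(out, "organ_id") <- organ_id
    attr(out, "curves") <- polys
    out
  })
}

#' Generate a train/test dataset of synthetic plants
#'
#' Plants are split by whole plant (never by block) into train and test
#' partitions, then each plant is block-split and every block resampled to
#' `n_points`.  A manifest records the seeds and parameters needed to
#' regenerate the dataset bitwise (see [regenerate_dataset()]).
#'
#' @param n_plants number of plants (`>= 2`).
#' @param spec base [plant_spec()]; per-plant specs jitter its organ counts
#'   and sizes slightly.
#' @param seed master RNG seed.
#' @param n_test number of held-out test plants (default: the 9:2
#'   train/test shape, `round(n_plants * 2/11)`).
#' @param target_points,min_points block-splitting parameters.
#' @param n_points points per resampled block.
#' @return list with `train` and `test` (each `blocks` + `provenance` plant
#'   ids), `plants` (the whole clouds) and `manifest`.
#' @export
generate_dataset <- function(n_plants, spec = plant_spec(), seed = 1L,
                             n_test = max(1L, round(n_plants * 2 / 11)),
                             target_points = 2048L,
                             min_points = max(1L, target_points %/% 4L),
                             n_points = target_points) {
  if (n_plants < 2L) stop("n_plants must be >= 2")
  if (n_test < 1L || n_test >= n_plants)
    stop("n_test must leave at least one training plant")
  setup <- with_local_seed(seed, list(
    plant_seeds = sample.int(.Machine$integer.max, n_plants),
    test_ids = sort(sample.int(n_plants, n_test))))
  plants <- lapply(seq_len(n_plants), function(i) {
    sp <- jitter_spec(spec, setup$plant_seeds[i])
    generate_plant(sp)
  })
  make_part <- function(ids) {
    blocks <- list(); prov <- integer()
    for (i in ids) {
      bs <- split_into_blocks(plants[[i]], target_points, min_points)
      for (j in seq_along(bs$blocks)) {
        blocks[[length(blocks) + 1L]] <-
          resample_block(bs$blocks[[j]], n_points,
                         seed = setup$plant_seeds[i] %% 1000000L + j)
        prov <- c(prov, i)
      }
    }
    list(blocks = blocks, provenance = prov)
  }
  train_ids <- setdiff(seq_len(n_plants), setup$test_ids)
  manifest <- list(format = "plantseg3d-dataset/1",
                   n_plants = n_plants, seed = seed, n_test = n_test,
                   plant_seeds = setup$plant_seeds,
                   test_ids = setup$test_ids,
                   target_points = target_points,
                   min_points = min_points, n_points = n_points,
                   base_spec = unclass(spec))
  list(train = make_part(train_ids), test = make_part(setup$test_ids),
       plants = plants, manifest = manifest)
}

# Per-plant variation around the base spec: counts jittered by +/-1,
# sizes by +/-10%.
jitter_spec <- function(spec, seed) {
  with_local_seed(seed, {
    s <- unclass(spec)
    s$seed <- seed
    s$n_leaves <- max(0L, s$n_leaves + sample(-1:1, 1L))
    s$n_flowers <- max(0L, s$n_flowers + sample(-1:1, 1L))
    s$leaf_size <- s$leaf_size * stats::runif(1L, 0.9, 1.1)
    s$flower_radius <- s$flower_radius * stats::runif(1L, 0.9, 1.1)
    do.call(plant_spec, s)
  })
}

#' Regenerate a dataset from its manifest
#'
#' Reruns [generate_dataset()] with the recorded parameters; the result is
#' bitwise identical to the original.
#'
#' @param manifest the `manifest` element returned by [generate_dataset()].
#' @return as [generate_dataset()].
#' @export
regenerate_dataset <- function(manifest) {
  stopifnot(identical(manifest$format, "plantseg3d-dataset/1"))
  generate_dataset(n_plants = manifest$n_plants,
                   spec = do.call(plant_spec, manifest$base_spec),
                   seed = manifest$seed, n_test = manifest$n_test,
                   target_points = manifest$target_points,
                   min_points = manifest$min_points,
                   n_points = manifest$n_points)
}
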