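#' Organ class encoding
#'
#' Fixed label encoding used throughout the package: flower = 0, leaf = 1,
#' stem = 2.
#' @export
ORGAN_CLASSES <- c(flower = 0L, leaf = 1L, stem = 2L)

#' Construct a (optionally labelled) point cloud
#'
#' The fundamental container: an N x 3 matrix of x, y, z coordinates plus an
#' optional integer organ label per point (0 = flower, 1 = leaf, 2 = stem).
#'
#' @param coords numeric N x 3 matrix of coordinates (any consistent unit).
#' @param labels optional integer vector of length N with values in 0:2.
#' @return an object of class `point_cloud` with elements `coords`, `labels`
#'   (possibly `NULL`) and `n`.
#' @export
point_cloud <- function(coords, labels = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must have 3 columns (x, y, z)")
  if (nrow(coords) < 1L) stop("point cloud must contain at least one point")
  if (!all(is.finite(coords))) stop("coords contain non-finite values")
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(coords))
      stop("labels length (", length(labels), ") != point count (",
           nrow(coords), ")")
    bad <- !labels %in% ORGAN_CLASSES
    if (any(bad))
      stop("unknown label value(s): ",
           paste(unique(labels[bad]), collapse = ", "),
           " (allowed: 0=flower, 1=leaf, 2=stem)")
  }
  structure(list(coords = coords, labels = labels, n = nrow(coords)),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat("point_cloud:", x$n, "points,",
      if (is.null(x$labels)) "unlabelled" else "labelled", "\n")
  if (!is.null(x$labels)) {
    tab <- table(factor(x$labels, levels = ORGAN_CLASSES,
                        labels = names(ORGAN_CLASSES)))
    cat("  ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

has_labels <- function(cloud) !is.null(cloud$labels)

#' Read a point cloud from disk
#'
#' Supports plain ASCII `x y z [label]` files (whitespace separated, `#`
#' comments) and PLY files (ascii or binary_little_endian) with vertex
#' properties x, y, z and an optional integer label.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"xyz"` or `"ply"`.
#' @return a [point_cloud], labelled if the file carries a label column.
#' @export
read_point_cloud <- function(path, format = c("auto", "xyz", "ply")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz"
  switch(format, xyz = read_xyz(path), ply = read_ply(path))
}

#' Write a point cloud to disk
#'
#' The written file is re-readable by [read_point_cloud()] with exact
#' equality of coordinates and labels (coordinates are stored as doubles in
#' both formats).
#'
#' @param cloud a [point_cloud].
#' @param path output file path.
#' @param format `"auto"` (by extension), `"xyz"` or `"ply"`.
#' @param ply_mode `"binary_little_endian"` or `"ascii"` (PLY only).
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = c("auto", "xyz", "ply"),
                              ply_mode = c("binary_little_endian", "ascii")) {
  format <- match.arg(format)
  ply_mode <- match.arg(ply_mode)
  stopifnot(inherits(cloud, "point_cloud"))
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz"
  switch(format,
         xyz = write_xyz(cloud, path),
         ply = write_ply(cloud, path, ply_mode))
  invisible(path)
}

## ---- ASCII xyz -------------------------------------------------------------

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no data records in ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(toks)
  if (any(nf != nf[1L]))
    stop("malformed record at line ", lineno[which(nf != nf[1L])[1L]],
         " of ", path, ": expected ", nf[1L], " fields, got ",
         nf[nf != nf[1L]][1L])
  if (!nf[1L] %in% c(3L, 4L))
    stop("expected 3 (x y z) or 4 (x y z label) columns, got ", nf[1L])
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) {
    bad <- ceiling(which(is.na(vals))[1L] / nf[1L])
    stop("non-numeric field at line ", lineno[bad], " of ", path)
  }
  m <- matrix(vals, ncol = nf[1L], byrow = TRUE)
  labels <- if (nf[1L] == 4L) {
    l <- m[, 4L]
    if (any(l != round(l))) stop("non-integer label values in ", path)
    as.integer(l)
  }
  point_cloud(m[, 1:3, drop = FALSE], labels)
}

write_xyz <- function(cloud, path) {
  co <- matrix(sprintf("%.17g", cloud$coords), ncol = 3L)
  rows <- paste(co[, 1L], co[, 2L], co[, 3L])
  if (has_labels(cloud)) rows <- paste(rows, cloud$labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(rows, con)
}

## ---- PLY -------------------------------------------------------------------

.ply_sizes <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                float = 4L, float32 = 4L, double = 8L, float64 = 8L)

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ascii, one statement per line
  hdr <- character()
  repeat {
    line <- readBin(con, "raw", n = 1L)
    buf <- raw()
    while (length(line) == 1L && line != as.raw(10L)) {
      buf <- c(buf, line)
      line <- readBin(con, "raw", n = 1L)
    }
    stmt <- trimws(rawToChar(buf))
    hdr <- c(hdr, stmt)
    if (identical(stmt, "end_header")) break
    if (length(line) == 0L) stop("truncated PLY header in ", path)
  }
  if (!identical(hdr[1L], "ply")) stop(path, " is not a PLY file")
  fmt <- sub("^format\\s+", "", grep("^format ", hdr, value = TRUE)[1L])
  fmt <- strsplit(fmt, "\\s+")[[1L]][1L]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)
  # first element must be vertex; trailing elements are ignored
  el <- grep("^element ", hdr)
  if (length(el) == 0L) stop("PLY file has no element declarations")
  first <- strsplit(hdr[el[1L]], "\\s+")[[1L]]
  if (first[2L] != "vertex")
    stop("expected 'element vertex' first in PLY header, got ", first[2L])
  nvert <- as.integer(first[3L])
  pend <- if (length(el) > 1L) el[2L] - 1L else length(hdr) - 1L
  props <- hdr[seq(el[1L] + 1L, pend)]
  props <- props[grepl("^property ", props)]
  ptok <- strsplit(props, "\\s+")
  if (any(vapply(ptok, function(t) t[2L] == "list", logical(1))))
    stop("list properties on vertex element are not supported")
  ptype <- vapply(ptok, `[[`, "", 2L)
  pname <- vapply(ptok, `[[`, "", 3L)
  if (!all(ptype %in% names(.ply_sizes)))
    stop("unsupported property type(s): ",
         paste(setdiff(ptype, names(.ply_sizes)), collapse = ", "))
  need <- c("x", "y", "z")
  if (!all(need %in% pname))
    stop("PLY vertex element lacks x/y/z properties")

  cols <- if (fmt == "ascii") {
    lines <- readLines(con, n = nvert, warn = FALSE)
    if (length(lines) < nvert) stop("truncated PLY body in ", path)
    vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(lines), "\\s+"))))
    if (anyNA(vals) || length(vals) != nvert * length(pname))
      stop("malformed PLY ascii body in ", path)
    m <- matrix(vals, ncol = length(pname), byrow = TRUE)
    stats::setNames(lapply(seq_along(pname), function(j) m[, j]), pname)
  } else {
    sizes <- .ply_sizes[ptype]
    rowbytes <- sum(sizes)
    body <- readBin(con, "raw", n = nvert * rowbytes)
    if (length(body) < nvert * rowbytes) stop("truncated PLY body in ", path)
    offs <- c(0L, cumsum(sizes))
    out <- lapply(seq_along(pname), function(j) {
      s <- sizes[j]
      pos <- rep((seq_len(nvert) - 1L) * rowbytes, each = s) +
        rep((offs[j] + 1L):(offs[j] + s), times = nvert)
      sub <- body[pos]
      tp <- ptype[j]
      if (tp %in% c("float", "float32", "double", "float64")) {
        readBin(sub, "double", n = nvert, size = s, endian = "little")
      } else {
        signed <- tp %in% c("char", "int8", "short", "int16", "int", "int32")
        as.numeric(readBin(sub, "integer", n = nvert, size = s,
                           endian = "little", signed = signed || s == 4L))
      }
    })
    stats::setNames(out, pname)
  }
  labels <- if ("label" %in% pname) as.integer(cols[["label"]])
  point_cloud(cbind(cols[["x"]], cols[["y"]], cols[["z"]]), labels)
}

write_ply <- function(cloud, path, mode = "binary_little_endian") {
  n <- cloud$n
  hdr <- c("ply",
           paste("format", mode, "1.0"),
           "comment written by plantseg3d",
           paste("element vertex", n),
           "property double x",
           "property double y",
           "property double z",
           if (has_labels(cloud)) "property int label",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  if (mode == "ascii") {
    co <- matrix(sprintf("%.17g", cloud$coords), ncol = 3L)
    rows <- paste(co[, 1L], co[, 2L], co[, 3L])
    if (has_labels(cloud)) rows <- paste(rows, cloud$labels)
    writeBin(charToRaw(paste0(paste(rows, collapse = "\n"), "\n")), con)
  } else {
    craw <- writeBin(as.vector(t(cloud$coords)), raw(), size = 8L,
                     endian = "little")
    if (has_labels(cloud)) {
      lraw <- writeBin(cloud$labels, raw(), size = 4L, endian = "little")
      rowbytes <- 28L
      out <- raw(n * rowbytes)
      cpos <- rep((seq_len(n) - 1L) * rowbytes, each = 24L) + rep(1:24, n)
      lpos <- rep((seq_len(n) - 1L) * rowbytes, each = 4L) + rep(25:28, n)
      out[cpos] <- craw
      out[lpos] <- lraw
      writeBin(out, con)
    } else {
      writeBin(craw, con)
    }
  }
}

## ---- block-set persistence -------------------------------------------------

#' Write a block set to a directory
#'
#' Each block becomes `block_0001.xyz`, `block_0002.xyz`, ... alongside a
#' `manifest.json` recording per-block provenance (source plant index).
#'
#' @param bs a `block_set` (see [split_into_blocks()]) or plain list of
#'   [point_cloud] blocks.
#' @param dir output directory (created if missing).
#' @param provenance optional integer vector of source-plant ids per block.
#' @return `dir`, invisibly.
#' @export
write_block_dir <- function(bs, dir, provenance = NULL) {
  blocks <- if (inherits(bs, "block_set")) bs$blocks else bs
  if (is.null(provenance) && inherits(bs, "block_set"))
    provenance <- bs$provenance
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("block_%04d.xyz", seq_along(blocks))
  for (i in seq_along(blocks))
    write_point_cloud(blocks[[i]], file.path(dir, files[i]), "xyz")
  manifest <- list(n_blocks = length(blocks), files = files,
                   provenance = provenance,
                   sizes = vapply(blocks, function(b) b$n, integer(1)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a block set written by [write_block_dir()]
#' @param dir directory containing `manifest.json`.
#' @return list with `blocks` and `provenance`.
#' @export
read_block_dir <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  blocks <- lapply(file.path(dir, mf$files), read_point_cloud, format = "xyz")
  list(blocks = blocks, provenance = mf$provenance)
}
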