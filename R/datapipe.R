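# Multispectral data pipeline: radiometric conversion, scene tiling,
# train/validation/test splitting, augmentation, and tile I/O.
#
# Conventions: images are H x W x C reflectance/DN arrays, masks are H x W
# with 0 = background and 1 = foreground; on disk masks are 8-bit rasters
# with {0, 255} mapped to {0, 1} on read.  Tile origins are 0-based
# (row, col) offsets into the source scene; tile intervals are half-open.

#' Radiometric conversion from digital numbers to radiance
#'
#' Applies the per-band affine sensor calibration `L = gain * DN + bias`.
#'
#' @param dn digital-number grid: H x W matrix (one band) or H x W x B array.
#' @param gain,bias numeric vectors with one entry per band (scalars are
#'   recycled across a single band only).
#' @return Radiance grid with the same shape as `dn`.
#' @examples
#' to_radiance(matrix(200, 2, 2), gain = 0.5, bias = 3)  # 103
#' @export
to_radiance <- function(dn, gain, bias = 0) {
  one_band <- is.matrix(dn)
  if (one_band) dn <- array(dn, c(dim(dn), 1L))
  if (!is.array(dn) || length(dim(dn)) != 3L)
    stop("`dn` must be a matrix or an H x W x B array")
  B <- dim(dn)[3]
  if (length(bias) == 1L) bias <- rep(bias, B)
  if (length(gain) != B || length(bias) != B)
    stop(sprintf("need %d gains/biases, got %d/%d", B, length(gain), length(bias)))
  stopifnot(all(is.finite(gain)), all(is.finite(bias)))
  M <- dim(dn)[1] * dim(dn)[2]
  out <- dn * rep(gain, each = M) + rep(bias, each = M)
  if (one_band) out <- out[, , 1]
  out
}

#' Tile origins covering a scene
#'
#' Row-major grid of non-overlapping `tile` x `tile` windows.  Under the
#' default `"drop"` policy partial edge tiles are discarded; under
#' `"mirror"` the scene is reflection-padded up to whole multiples first.
#'
#' @param scene_dim integer (rows, cols) of the scene.
#' @param tile tile edge length in pixels.
#' @param policy `"drop"` or `"mirror"`.
#' @return Data frame with 0-based `row0`, `col0` origins.
#' @examples
#' nrow(tile_origins(c(8076, 27058), 512))  # 15 * 52 = 780
#' @export
tile_origins <- function(scene_dim, tile = 512L, policy = c("drop", "mirror")) {
  policy <- match.arg(policy)
  tile <- as.integer(tile)
  nr <- if (policy == "drop") scene_dim[1] %/% tile else ceiling(scene_dim[1] / tile)
  nc <- if (policy == "drop") scene_dim[2] %/% tile else ceiling(scene_dim[2] / tile)
  if (nr < 1L || nc < 1L) stop("scene is smaller than one tile")
  g <- expand.grid(col0 = (seq_len(nc) - 1L) * tile,
                   row0 = (seq_len(nr) - 1L) * tile)
  data.frame(row0 = g$row0, col0 = g$col0)
}

#' @keywords internal
mirror_pad_to <- function(a, nr, nc) {
  d <- dim(a)
  ri <- c(seq_len(d[1]), rev(seq_len(d[1])))[seq_len(nr)]
  ci <- c(seq_len(d[2]), rev(seq_len(d[2])))[seq_len(nc)]
  if (length(d) == 3L) a[ri, ci, , drop = FALSE] else a[ri, ci, drop = FALSE]
}

#' Cut a scene into paired image/mask tiles
#'
#' Subdivides a multiband scene and its ground-truth masks into aligned
#' `tile` x `tile` records on a row-major grid.
#'
#' @param image H x W x B scene array.
#' @param stand_mask,row_mask H x W binary masks aligned with `image`
#'   (either may be `NULL`, in which case an all-zero mask is substituted).
#' @param tile tile edge length (default 512).
#' @param policy edge policy, see [tile_origins()].
#' @param scene scene/cultivar identifier recorded in each tile.
#' @return List of tile records: each has `id`, `scene`, `image`,
#'   `stand_mask`, `row_mask`, `origin` (0-based row, col) and `split`
#'   (initially `"unassigned"`).
#' @export
tile_scene <- function(image, stand_mask = NULL, row_mask = NULL, tile = 512L,
                       policy = c("drop", "mirror"), scene = "scene") {
  policy <- match.arg(policy)
  stopifnot(is.array(image), length(dim(image)) == 3L)
  d <- dim(image)
  zero <- matrix(0, d[1], d[2])
  stand_mask <- stand_mask %||% zero
  row_mask <- row_mask %||% zero
  if (!all(dim(stand_mask) == d[1:2]) || !all(dim(row_mask) == d[1:2]))
    stop("masks must be aligned with the image")
  org <- tile_origins(d[1:2], tile, policy)
  if (policy == "mirror") {
    nr <- max(org$row0) + tile; nc <- max(org$col0) + tile
    image <- mirror_pad_to(image, nr, nc)
    stand_mask <- mirror_pad_to(stand_mask, nr, nc)
    row_mask <- mirror_pad_to(row_mask, nr, nc)
  }
  lapply(seq_len(nrow(org)), function(i) {
    r <- org$row0[i]; c <- org$col0[i]
    ri <- (r + 1L):(r + tile); ci <- (c + 1L):(c + tile)
    tile_record(id = sprintf("%s_%05d_%05d", scene, r, c), scene = scene,
                image = image[ri, ci, , drop = FALSE],
                stand_mask = stand_mask[ri, ci],
                row_mask = row_mask[ri, ci],
                origin = c(r, c))
  })
}

#' @keywords internal
tile_record <- function(id, scene, image, stand_mask, row_mask,
                        origin = c(0L, 0L), split = "unassigned") {
  stopifnot(all(stand_mask %in% c(0, 1)), all(row_mask %in% c(0, 1)),
            all(dim(image)[1:2] == dim(stand_mask)),
            all(dim(image)[1:2] == dim(row_mask)), all(origin >= 0))
  structure(list(id = id, scene = scene, image = image,
                 stand_mask = stand_mask, row_mask = row_mask,
                 origin = as.integer(origin), split = split),
            class = "tile_record")
}

#' @export
print.tile_record <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<tile_record> %s  %dx%dx%d  origin (%d, %d)  split %s\n",
              x$id, d[1], d[2], d[3], x$origin[1], x$origin[2], x$split))
  invisible(x)
}

#' Assign tiles to train/validation/test partitions
#'
#' Seeded uniform shuffle followed by contiguous assignment.  Counts use
#' round-half-up on the train and validation fractions, with the test set
#' taking the remainder; for sizes divisible by 10 a 6:1:3 ratio therefore
#' gives exactly 60/10/30 percent.  When `strata` is supplied (e.g. one
#' stratum per cultivar scene) the assignment is done independently within
#' each stratum.
#'
#' @param ids vector of tile identifiers (length >= 10 overall).
#' @param ratios train/validation/test fractions summing to 1.
#' @param seed integer shuffle seed; same seed, same assignment.
#' @param strata optional factor aligned with `ids`.
#' @return A data frame (class `"split_assignment"`) with columns `id` and
#'   `split`, in the original order of `ids`.
#' @examples
#' table(split_dataset(sprintf("t%04d", 1:3800), seed = 7)$split)
#' @export
split_dataset <- function(ids, ratios = c(0.6, 0.1, 0.3), seed = 1L,
                          strata = NULL) {
  if (abs(sum(ratios) - 1) > 1e-8 || length(ratios) != 3L || any(ratios < 0))
    stop("`ratios` must be three non-negative fractions summing to 1")
  N <- length(ids)
  if (N < 10L) stop("need at least 10 tiles to split")
  if (anyDuplicated(ids)) stop("tile ids must be unique")
  split <- character(N)
  groups <- if (is.null(strata)) list(seq_len(N))
            else unname(split(seq_len(N), strata))
  with_seed(seed, {
    for (idx in groups) {
      n <- length(idx)
      n_tr <- round_half_up(ratios[1] * n)
      n_va <- round_half_up(ratios[2] * n)
      n_te <- n - n_tr - n_va
      if (n_te < 0) stop("degenerate split for a stratum of size ", n)
      perm <- sample(idx)
      split[perm] <- rep(c("train", "validation", "test"),
                         c(n_tr, n_va, n_te))
    }
  })
  structure(data.frame(id = ids, split = split, stringsAsFactors = FALSE),
            class = c("split_assignment", "data.frame"),
            ratios = ratios, seed = as.integer(seed))
}

#' Apply a split assignment to a list of tile records
#'
#' @param records list of tile records.
#' @param assignment a [split_dataset()] result.
#' @return The records with their `split` fields filled in.
#' @export
assign_split <- function(records, assignment) {
  m <- match(vapply(records, `[[`, "", "id"), assignment$id)
  if (anyNA(m)) stop("assignment does not cover all records")
  for (i in seq_along(records)) records[[i]]$split <- assignment$split[m[i]]
  records
}

# ---- augmentation ------------------------------------------------------

#' @keywords internal
flip_lr <- function(a) if (length(dim(a)) == 3L) a[, rev(seq_len(dim(a)[2])), , drop = FALSE] else a[, rev(seq_len(ncol(a)))]

#' @keywords internal
flip_ud <- function(a) if (length(dim(a)) == 3L) a[rev(seq_len(dim(a)[1])), , , drop = FALSE] else a[rev(seq_len(nrow(a))), ]

# 90-degree counter-clockwise rotation of the two leading dims.
#' @keywords internal
rot90_ccw <- function(a) {
  if (length(dim(a)) == 3L) {
    b <- aperm(a, c(2, 1, 3))
    b[rev(seq_len(dim(b)[1])), , , drop = FALSE]
  } else {
    b <- t(a)
    b[rev(seq_len(nrow(b))), , drop = FALSE]
  }
}

# Mild rescale (factor in [0.8, 1.25]) followed by centre crop/pad back to
# the original size; bilinear for images, nearest-neighbour for masks.
#' @keywords internal
resample_plane <- function(a, factor, nearest) {
  d <- dim(a)[1:2]
  ns <- pmax(round(d * factor), 1L)
  map_idx <- function(n_out, n_in) {
    src <- (seq_len(n_out) - 0.5) / factor - 0.5  # 0-based source coords
    list(lo = pmin(pmax(floor(src), 0), n_in - 1),
         fr = src - floor(src))
  }
  ri <- map_idx(ns[1], d[1]); ci <- map_idx(ns[2], d[2])
  if (nearest) {
    r <- pmin(pmax(round(ri$lo + ri$fr), 0), d[1] - 1) + 1
    c <- pmin(pmax(round(ci$lo + ci$fr), 0), d[2] - 1) + 1
    s <- if (length(dim(a)) == 3L) a[r, c, , drop = FALSE] else a[r, c]
  } else {
    rlo <- ri$lo + 1; rhi <- pmin(ri$lo + 1, d[1] - 1) + 1; rf <- ri$fr
    clo <- ci$lo + 1; chi <- pmin(ci$lo + 1, d[2] - 1) + 1; cf <- ci$fr
    gget <- function(r, c) if (length(dim(a)) == 3L) a[r, c, , drop = FALSE] else a[r, c]
    # weights as plain vectors so they recycle over a trailing band axis
    s <- gget(rlo, clo) * c(outer(1 - rf, 1 - cf)) +
      gget(rhi, clo) * c(outer(rf, 1 - cf)) +
      gget(rlo, chi) * c(outer(1 - rf, cf)) +
      gget(rhi, chi) * c(outer(rf, cf))
  }
  # centre crop or zero-pad back to the original size
  out <- if (length(dim(a)) == 3L) array(0, dim(a)) else matrix(0, d[1], d[2])
  off <- floor((ns - d) / 2)
  src_r <- pmax(off[1], 0) + seq_len(min(ns[1], d[1]))
  src_c <- pmax(off[2], 0) + seq_len(min(ns[2], d[2]))
  dst_r <- pmax(-off[1], 0) + seq_len(min(ns[1], d[1]))
  dst_c <- pmax(-off[2], 0) + seq_len(min(ns[2], d[2]))
  if (length(dim(a)) == 3L) out[dst_r, dst_c, ] <- s[src_r, src_c, , drop = FALSE]
  else out[dst_r, dst_c] <- s[src_r, src_c]
  out
}

#' Augment a tile record
#'
#' Applies each plan entry to the image and both masks identically and
#' returns one new record per entry.  Supported operations: `"hflip"`,
#' `"vflip"`, `"rot90"`, `"rot180"`, `"rot270"` (counter-clockwise) and
#' `"resample"` (mild rescale by a factor in [0.8, 1.25], bilinear for the
#' image and nearest-neighbour for the masks, cropped/padded back to size).
#' A plan entry may also be `list(op = "resample", factor = 1.1)`; a bare
#' `"resample"` draws its factor from the seeded RNG.
#'
#' @param record a tile record.
#' @param plan non-empty character vector or list of op entries.
#' @param seed seed for any randomized ops.
#' @return List of augmented tile records (ids suffixed with the op).
#' @export
augment <- function(record, plan, seed = 1L) {
  stopifnot(inherits(record, "tile_record"), length(plan) >= 1L)
  apply_op <- function(a, op, factor, nearest) {
    switch(op,
           hflip = flip_lr(a),
           vflip = flip_ud(a),
           rot90 = rot90_ccw(a),
           rot180 = rot90_ccw(rot90_ccw(a)),
           rot270 = rot90_ccw(rot90_ccw(rot90_ccw(a))),
           resample = resample_plane(a, factor, nearest),
           stop("unknown augmentation op: ", op))
  }
  with_seed(seed, {
    lapply(seq_along(plan), function(i) {
      entry <- plan[[i]]
      op <- if (is.list(entry)) entry$op else entry
      factor <- if (is.list(entry) && !is.null(entry$factor)) entry$factor
                else stats::runif(1, 0.8, 1.25)
      rec <- record
      rec$image <- apply_op(record$image, op, factor, nearest = FALSE)
      rec$stand_mask <- apply_op(record$stand_mask, op, factor, nearest = TRUE)
      rec$row_mask <- apply_op(record$row_mask, op, factor, nearest = TRUE)
      rec$id <- paste0(record$id, "_", op, i)
      rec
    })
  })
}

# ---- tile I/O ----------------------------------------------------------

#' Write tile records to a directory
#'
#' Images are written as multi-page 32-bit float TIFFs (one page per band),
#' masks as single-band PNGs with values {0, 255}, plus a tab-separated
#' manifest (`manifest.tsv`) mapping each tile id to its scene, origin,
#' split and file names.
#'
#' @param records list of tile records.
#' @param dir output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_tile_dataset <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(records, function(r) {
    img_file <- paste0(r$id, "_img.tif")
    st_file <- paste0(r$id, "_stand.png")
    rw_file <- paste0(r$id, "_row.png")
    bands <- lapply(seq_len(dim(r$image)[3]), function(b) r$image[, , b])
    tiff::writeTIFF(bands, file.path(dir, img_file), bits.per.sample = 32L,
                    compression = "none")
    png::writePNG(r$stand_mask, file.path(dir, st_file))
    png::writePNG(r$row_mask, file.path(dir, rw_file))
    data.frame(id = r$id, scene = r$scene, row0 = r$origin[1],
               col0 = r$origin[2], split = r$split, image = img_file,
               stand_mask = st_file, row_mask = rw_file,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a tile dataset written by [write_tile_dataset()]
#'
#' @param dir directory containing `manifest.tsv`.
#' @param split optionally restrict to one partition.
#' @return List of tile records.
#' @export
read_tile_dataset <- function(dir, split = NULL) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  if (!is.null(split)) manifest <- manifest[manifest$split %in% split, ]
  lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    pages <- tiff::readTIFF(file.path(dir, m$image), all = TRUE)
    img <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
    for (b in seq_along(pages)) img[, , b] <- pages[[b]]
    read_mask <- function(f) {
      px <- png::readPNG(file.path(dir, f))
      if (length(dim(px)) == 3L) px <- px[, , 1]
      (px > 0.5) * 1
    }
    tile_record(id = m$id, scene = m$scene, image = img,
                stand_mask = read_mask(m$stand_mask),
                row_mask = read_mask(m$row_mask),
                origin = c(m$row0, m$col0), split = m$split)
  })
}
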