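# Dataset-construction pipeline: band resampling to 10 m, reflectance
# normalisation, sliding-window tiling, background filtering, mirror
# augmentation, 7:2:1 splitting, and overlap-averaged stitching of tile
# predictions back into a whole-raster probability plane.

#' Bilinear upsampling of a raster band
#'
#' Upsamples a 2-D plane by an integer factor using bilinear interpolation
#' with the pixel-centre (half-pixel) convention, as used when unifying 20 m
#' Sentinel-2 bands to 10 m.
#'
#' @param band 2-D numeric matrix (NA = nodata).
#' @param factor integer upsampling factor (2 for 20 m -> 10 m).
#' @return matrix with extents `dim(band) * factor`.
#' @export
resample_to_10m <- function(band, factor = 2L) {
  if (!is.matrix(band)) stop("band must be a matrix")
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (factor == 1L) return(band)
  h <- nrow(band); w <- ncol(band)
  coords <- function(n_out, n_in) {
    s <- (seq_len(n_out) - 0.5) / factor - 0.5
    s <- pmin(pmax(s, 0), n_in - 1)
    f <- pmin(floor(s), n_in - 2)
    f <- pmax(f, 0)
    if (n_in == 1L) list(i0 = rep(1L, n_out), i1 = rep(1L, n_out), w1 = rep(0, n_out))
    else list(i0 = as.integer(f) + 1L, i1 = as.integer(f) + 2L, w1 = s - f)
  }
  rc <- coords(h * factor, h)
  cc <- coords(w * factor, w)
  a00 <- band[rc$i0, cc$i0, drop = FALSE]
  a10 <- band[rc$i1, cc$i0, drop = FALSE]
  a01 <- band[rc$i0, cc$i1, drop = FALSE]
  a11 <- band[rc$i1, cc$i1, drop = FALSE]
  wr <- matrix(rc$w1, h * factor, w * factor)
  wc <- matrix(cc$w1, h * factor, w * factor, byrow = TRUE)
  a00 * (1 - wr) * (1 - wc) + a10 * wr * (1 - wc) +
    a01 * (1 - wr) * wc + a11 * wr * wc
}

#' Normalise L2A digital numbers to surface reflectance
#'
#' Standard Sentinel-2 L2A scaling: DN / 10000, clipped to [0, 1]; NA
#' (nodata) is propagated.
#'
#' @param dn numeric array of digital numbers.
#' @return reflectance values in [0, 1].
#' @export
normalize_reflectance <- function(dn) {
  pmin(pmax(dn / 10000, 0), 1)
}

# Window offsets covering axis length L: regular step grid plus one window
# snapped flush to the far edge if the grid does not reach it (0-based).
.window_offsets <- function(len, window, step) {
  offs <- seq.int(0L, len - window, by = step)
  if (offs[length(offs)] + window < len) offs <- c(offs, len - window)
  unique(as.integer(offs))
}

#' Sliding-window tiling of a band stack
#'
#' Emits half-open windows `[r, r+window)` at offsets `0, step, 2*step, ...`
#' per axis, plus a window snapped flush to the raster edge when the grid
#' overruns, so that every pixel is covered by at least one tile.
#'
#' @param stack a [band_stack()] (or bare 10-band array (bands, H, W)).
#' @param mask optional co-registered binary label matrix (H x W).
#' @param window tile side in pixels.
#' @param step window step in pixels (`step <= window`).
#' @return list of tile pairs: `image` (bands, window, window), `mask`
#'   (window x window or NULL), `origin` (0-based row, col), `source_id`,
#'   `keep_flag`.
#' @export
sliding_window_tiles <- function(stack, mask = NULL, window = 512L, step = 256L) {
  window <- as.integer(window); step <- as.integer(step)
  if (step < 1L || step > window) stop("need 1 <= step <= window")
  arr <- if (inherits(stack, "band_stack")) stack$data else stack
  if (length(dim(arr)) != 3L) stop("stack must be a (bands, H, W) array")
  h <- dim(arr)[2L]; w <- dim(arr)[3L]
  if (h < window || w < window)
    stop(sprintf("raster (%dx%d) smaller than window (%d)", h, w, window))
  src <- if (inherits(stack, "band_stack")) stack$source_id else "raster"
  tiles <- list()
  for (r0 in .window_offsets(h, window, step))
    for (c0 in .window_offsets(w, window, step)) {
      tiles[[length(tiles) + 1L]] <- list(
        image = arr[, r0 + seq_len(window), c0 + seq_len(window), drop = FALSE],
        mask = if (!is.null(mask)) mask[r0 + seq_len(window), c0 + seq_len(window)],
        origin = c(row = r0, col = c0),
        source_id = src, keep_flag = TRUE)
    }
  tiles
}

#' Filter out pure-background tiles
#'
#' Tiles with at least one FRA pixel are always retained. Zero-FRA tiles are
#' retained only if they intersect a user-supplied keep region (e.g.
#' rasterised land / tidal-flat polygons) or are sampled as negatives with
#' probability `keep_p` (seeded draws in tile order).
#'
#' @param tiles list of tile pairs with masks.
#' @param keep_region optional binary H x W matrix over the source raster;
#'   a zero-FRA tile overlapping a 1-pixel is kept.
#' @param keep_p probability of retaining a non-overlapping zero-FRA tile.
#' @param seed seed for the retention draws.
#' @return list of retained tiles; the decision log is attached as the
#'   `"decisions"` attribute (one row per input tile).
#' @export
filter_background_tiles <- function(tiles, keep_region = NULL, keep_p = 0,
                                    seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  keep <- logical(length(tiles))
  why <- character(length(tiles))
  for (i in seq_along(tiles)) {
    tl <- tiles[[i]]
    if (is.null(tl$mask)) stop("tiles must carry masks")
    if (sum(tl$mask) > 0) {
      keep[i] <- TRUE; why[i] <- "fra"
    } else if (!is.null(keep_region) &&
               sum(keep_region[tl$origin["row"] + seq_len(nrow(tl$mask)),
                               tl$origin["col"] + seq_len(ncol(tl$mask))]) > 0) {
      keep[i] <- TRUE; why[i] <- "keep_region"
    } else if (stats::runif(1) < keep_p) {
      keep[i] <- TRUE; why[i] <- "sampled_negative"
    } else {
      keep[i] <- FALSE; why[i] <- "background_dropped"
    }
  }
  out <- tiles[keep]
  for (i in seq_along(out)) out[[i]]$keep_flag <- TRUE
  attr(out, "decisions") <- data.frame(tile = seq_along(tiles), kept = keep,
                                       reason = why)
  out
}

# Mirror operations on one tile (image (bands,h,w), mask (h,w)).
.flip_h <- function(tl) {  # horizontal flip: reverse width
  tl$image <- tl$image[, , rev(seq_len(dim(tl$image)[3L])), drop = FALSE]
  if (!is.null(tl$mask)) tl$mask <- tl$mask[, rev(seq_len(ncol(tl$mask)))]
  tl
}
.flip_v <- function(tl) {  # vertical flip: reverse height
  tl$image <- tl$image[, rev(seq_len(dim(tl$image)[2L])), , drop = FALSE]
  if (!is.null(tl$mask)) tl$mask <- tl$mask[rev(seq_len(nrow(tl$mask))), ]
  tl
}
.transpose_tile <- function(tl, anti = FALSE) {  # diagonal mirror
  tl$image <- aperm(tl$image, c(1L, 3L, 2L))
  if (!is.null(tl$mask)) tl$mask <- t(tl$mask)
  if (anti) tl <- .flip_h(.flip_v(tl))
  tl
}

#' Mirror augmentation
#'
#' For each tile emits the original plus its horizontal flip, vertical flip,
#' and diagonal mirror (transpose), expanding the set exactly 4-fold. Image
#' and mask are transformed identically.
#'
#' @param tiles non-empty list of tile pairs.
#' @param anti_diagonal use the anti-diagonal mirror instead of the main
#'   diagonal transpose.
#' @return list of `4 * length(tiles)` tiles (original, hflip, vflip,
#'   diagonal, in that order per tile; `variant` field records which).
#' @export
augment_tiles <- function(tiles, anti_diagonal = FALSE) {
  if (length(tiles) == 0L) stop("tiles must be non-empty")
  out <- vector("list", 4L * length(tiles))
  j <- 0L
  for (tl in tiles) {
    vs <- list(tl, .flip_h(tl), .flip_v(tl),
               .transpose_tile(tl, anti = anti_diagonal))
    nm <- c("orig", "hflip", "vflip", "diag")
    for (i in 1:4) {
      vs[[i]]$variant <- nm[i]
      out[[j + i]] <- vs[[i]]
    }
    j <- j + 4L
  }
  out
}

#' 7:2:1 random split
#'
#' Test gets `floor(0.2 n)`, validation `floor(0.1 n)`, training the
#' remainder (the convention that reproduces 7051/2014/1007 from 10,072);
#' assignment is a seeded shuffle.
#'
#' @param n_tiles number of tiles (>= 10).
#' @param seed shuffle seed.
#' @return a `split_manifest` list: `train`, `test`, `validation` id vectors,
#'   `seed`, `ratio`.
#' @export
split_dataset <- function(n_tiles, seed = 1L) {
  n <- as.integer(n_tiles)
  if (n < 10L) stop("need at least 10 tiles for a 7:2:1 split")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n_test <- floor(0.2 * n)
  n_val <- floor(0.1 * n)
  perm <- sample.int(n)
  structure(list(test = sort(perm[seq_len(n_test)]),
                 validation = sort(perm[n_test + seq_len(n_val)]),
                 train = sort(perm[-seq_len(n_test + n_val)]),
                 seed = seed, ratio = c(train = 7, test = 2, validation = 1)),
            class = "split_manifest")
}

#' Stitch overlapping tile predictions into a raster plane
#'
#' Per-pixel mean of all tile probabilities covering the pixel.
#'
#' @param tile_probs list of (window x window) probability matrices.
#' @param origins list/matrix of 0-based (row, col) tile origins.
#' @param extents target raster extents c(H, W).
#' @return H x W probability matrix.
#' @export
stitch_predictions <- function(tile_probs, origins, extents) {
  h <- extents[1L]; w <- extents[2L]
  acc <- matrix(0, h, w)
  cnt <- matrix(0L, h, w)
  for (i in seq_along(tile_probs)) {
    p <- tile_probs[[i]]
    o <- if (is.list(origins)) origins[[i]] else origins[i, ]
    ri <- o[1L] + seq_len(nrow(p)); ci <- o[2L] + seq_len(ncol(p))
    if (max(ri) > h || max(ci) > w) stop("tile exceeds raster extents")
    acc[ri, ci] <- acc[ri, ci] + p
    cnt[ri, ci] <- cnt[ri, ci] + 1L
  }
  if (any(cnt == 0L)) stop("stitching left uncovered pixels")
  acc / cnt
}
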