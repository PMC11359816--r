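# Raster and tile-directory I/O. Band stacks are stored as multi-page 32-bit
# float TIFFs (one page per band, fixed band order B2,B3,B4,B5,B6,B7,B8,B8A,
# B11,B12) with georeferencing in a plain-text ESRI worldfile (.tfw) and the
# CRS identifier in a .crs.txt sidecar. Label masks are single-channel PNGs.

BAND_NAMES <- c("B2", "B3", "B4", "B5", "B6", "B7", "B8", "B8A", "B11", "B12")

#' Construct a band stack
#'
#' @param data (bands, H, W) reflectance array, values in [0,1], NA = nodata.
#' @param transform geotransform `c(x_origin, pixel_dx, y_origin, pixel_dy)`
#'   of the upper-left pixel centre (dy is negative for north-up rasters).
#' @param crs CRS identifier string (e.g. "EPSG:32651").
#' @param nodata nodata marker used on disk.
#' @param source_id free-text provenance identifier.
#' @return list of class `band_stack`.
#' @export
band_stack <- function(data, transform = c(0, 10, 0, -10), crs = "EPSG:32651",
                       nodata = -9999, source_id = "scene") {
  if (length(dim(data)) != 3L) stop("data must be (bands, H, W)")
  if (dim(data)[1L] != length(BAND_NAMES))
    stop(sprintf("expected %d bands, got %d", length(BAND_NAMES), dim(data)[1L]))
  structure(list(data = data, bands = BAND_NAMES, pixel_size = abs(transform[2L]),
                 transform = transform, crs = crs, nodata = nodata,
                 source_id = source_id),
            class = "band_stack")
}

#' Write / read a band stack as GeoTIFF + worldfile
#'
#' @param stack a [band_stack()].
#' @param path output `.tif` path; `.tfw` and `.crs.txt` sidecars are written
#'   next to it.
#' @export
write_bandstack <- function(stack, path) {
  arr <- stack$data
  arr[is.na(arr)] <- stack$nodata
  pages <- lapply(seq_len(dim(arr)[1L]), function(b) {
    m <- arr[b, , ]
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  tr <- stack$transform
  writeLines(format(c(tr[2L], 0, 0, tr[4L], tr[1L], tr[3L]), digits = 15),
             sub("\\.tiff?$", ".tfw", path))
  writeLines(c(stack$crs, paste("nodata", stack$nodata),
               paste("source", stack$source_id)),
             sub("\\.tiff?$", ".crs.txt", path))
  invisible(path)
}

#' @rdname write_bandstack
#' @export
read_bandstack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
  for (b in seq_along(pages)) arr[b, , ] <- pages[[b]]
  tfw <- sub("\\.tiff?$", ".tfw", path)
  transform <- c(0, 10, 0, -10)
  crs <- "unknown"; nodata <- -9999; src <- basename(path)
  if (file.exists(tfw)) {
    v <- as.numeric(readLines(tfw))
    transform <- c(v[5L], v[1L], v[6L], v[4L])
  }
  crsf <- sub("\\.tiff?$", ".crs.txt", path)
  if (file.exists(crsf)) {
    ln <- readLines(crsf)
    crs <- ln[1L]
    nd <- grep("^nodata ", ln, value = TRUE)
    if (length(nd)) nodata <- as.numeric(sub("^nodata ", "", nd[1L]))
    sc <- grep("^source ", ln, value = TRUE)
    if (length(sc)) src <- sub("^source ", "", sc[1L])
  }
  arr[arr == nodata] <- NA
  band_stack(arr, transform = transform, crs = crs, nodata = nodata,
             source_id = src)
}

#' Write a single-band raster (probability plane or binary mask)
#'
#' @param plane H x W matrix.
#' @param path output `.tif` path (worldfile written alongside).
#' @param transform,crs georeferencing of the source raster.
#' @export
write_raster <- function(plane, path, transform = c(0, 10, 0, -10),
                         crs = "unknown") {
  storage.mode(plane) <- "double"
  tiff::writeTIFF(plane, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  writeLines(format(c(transform[2L], 0, 0, transform[4L],
                      transform[1L], transform[3L]), digits = 15),
             sub("\\.tiff?$", ".tfw", path))
  writeLines(crs, sub("\\.tiff?$", ".crs.txt", path))
  invisible(path)
}

#' Write / read a tile directory
#'
#' Layout: `dir/images/<id>.tif` (10-page float TIFF), `dir/masks/<id>.png`
#' (binary PNG), and `dir/manifest.csv` with one row per tile
#' (id, source, row, col, split, keep_flag, and any extra columns supplied).
#'
#' @param tiles list of tile pairs.
#' @param dir output directory (created).
#' @param split optional character vector of split labels per tile.
#' @param extra optional data frame of extra manifest columns.
#' @export
write_tile_dir <- function(tiles, dir, split = NULL, extra = NULL) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("tile_%05d", seq_along(tiles))
  rows <- integer(length(tiles)); cols <- integer(length(tiles))
  srcs <- character(length(tiles))
  for (i in seq_along(tiles)) {
    tl <- tiles[[i]]
    pages <- lapply(seq_len(dim(tl$image)[1L]), function(b) {
      m <- tl$image[b, , ]
      storage.mode(m) <- "double"
      m
    })
    tiff::writeTIFF(pages, file.path(dir, "images", paste0(ids[i], ".tif")),
                    bits.per.sample = 32L, compression = "none", reduce = FALSE)
    if (!is.null(tl$mask)) {
      msk <- tl$mask
      storage.mode(msk) <- "double"
      png::writePNG(msk, file.path(dir, "masks", paste0(ids[i], ".png")))
    }
    o <- tl$origin
    rows[i] <- if (is.null(o)) 0L else o[1L]
    cols[i] <- if (is.null(o)) 0L else o[2L]
    srcs[i] <- if (is.null(tl$source_id)) "unknown" else tl$source_id
  }
  man <- data.frame(id = ids, source = srcs, row = rows, col = cols,
                    split = if (is.null(split)) "unassigned" else split,
                    keep_flag = TRUE, stringsAsFactors = FALSE)
  if (!is.null(extra)) man <- cbind(man, extra)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_tile_dir
#' @param dir tile directory to read.
#' @export
read_tile_dir <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  tiles <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    pages <- tiff::readTIFF(file.path(dir, "images", paste0(man$id[i], ".tif")),
                            all = TRUE)
    img <- array(0, dim = c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
    for (b in seq_along(pages)) img[b, , ] <- pages[[b]]
    mp <- file.path(dir, "masks", paste0(man$id[i], ".png"))
    msk <- if (file.exists(mp)) round(png::readPNG(mp)) else NULL
    tiles[[i]] <- list(image = img, mask = msk,
                       origin = c(row = man$row[i], col = man$col[i]),
                       source_id = man$source[i], keep_flag = man$keep_flag[i],
                       split = man$split[i], id = man$id[i])
  }
  attr(tiles, "manifest") <- man
  tiles
}
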