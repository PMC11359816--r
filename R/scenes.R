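# Seeded generator of synthetic multispectral raft-aquaculture scenes.
# Floating raft aquaculture appears in Sentinel-2 imagery as regular dark
# strip grids over brighter seawater; the generator renders parametric strip
# blocks (darker than water in every band), correlated per-band water noise,
# and optional distractors (suspended-sediment blobs, cloud patches, a land
# margin) that are never labelled as raft.

# Winter coastal-water surface reflectance means per band (B2..B12) and the
# spectra used for distractors; values are plausible L2A reflectances.
.WATER_MEAN <- c(0.080, 0.070, 0.050, 0.040, 0.030, 0.025, 0.020, 0.018, 0.010, 0.008)
.LAND_MEAN <- c(0.050, 0.070, 0.080, 0.120, 0.160, 0.180, 0.200, 0.210, 0.240, 0.200)
.CLOUD_REFL <- 0.60
.SEDIMENT_BOOST <- c(0.050, 0.045, 0.040, 0.025, 0.015, 0.010, 0.008, 0.008, 0.004, 0.003)
.BAND_NOISE_CORR <- 0.8

#' Synthetic scene specification
#'
#' @param size scene extents c(H, W) in pixels.
#' @param n_blocks number of raft blocks (each a rows x cols grid of strips).
#' @param blocks optional explicit list of block descriptors (fields: center
#'   c(row, col), orientation_deg, strip_width, strip_length, spacing, rows,
#'   cols, gap_x); if NULL, blocks are sampled from the seeded RNG to fit the
#'   scene.
#' @param water_mean per-band water reflectance means.
#' @param noise_sd per-pixel reflectance noise standard deviation (shared
#'   across bands with correlation 0.8).
#' @param raft_contrast per-band multiplicative raft factor in (0, 1); rafts
#'   are strictly darker than water in every band.
#' @param sediment_blobs,sediment_intensity suspended-sediment distractors
#'   (count; peak reflectance boost scale).
#' @param cloud_patches,cloud_opacity cloud distractors (count; peak opacity).
#' @param land_fraction fraction of the left edge covered by a land margin
#'   (0 disables it).
#' @param seed RNG seed; identical specs (including seed) regenerate
#'   identical scenes.
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(size = c(64L, 64L), n_blocks = 2L, blocks = NULL,
                       water_mean = .WATER_MEAN, noise_sd = 0.01,
                       raft_contrast = rep(0.5, 10L),
                       sediment_blobs = 1L, sediment_intensity = 1,
                       cloud_patches = 0L, cloud_opacity = 0.2,
                       land_fraction = 0, seed = 1L) {
  if (any(raft_contrast <= 0) || any(raft_contrast >= 1))
    stop("raft_contrast must lie in (0, 1): rafts are darker than water")
  if (length(water_mean) != 10L || length(raft_contrast) != 10L)
    stop("water_mean and raft_contrast must have 10 bands")
  if (any(size < 8L)) stop("scene too small")
  structure(list(size = as.integer(size), n_blocks = as.integer(n_blocks),
                 blocks = blocks, water_mean = water_mean, noise_sd = noise_sd,
                 raft_contrast = raft_contrast,
                 sediment_blobs = as.integer(sediment_blobs),
                 sediment_intensity = sediment_intensity,
                 cloud_patches = as.integer(cloud_patches),
                 cloud_opacity = cloud_opacity,
                 land_fraction = land_fraction, seed = as.integer(seed)),
            class = "scene_spec")
}

# Rasterise one strip-grid block at pixel centres (no anti-aliasing); returns
# a logical H x W membership matrix. Errors if the rotated block leaves the
# scene.
.render_block <- function(blk, h, w) {
  ex <- blk$cols * (blk$strip_length + blk$gap_x) - blk$gap_x
  ey <- blk$rows * (blk$strip_width + blk$spacing) - blk$spacing
  th <- blk$orientation_deg * pi / 180
  hx <- (ex * abs(cos(th)) + ey * abs(sin(th))) / 2
  hy <- (ex * abs(sin(th)) + ey * abs(cos(th))) / 2
  if (blk$center[1L] - hy < 0 || blk$center[1L] + hy > h ||
      blk$center[2L] - hx < 0 || blk$center[2L] + hx > w)
    stop("raft block exceeds scene bounds")
  rows <- matrix(seq_len(h) - 0.5, h, w)
  cols <- matrix(seq_len(w) - 0.5, h, w, byrow = TRUE)
  dx <- cols - blk$center[2L]
  dy <- rows - blk$center[1L]
  lx <- dx * cos(th) + dy * sin(th) + ex / 2
  ly <- -dx * sin(th) + dy * cos(th) + ey / 2
  px <- blk$strip_length + blk$gap_x
  py <- blk$strip_width + blk$spacing
  inside <- lx >= 0 & lx < ex & ly >= 0 & ly < ey &
    (lx %% px) < blk$strip_length & (ly %% py) < blk$strip_width
  inside
}

.sample_block <- function(h, w) {
  for (try in 1:50) {
    blk <- list(orientation_deg = stats::runif(1, 0, 180),
                strip_width = sample(1:4, 1),
                strip_length = sample(10:20, 1),
                spacing = sample(2:5, 1),
                rows = sample(3:6, 1),
                cols = sample(1:2, 1),
                gap_x = sample(3:6, 1))
    ex <- blk$cols * (blk$strip_length + blk$gap_x) - blk$gap_x
    ey <- blk$rows * (blk$strip_width + blk$spacing) - blk$spacing
    th <- blk$orientation_deg * pi / 180
    hx <- (ex * abs(cos(th)) + ey * abs(sin(th))) / 2
    hy <- (ex * abs(sin(th)) + ey * abs(cos(th))) / 2
    if (2 * hx + 2 > w || 2 * hy + 2 > h) next
    blk$center <- c(stats::runif(1, hy + 1, h - hy - 1),
                    stats::runif(1, hx + 1, w - hx - 1))
    return(blk)
  }
  # fall back to a minimal horizontal block that always fits
  list(orientation_deg = 0, strip_width = 1L, strip_length = 10L,
       spacing = 3L, rows = 3L, cols = 1L, gap_x = 3L,
       center = c(h / 2, w / 2))
}

#' Generate a synthetic raft scene
#'
#' @param spec a [scene_spec()].
#' @return list with `stack` (a [band_stack()]), `mask` (H x W binary raft
#'   mask), `distractors` (H x W binary map of sediment/cloud/land pixels,
#'   always labelled background in `mask`), and the realised `blocks`.
#' @export
generate_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop("spec must be a scene_spec")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  h <- spec$size[1L]; w <- spec$size[2L]

  blocks <- spec$blocks
  if (is.null(blocks) && spec$n_blocks > 0L)
    blocks <- lapply(seq_len(spec$n_blocks), function(i) .sample_block(h, w))
  mask <- matrix(0L, h, w)
  for (blk in blocks) mask[.render_block(blk, h, w)] <- 1L

  # correlated per-band noise: one shared field plus band-specific residuals
  shared <- matrix(stats::rnorm(h * w), h, w)
  rho <- .BAND_NOISE_CORR
  arr <- array(0, dim = c(10L, h, w))
  land_width <- 0L
  land <- matrix(FALSE, h, w)
  if (spec$land_fraction > 0) {
    land_width <- round(spec$land_fraction * w)
    edge <- pmax(1, pmin(w, round(land_width +
      stats::filter(stats::rnorm(h, 0, 2), rep(1 / 5, 5), circular = TRUE))))
    for (r in seq_len(h)) land[r, seq_len(edge[r])] <- TRUE
  }
  sed <- matrix(0, h, w)
  if (spec$sediment_blobs > 0L) {
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (i in seq_len(spec$sediment_blobs)) {
      cy <- stats::runif(1, 1, h); cx <- stats::runif(1, 1, w)
      rad <- stats::runif(1, 4, 10)
      sed <- sed + spec$sediment_intensity *
        exp(-((rows - cy)^2 + (cols - cx)^2) / (2 * rad^2))
    }
  }
  cloud_alpha <- matrix(0, h, w)
  if (spec$cloud_patches > 0L) {
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (i in seq_len(spec$cloud_patches)) {
      cy <- stats::runif(1, 1, h); cx <- stats::runif(1, 1, w)
      rad <- stats::runif(1, 5, 12)
      cloud_alpha <- pmax(cloud_alpha, spec$cloud_opacity *
        exp(-((rows - cy)^2 + (cols - cx)^2) / (2 * rad^2)))
    }
  }

  raft <- mask == 1L
  for (b in 1:10) {
    noise <- spec$noise_sd *
      (sqrt(rho) * shared + sqrt(1 - rho) * matrix(stats::rnorm(h * w), h, w))
    plane <- spec$water_mean[b] + noise
    plane[land & !raft] <- .LAND_MEAN[b] + noise[land & !raft]
    plane <- plane + sed * .SEDIMENT_BOOST[b] * (!raft & !land)
    plane[raft] <- spec$water_mean[b] * spec$raft_contrast[b] + noise[raft]
    plane <- (1 - cloud_alpha) * plane + cloud_alpha * .CLOUD_REFL
    arr[b, , ] <- pmin(pmax(plane, 0), 1)
  }
  distractors <- (land | sed > 0.05 | cloud_alpha > 0.05) & !raft
  list(stack = band_stack(arr, source_id = sprintf("synthetic_seed%d", spec$seed)),
       mask = mask, distractors = distractors, blocks = blocks)
}

#' Generate a batch of synthetic scenes
#'
#' Samples a spec per scene from the given ranges (all draws seeded by
#' `seed`; each scene also records its own sub-seed so it can be regenerated
#' from the manifest alone).
#'
#' @param n_scenes number of scenes (>= 1).
#' @param seed master seed.
#' @param size scene extents.
#' @param n_blocks_range,contrast_range,noise_sd_range,sediment_range,cloud_range,land_prob
#'   sampling ranges of the per-scene spec fields.
#' @param dir optional directory: scenes are written in the tile-directory
#'   interchange format with the serialized spec of every scene recorded in
#'   the manifest (`spec_json` column).
#' @return list of scenes (as from [generate_scene()]), each with its `spec`;
#'   the spec table is attached as attribute `"specs"`.
#' @export
generate_dataset <- function(n_scenes, seed = 1L, size = c(64L, 64L),
                             n_blocks_range = c(1L, 3L),
                             contrast_range = c(0.4, 0.6),
                             noise_sd_range = c(0.008, 0.015),
                             sediment_range = c(0L, 2L),
                             cloud_range = c(0L, 1L),
                             land_prob = 0.25,
                             dir = NULL) {
  if (n_scenes < 1L) stop("n_scenes must be >= 1")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  specs <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    u <- stats::runif(1, contrast_range[1L], contrast_range[2L])
    specs[[i]] <- scene_spec(
      size = size,
      n_blocks = sample(n_blocks_range[1L]:n_blocks_range[2L], 1),
      noise_sd = stats::runif(1, noise_sd_range[1L], noise_sd_range[2L]),
      raft_contrast = pmin(0.95, pmax(0.05, u + stats::runif(10, -0.05, 0.05))),
      sediment_blobs = sample(sediment_range[1L]:sediment_range[2L], 1),
      cloud_patches = sample(cloud_range[1L]:cloud_range[2L], 1),
      land_fraction = if (stats::runif(1) < land_prob) stats::runif(1, 0.1, 0.25) else 0,
      seed = sample.int(.Machine$integer.max, 1))
  }
  scenes <- lapply(specs, function(sp) {
    sc <- generate_scene(sp)
    sc$spec <- sp
    sc
  })
  if (!is.null(dir)) {
    tiles <- lapply(scenes, function(sc)
      list(image = sc$stack$data, mask = sc$mask, origin = c(row = 0L, col = 0L),
           source_id = sc$stack$source_id, keep_flag = TRUE))
    spec_json <- vapply(specs, function(sp)
      as.character(jsonlite::toJSON(unclass(sp), auto_unbox = TRUE, digits = NA)),
      character(1))
    write_tile_dir(tiles, dir, extra = data.frame(spec_json = spec_json,
                                                  stringsAsFactors = FALSE))
  }
  attr(scenes, "specs") <- specs
  scenes
}

#' Recreate a scene spec from its manifest JSON record
#'
#' @param json one `spec_json` manifest entry.
#' @return a [scene_spec()].
#' @export
spec_from_json <- function(json) {
  v <- jsonlite::fromJSON(json)
  blocks <- NULL
  if (!is.null(v$blocks) && length(v$blocks))
    blocks <- lapply(seq_len(nrow(v$blocks)), function(i) as.list(v$blocks[i, ]))
  scene_spec(size = v$size, n_blocks = v$n_blocks, blocks = blocks,
             water_mean = v$water_mean, noise_sd = v$noise_sd,
             raft_contrast = v$raft_contrast, sediment_blobs = v$sediment_blobs,
             sediment_intensity = v$sediment_intensity,
             cloud_patches = v$cloud_patches, cloud_opacity = v$cloud_opacity,
             land_fraction = v$land_fraction, seed = v$seed)
}

#' Summary statistics of a generated scene
#'
#' @param stack a [band_stack()] (or bare (bands,H,W) array).
#' @param mask binary raft mask.
#' @param distractors optional distractor map; distractor pixels are excluded
#'   from the water statistics.
#' @return list: per-band raft/water means and sds, `raft_fraction`, and
#'   `block_estimate` (connected components of the mask).
#' @export
scene_statistics <- function(stack, mask, distractors = NULL) {
  arr <- if (inherits(stack, "band_stack")) stack$data else stack
  if (!all(dim(arr)[2:3] == dim(mask))) stop("stack and mask extents differ")
  raft <- mask == 1
  water <- !raft
  if (!is.null(distractors)) water <- water & !distractors
  raft_mean <- raft_sd <- water_mean <- water_sd <- rep(NA_real_, dim(arr)[1L])
  for (b in seq_len(dim(arr)[1L])) {
    plane <- arr[b, , ]
    if (any(raft)) {
      raft_mean[b] <- mean(plane[raft]); raft_sd[b] <- stats::sd(plane[raft])
    }
    water_mean[b] <- mean(plane[water]); water_sd[b] <- stats::sd(plane[water])
  }
  ncomp <- if (any(raft)) max(EBImage::bwlabel(mask)) else 0L
  list(raft_mean = raft_mean, raft_sd = raft_sd,
       water_mean = water_mean, water_sd = water_sd,
       raft_fraction = mean(raft),
       raft_defined = any(raft),
       block_estimate = as.integer(ncomp))
}
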