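# Dataset-construction pipeline: resampling, normalisation, window
# offsets/coverage, background filtering, mirror augmentation, splitting,
# stitching, and the tile-directory round trip.

ns <- asNamespace("mssfnet")

test_that("bilinear resampling doubles extents and matches closed-form weights", {
  const <- matrix(0.3, 5, 7)
  up <- resample_to_10m(const)
  expect_equal(dim(up), c(10L, 14L))
  expect_equal(max(abs(up - 0.3)), 0)
  expect_equal(dim(resample_to_10m(matrix(0, 50, 60))), c(100L, 120L))

  # 2x2 ramp: half-pixel-centre source coords s_j = (j - 0.5)/2 - 0.5 give
  # column values 0, 0.25, 0.75, 1 (edge-clamped), constant down rows
  ramp <- matrix(c(0, 0, 1, 1), 2, 2)
  up2 <- resample_to_10m(ramp)
  expected_cols <- c(0, 0.25, 0.75, 1)
  for (r in 1:4) expect_equal(up2[r, ], expected_cols, tolerance = 1e-12)
  # monotone linear interpolation between the corner values
  expect_true(all(diff(up2[1, ]) >= 0))
})

test_that("reflectance normalisation scales by 10000 and clips", {
  expect_equal(normalize_reflectance(5000), 0.5)
  expect_equal(normalize_reflectance(12000), 1.0)
  expect_equal(normalize_reflectance(0), 0.0)
  expect_equal(normalize_reflectance(-50), 0.0)
  expect_true(is.na(normalize_reflectance(NA)))
})

test_that("window offsets cover every pixel, with edge snapping", {
  expect_equal(ns$.window_offsets(1024L, 512L, 256L), c(0L, 256L, 512L))
  expect_equal(ns$.window_offsets(512L, 512L, 256L), 0L)
  expect_equal(ns$.window_offsets(1000L, 512L, 256L), c(0L, 256L, 488L))

  arr <- array(runif(10 * 96 * 80), c(10, 96, 80))
  tiles <- sliding_window_tiles(arr, window = 64L, step = 32L)
  # per axis: floor((L-64)/32)+1 regular offsets plus a snapped edge window
  # when the grid stops short: 96 -> {0, 32}; 80 -> {0} + snap {16}
  expect_length(tiles, 2 * 2)
  cover <- matrix(0L, 96, 80)
  for (tl in tiles) {
    cover[tl$origin["row"] + 1:64, tl$origin["col"] + 1:64] <-
      cover[tl$origin["row"] + 1:64, tl$origin["col"] + 1:64] + 1L
    expect_equal(dim(tl$image), c(10L, 64L, 64L))
    expect_identical(tl$image,
                     arr[, tl$origin["row"] + 1:64, tl$origin["col"] + 1:64,
                         drop = FALSE])
  }
  expect_true(all(cover >= 1L))
  expect_error(sliding_window_tiles(arr, window = 128L, step = 64L), "smaller")
})

test_that("background filtering keeps FRA tiles and replays seeded draws", {
  mk <- function(mask) list(image = array(0, c(10, 4, 4)), mask = mask,
                            origin = c(row = 0L, col = 0L), source_id = "t",
                            keep_flag = TRUE)
  fra <- mk(matrix(c(1, rep(0, 15)), 4, 4))
  bg <- mk(matrix(0, 4, 4))
  expect_length(filter_background_tiles(list(fra, bg), keep_p = 0), 1)
  expect_length(filter_background_tiles(list(bg), keep_p = 0), 0)
  keep <- matrix(1, 4, 4)
  expect_length(filter_background_tiles(list(bg), keep_region = keep), 1)

  tiles <- replicate(100, bg, simplify = FALSE)
  kept <- filter_background_tiles(tiles, keep_p = 0.2, seed = 33)
  # independent replay of the seeded draws, in tile order
  set.seed(33)
  expect_length(kept, sum(runif(100) < 0.2))
  kept2 <- filter_background_tiles(tiles, keep_p = 0.2, seed = 33)
  expect_equal(attr(kept, "decisions"), attr(kept2, "decisions"))
})

test_that("mirror augmentation quadruples tiles with exact involutions", {
  set.seed(30)
  probe <- matrix(c(1, 0, 0, 1, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  img <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  tl <- list(image = img, mask = probe, origin = c(row = 0L, col = 0L),
             source_id = "p", keep_flag = TRUE)
  out <- augment_tiles(list(tl))
  expect_length(out, 4)
  # hand-enumerated variants of the asymmetric probe
  expect_equal(out[[1]]$mask, probe)
  expect_equal(out[[2]]$mask, probe[, 3:1])
  expect_equal(out[[3]]$mask, probe[3:1, ])
  expect_equal(out[[4]]$mask, t(probe))
  # image transforms co-registered with the mask
  expect_equal(out[[2]]$image, img[, , 3:1, drop = FALSE])
  expect_equal(out[[4]]$image, aperm(img, c(1, 3, 2)))
  # flips are involutions
  expect_identical(ns$.flip_h(ns$.flip_h(tl)), tl)
  expect_identical(ns$.flip_v(ns$.flip_v(tl)), tl)
  expect_identical(ns$.transpose_tile(ns$.transpose_tile(tl)), tl)
  # the four variants are closed under the dihedral operations used
  masks <- lapply(out, `[[`, "mask")
  expect_equal(length(unique(lapply(masks, as.vector))), 4)
})

test_that("splitting follows the floor/remainder rule deterministically", {
  sm <- split_dataset(10072, seed = 1)
  expect_length(sm$train, 7051)
  expect_length(sm$test, 2014)
  expect_length(sm$validation, 1007)
  expect_equal(sort(c(sm$train, sm$test, sm$validation)), 1:10072)

  sm10 <- split_dataset(10, seed = 2)
  expect_equal(vapply(sm10[c("train", "test", "validation")], length,
                      integer(1)),
               c(train = 7L, test = 2L, validation = 1L))
  expect_error(split_dataset(9), "at least 10")

  set.seed(31)
  for (i in 1:100) {
    n <- sample(10:5000, 1)
    sm_i <- split_dataset(n, seed = i)
    expect_equal(length(sm_i$train) + length(sm_i$test) + length(sm_i$validation), n)
  }
  expect_identical(split_dataset(500, seed = 9), split_dataset(500, seed = 9))
  a <- split_dataset(500, seed = 9); b <- split_dataset(500, seed = 10)
  expect_false(identical(a$test, b$test))
  expect_equal(length(a$test), length(b$test))
})

test_that("stitching averages overlaps and reconstructs consistent fields", {
  # single tile covering the raster: identity
  p <- matrix(runif(64 * 64), 64, 64)
  expect_equal(stitch_predictions(list(p), list(c(0L, 0L)), c(64L, 64L)), p)

  # two half-overlapping constant tiles: overlap is the mean
  t1 <- matrix(0.2, 4, 4); t2 <- matrix(0.8, 4, 4)
  st <- stitch_predictions(list(t1, t2), list(c(0L, 0L), c(0L, 2L)), c(4L, 6L))
  expect_equal(st[, 1:2], matrix(0.2, 4, 2))
  expect_equal(st[, 3:4], matrix(0.5, 4, 2))
  expect_equal(st[, 5:6], matrix(0.8, 4, 2))

  # random tiling of a known plane where every tile reports the truth
  set.seed(32)
  truth <- matrix(runif(100 * 90), 100, 90)
  probs <- list(); origins <- list()
  for (r0 in ns$.window_offsets(100L, 32L, 16L))
    for (c0 in ns$.window_offsets(90L, 32L, 16L)) {
      probs[[length(probs) + 1]] <- truth[r0 + 1:32, c0 + 1:32]
      origins[[length(origins) + 1]] <- c(r0, c0)
    }
  expect_equal(stitch_predictions(probs, origins, c(100L, 90L)), truth,
               tolerance = 1e-12)
  expect_error(stitch_predictions(list(t1), list(c(0L, 0L)), c(10L, 10L)),
               "uncovered")
})

test_that("band stacks and tile directories round-trip on disk", {
  set.seed(34)
  arr <- array(runif(10 * 20 * 24), c(10, 20, 24))
  st <- band_stack(arr, transform = c(500000, 10, 4300000, -10),
                   crs = "EPSG:32651", source_id = "fixture")
  tif <- tempfile(fileext = ".tif")
  write_bandstack(st, tif)
  st2 <- read_bandstack(tif)
  expect_equal(st2$data, arr, tolerance = 1e-6)     # float32 on disk
  expect_equal(st2$transform, st$transform)
  expect_equal(st2$crs, "EPSG:32651")

  tiles <- sliding_window_tiles(st, mask = matrix(rbinom(20 * 24, 1, 0.3), 20, 24),
                                window = 16L, step = 8L)
  dir <- tempfile("tiledir")
  write_tile_dir(tiles, dir, split = rep("train", length(tiles)))
  back <- read_tile_dir(dir)
  expect_length(back, length(tiles))
  expect_equal(back[[3]]$image, tiles[[3]]$image, tolerance = 1e-6)
  expect_equal(back[[3]]$mask, tiles[[3]]$mask)
  expect_equal(back[[3]]$origin, tiles[[3]]$origin)
})
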