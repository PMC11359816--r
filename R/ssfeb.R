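# Spatial-spectral feature extraction block (SSFEB).
#
# The spectral branch permutes the (batch, channels, height, width) feature
# map so that the original width axis becomes the grouping ("channel") axis
# and depthwise kernels slide over the (height, original-channels) plane: a
# 1 x k kernel then spans k spectral channels and a k x 1 kernel spans k
# image rows, which is what makes the branch a spectral-correlation
# extractor. The spatial branch is a 1x1 -> depthwise 3x3 -> 1x1 bottleneck.
# Block output = spectral branch + spatial branch + input (pure residual).

#' SSFEB configuration
#'
#' @param spectral_kernel odd length of the long spectral kernels (1 x k and
#'   k x 1 depthwise convolutions).
#' @param split_count number of sub-maps the permuted map is split into along
#'   the grouping axis; each gets its own depthwise kernel shape.
#' @param spatial_reduction channel reduction ratio of the spatial bottleneck.
#' @param mlp_expansion expansion factor of the two-layer perceptron applied
#'   after the spectral concatenation.
#' @return a list of class `ssfeb_config`.
#' @export
ssfeb_config <- function(spectral_kernel = 11L, split_count = 3L,
                         spatial_reduction = 4L, mlp_expansion = 4L) {
  if (spectral_kernel %% 2L != 1L) stop("spectral_kernel must be odd")
  if (split_count < 1L) stop("split_count must be >= 1")
  structure(list(spectral_kernel = as.integer(spectral_kernel),
                 split_count = as.integer(split_count),
                 spatial_reduction = as.integer(spatial_reduction),
                 mlp_expansion = as.integer(mlp_expansion)),
            class = "ssfeb_config")
}

#' Permute a feature map for spectral-domain processing
#'
#' Exchanges the channel and width axes of a (batch, channels, height, width)
#' feature map, so the original width becomes the grouping axis and the plane
#' seen by subsequent depthwise kernels is (height, original channels). The
#' operation is its own inverse.
#'
#' @param x feature map, (b, c, h, w) array.
#' @return the permuted array, (b, w, h, c).
#' @export
permute_spectral <- function(x) {
  check_fmap(x)
  aperm(x, c(1L, 4L, 3L, 2L))
}

#' @rdname permute_spectral
#' @export
unpermute_spectral <- permute_spectral

#' Split a feature map into equal groups along the channel axis
#'
#' @param xp feature map (typically the spectrally permuted map).
#' @param n number of groups.
#' @param pad if `TRUE` and the grouping-axis extent is not divisible by `n`,
#'   zero-pad it up to the next multiple (padded positions are recorded in the
#'   `"padded_positions"` attribute of the result); if `FALSE`, error.
#' @return list of `n` feature maps of equal grouping-axis extent.
#' @export
split_groups <- function(xp, n, pad = FALSE) {
  check_fmap(xp)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  w <- dim(xp)[2L]
  padded <- integer(0)
  if (w %% n != 0L) {
    if (!pad)
      stop(sprintf(
        "grouping axis extent %d is not divisible by %d groups (enable pad)", w, n))
    wp <- as.integer(ceiling(w / n) * n)
    padded <- (w + 1L):wp
    xp <- pad_channels(xp, wp)
    w <- wp
  }
  out <- split_channels(xp, rep(w %/% n, n))
  attr(out, "padded_positions") <- padded
  out
}

#' Build an SSFEB
#'
#' The spectral branch's depthwise filter count equals the feature-map width,
#' so `width` is a build-time constant: a block only accepts inputs of the
#' width it was built for.
#'
#' @param channels input/output channel count.
#' @param width feature-map width at this stage.
#' @param cfg an [ssfeb_config()].
#' @return an SSFEB module list.
#' @export
ssfeb_new <- function(channels, width, cfg = ssfeb_config()) {
  channels <- as.integer(channels)
  width <- as.integer(width)
  if (channels %% cfg$spatial_reduction != 0L)
    stop(sprintf("channels (%d) must be divisible by spatial_reduction (%d)",
                 channels, cfg$spatial_reduction))
  wp <- as.integer(ceiling(width / cfg$split_count) * cfg$split_count)
  gs <- wp %/% cfg$split_count
  k <- cfg$spectral_kernel
  e <- cfg$mlp_expansion
  cr <- channels %/% cfg$spatial_reduction
  list(kind = "ssfeb", cfg = cfg, channels = channels, width = width, wp = wp,
       spe = list(
         dw1 = conv_new(gs, gs, 3L, 3L, groups = gs),
         dw2 = conv_new(gs, gs, 1L, k, groups = gs),
         dw3 = conv_new(gs, gs, k, 1L, groups = gs),
         bn = bn_new(wp),
         mlp1 = conv_new(wp, wp * e, 1L, 1L),
         mlp2 = conv_new(wp * e, wp, 1L, 1L)),
       spa = list(
         red = conv_new(channels, cr, 1L, 1L),
         dw = conv_new(cr, cr, 3L, 3L, groups = cr),
         exp = conv_new(cr, channels, 1L, 1L)))
}

.spefeb_fw <- function(mod, x, training) {
  n <- mod$cfg$split_count
  xp <- permute_spectral(x)
  parts <- split_groups(xp, n, pad = TRUE)
  c1 <- conv_fw(mod$spe$dw1, parts[[1L]])
  c2 <- conv_fw(mod$spe$dw2, parts[[2L]])
  c3 <- conv_fw(mod$spe$dw3, parts[[3L]])
  f <- cat_channels(list(c1$y, c2$y, c3$y))
  bnr <- bn_fw(mod$spe$bn, f, training)
  mod$spe$bn <- bnr$mod
  m1 <- conv_fw(mod$spe$mlp1, bnr$y)
  ge <- gelu_fw(m1$y)
  m2 <- conv_fw(mod$spe$mlp2, ge$y)
  yc <- m2$y[, seq_len(mod$width), , , drop = FALSE]
  list(y = unpermute_spectral(yc), mod = mod,
       cache = list(c1 = c1$cache, c2 = c2$cache, c3 = c3$cache,
                    bn = bnr$cache, m1 = m1$cache, ge = ge$cache,
                    m2 = m2$cache, d = dim(x)))
}

.spefeb_bw <- function(mod, cache, gy) {
  gyc <- permute_spectral(gy)                     # (b, W, h, C)
  gm2y <- pad_channels(gyc, mod$wp)               # padded columns get zero grad
  b2 <- conv_bw(mod$spe$mlp2, cache$m2, gm2y)
  gge <- gelu_bw(cache$ge, b2$gx)
  b1 <- conv_bw(mod$spe$mlp1, cache$m1, gge)
  bbn <- bn_bw(mod$spe$bn, cache$bn, b1$gx)
  gs <- mod$wp %/% mod$cfg$split_count
  gparts <- split_channels(bbn$gx, rep(gs, 3L))
  g1 <- conv_bw(mod$spe$dw1, cache$c1, gparts[[1L]])
  g2 <- conv_bw(mod$spe$dw2, cache$c2, gparts[[2L]])
  g3 <- conv_bw(mod$spe$dw3, cache$c3, gparts[[3L]])
  gxp <- cat_channels(list(g1$gx, g2$gx, g3$gx))
  gxp <- gxp[, seq_len(mod$width), , , drop = FALSE]  # drop padding grad
  list(gx = unpermute_spectral(gxp),
       g = list(dw1 = g1$g, dw2 = g2$g, dw3 = g3$g, bn = bbn$g,
                mlp1 = b1$g, mlp2 = b2$g))
}

.spafeb_fw <- function(mod, x) {
  r <- conv_fw(mod$spa$red, x)
  d <- conv_fw(mod$spa$dw, r$y)
  e <- conv_fw(mod$spa$exp, d$y)
  list(y = e$y, cache = list(r = r$cache, d = d$cache, e = e$cache))
}

.spafeb_bw <- function(mod, cache, gy) {
  be <- conv_bw(mod$spa$exp, cache$e, gy)
  bd <- conv_bw(mod$spa$dw, cache$d, be$gx)
  br <- conv_bw(mod$spa$red, cache$r, bd$gx)
  list(gx = br$gx, g = list(red = br$g, dw = bd$g, exp = be$g))
}

.ssfeb_fw <- function(mod, x, training = FALSE) {
  spe <- .spefeb_fw(mod, x, training)
  mod <- spe$mod
  spa <- .spafeb_fw(mod, x)
  list(y = spe$y + spa$y + x, mod = mod,
       cache = list(spe = spe$cache, spa = spa$cache))
}

.ssfeb_bw <- function(mod, cache, gy) {
  bspe <- .spefeb_bw(mod, cache$spe, gy)
  bspa <- .spafeb_bw(mod, cache$spa, gy)
  list(gx = gy + bspe$gx + bspa$gx,
       g = list(spe = bspe$g, spa = bspa$g))
}

#' Spectral branch of an SSFEB
#'
#' Permutes the input, splits the grouping axis into `split_count` groups,
#' applies per-group depthwise convolutions (3x3, 1xk, kx1), concatenates,
#' applies batch normalisation and a two-layer GeLU perceptron, then restores
#' the original layout. Output shape equals input shape.
#'
#' @param block an SSFEB built by [ssfeb_new()].
#' @param x feature map with the block's channel count and width.
#' @param training use batch statistics (TRUE) or running statistics (FALSE)
#'   in the normalisation.
#' @return feature map with the same extents as `x`.
#' @export
spefeb_forward <- function(block, x, training = FALSE) {
  .check_ssfeb_input(block, x)
  .spefeb_fw(block, x, training)$y
}

#' Spatial bottleneck branch of an SSFEB
#'
#' 1x1 channel reduction, depthwise 3x3, 1x1 channel restoration.
#'
#' @inheritParams spefeb_forward
#' @return feature map with the same extents as `x`.
#' @export
spafeb_forward <- function(block, x) {
  .check_ssfeb_input(block, x)
  .spafeb_fw(block, x)$y
}

#' SSFEB forward pass
#'
#' Element-wise sum of the spectral branch, the spatial branch, and the input.
#'
#' @inheritParams spefeb_forward
#' @return feature map with the same extents as `x`.
#' @export
ssfeb_forward <- function(block, x, training = FALSE) {
  .check_ssfeb_input(block, x)
  .ssfeb_fw(block, x, training)$y
}

.check_ssfeb_input <- function(block, x) {
  check_fmap(x)
  if (dim(x)[2L] != block$channels)
    stop(sprintf("expected %d channels, got %d", block$channels, dim(x)[2L]))
  if (dim(x)[4L] != block$width)
    stop(sprintf(
      "SSFEB was built for width %d but input width is %d (the spectral branch has one depthwise filter per width position)",
      block$width, dim(x)[4L]))
  invisible(x)
}
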