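# Encoder-decoder assembly: ResNet18-shaped encoder whose residual blocks are
# SSFEBs, a multiscale attention block at the 1/32 bottleneck, and a UNet-style
# decoder with bilinear upsampling and skip connections, ending in a 1x1
# convolution + sigmoid probability head.

#' Network configuration
#'
#' @param in_bands input channel count (10 Sentinel-2 bands by default:
#'   B2,B3,B4,B5,B6,B7,B8,B8A,B11,B12 at 10 m).
#' @param stage_widths encoder channel widths of the four stages.
#' @param blocks_per_stage SSFEBs per encoder stage.
#' @param tile_size input tile side; must be divisible by 32 (five 2x
#'   reductions). The spectral branches are built for this fixed size.
#' @param decoder_widths decoder channel widths (deepest first).
#' @param width_multiplier multiplies all widths (use < 1 for desk-scale
#'   models); widths are rounded and floored at 1.
#' @param ssfeb,msab branch configurations.
#' @return a list of class `network_config`.
#' @export
network_config <- function(in_bands = 10L,
                           stage_widths = c(64L, 128L, 256L, 512L),
                           blocks_per_stage = 2L,
                           tile_size = 512L,
                           decoder_widths = c(256L, 128L, 64L, 32L),
                           width_multiplier = 1,
                           ssfeb = ssfeb_config(),
                           msab = msab_config()) {
  if (tile_size %% 32L != 0L)
    stop("invalid config field tile_size: must be divisible by 32")
  if (length(stage_widths) != 4L || any(diff(stage_widths) <= 0))
    stop("invalid config field stage_widths: need 4 strictly increasing widths")
  if (length(decoder_widths) != 4L)
    stop("invalid config field decoder_widths: need 4 widths")
  if (in_bands < 1L) stop("invalid config field in_bands")
  if (blocks_per_stage < 1L) stop("invalid config field blocks_per_stage")
  if (width_multiplier <= 0) stop("invalid config field width_multiplier")
  scale_w <- function(w) {
    w <- pmax(1L, as.integer(round(w * width_multiplier)))
    # keep widths compatible with the spatial bottleneck reduction
    r <- ssfeb$spatial_reduction
    pmax(r, (w %/% r) * r)
  }
  structure(list(in_bands = as.integer(in_bands),
                 stage_widths = scale_w(stage_widths),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 tile_size = as.integer(tile_size),
                 decoder_widths = pmax(1L, as.integer(round(decoder_widths * width_multiplier))),
                 width_multiplier = width_multiplier,
                 ssfeb = ssfeb, msab = msab),
            class = "network_config")
}

#' Build a segmentation model
#'
#' Deterministically initialises all parameters (He-uniform convolution
#' weights, zero biases, unit/zero normalisation parameters) from `seed`.
#'
#' @param cfg a [network_config()].
#' @param seed integer seed controlling initialisation.
#' @return a `segmentation_model` list: `$config`, module tree, and
#'   bookkeeping fields.
#' @export
build_model <- function(cfg = network_config(), seed = 1L) {
  if (!inherits(cfg, "network_config")) stop("cfg must be a network_config")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  sw <- cfg$stage_widths
  # spatial sides of the four stages (post stem+pool = /4, then /8 /16 /32)
  sides <- cfg$tile_size %/% c(4L, 8L, 16L, 32L)
  stages <- vector("list", 4L)
  for (s in 1:4)
    stages[[s]] <- lapply(seq_len(cfg$blocks_per_stage), function(i)
      ssfeb_new(sw[s], sides[s], cfg$ssfeb))
  downs <- lapply(1:3, function(s)
    conv_new(sw[s], sw[s + 1L], 1L, 1L, stride = 2L, pad = c(0L, 0L)))

  dw <- cfg$decoder_widths
  skip_ch <- c(sw[3L], sw[2L], sw[1L], sw[1L])   # stage3, stage2, stage1, stem
  in_ch <- c(sw[4L], dw[1L], dw[2L], dw[3L])
  dec <- vector("list", 4L)
  for (l in 1:4)
    dec[[l]] <- list(
      conv1 = conv_new(in_ch[l] + skip_ch[l], dw[l], 3L, 3L),
      bn1 = bn_new(dw[l]),
      conv2 = conv_new(dw[l], dw[l], 3L, 3L),
      bn2 = bn_new(dw[l]))

  model <- list(
    kind = "net", config = cfg, training_state = FALSE,
    stem = conv_new(cfg$in_bands, sw[1L], 7L, 7L, stride = 2L),
    stem_bn = bn_new(sw[1L]),
    stages = stages, downs = downs,
    msab = msab_new(sw[4L], cfg$msab),
    decoder = dec,
    head = conv_new(dw[4L], 1L, 1L, 1L))
  class(model) <- "segmentation_model"
  model
}

.net_fw <- function(model, x, training = FALSE) {
  cfg <- model$config
  d <- dim(x)
  if (d[2L] != cfg$in_bands)
    stop(sprintf("expected %d input bands, got %d", cfg$in_bands, d[2L]))
  if (d[3L] != cfg$tile_size || d[4L] != cfg$tile_size)
    stop(sprintf("model was built for %dx%d tiles, got %dx%d",
                 cfg$tile_size, cfg$tile_size, d[3L], d[4L]))
  cache <- list()
  st <- conv_fw(model$stem, x); cache$stem <- st$cache
  sb <- bn_fw(model$stem_bn, st$y, training)
  model$stem_bn <- sb$mod; cache$stem_bn <- sb$cache
  sa <- relu_fw(sb$y); cache$stem_act <- sa$cache
  x_stem <- sa$y                                   # /2, sw1 (conv-BN-ReLU stem)
  mp <- maxpool_fw(x_stem); cache$pool <- mp$cache
  h <- mp$y                                        # /4
  skips <- vector("list", 3L)
  cache$stages <- vector("list", 4L)
  cache$downs <- vector("list", 3L)
  for (s in 1:4) {
    blocks <- model$stages[[s]]
    bc <- vector("list", length(blocks))
    for (i in seq_along(blocks)) {
      r <- .ssfeb_fw(blocks[[i]], h, training)
      model$stages[[s]][[i]] <- r$mod
      bc[[i]] <- r$cache
      h <- r$y
    }
    cache$stages[[s]] <- bc
    if (s < 4L) {
      skips[[s]] <- h
      dn <- conv_fw(model$downs[[s]], h)
      cache$downs[[s]] <- dn$cache
      h <- dn$y
    }
  }
  ms <- .msab_fw(model$msab, h, training)
  model$msab <- ms$mod; cache$msab <- ms$cache
  h <- ms$y

  skip_maps <- list(skips[[3L]], skips[[2L]], skips[[1L]], x_stem)
  cache$dec <- vector("list", 4L)
  cache$skip_ch <- vapply(skip_maps, function(s) dim(s)[2L], integer(1))
  for (l in 1:4) {
    up <- upsample2x_fw(h)
    hcat <- cat_channels(list(up$y, skip_maps[[l]]))
    c1 <- conv_fw(model$decoder[[l]]$conv1, hcat)
    b1 <- bn_fw(model$decoder[[l]]$bn1, c1$y, training)
    model$decoder[[l]]$bn1 <- b1$mod
    a1 <- relu_fw(b1$y)
    c2 <- conv_fw(model$decoder[[l]]$conv2, a1$y)
    b2 <- bn_fw(model$decoder[[l]]$bn2, c2$y, training)
    model$decoder[[l]]$bn2 <- b2$mod
    a2 <- relu_fw(b2$y)
    cache$dec[[l]] <- list(up = up$cache, c1 = c1$cache, b1 = b1$cache,
                           a1 = a1$cache, c2 = c2$cache, b2 = b2$cache,
                           a2 = a2$cache, up_ch = dim(up$y)[2L])
    h <- a2$y
  }
  uph <- upsample2x_fw(h); cache$head_up <- uph$cache
  hd <- conv_fw(model$head, uph$y); cache$head <- hd$cache
  sg <- sigmoid_fw(hd$y); cache$sig <- sg$cache
  list(y = sg$y, mod = model, cache = cache)
}

.net_bw <- function(model, cache, gy) {
  g <- list()
  gh <- sigmoid_bw(cache$sig, gy)
  bh <- conv_bw(model$head, cache$head, gh)
  g$head <- bh$g
  gh <- upsample2x_bw(cache$head_up, bh$gx)

  gskips <- vector("list", 4L)
  g$decoder <- vector("list", 4L)
  for (l in 4:1) {
    dc <- cache$dec[[l]]
    ga2 <- relu_bw(dc$a2, gh)
    bb2 <- bn_bw(model$decoder[[l]]$bn2, dc$b2, ga2)
    bc2 <- conv_bw(model$decoder[[l]]$conv2, dc$c2, bb2$gx)
    ga1 <- relu_bw(dc$a1, bc2$gx)
    bb1 <- bn_bw(model$decoder[[l]]$bn1, dc$b1, ga1)
    bc1 <- conv_bw(model$decoder[[l]]$conv1, dc$c1, bb1$gx)
    parts <- split_channels(bc1$gx, c(dc$up_ch, cache$skip_ch[l]))
    gskips[[l]] <- parts[[2L]]
    gh <- upsample2x_bw(dc$up, parts[[1L]])
    g$decoder[[l]] <- list(conv1 = bc1$g, bn1 = bb1$g, conv2 = bc2$g, bn2 = bb2$g)
  }

  bms <- .msab_bw(model$msab, cache$msab, gh)
  g$msab <- bms$g
  gh <- bms$gx
  g$stages <- vector("list", 4L)
  g$downs <- vector("list", 3L)
  for (s in 4:1) {
    if (s < 4L) {
      bdn <- conv_bw(model$downs[[s]], cache$downs[[s]], gh)
      g$downs[[s]] <- bdn$g
      gh <- bdn$gx + gskips[[4L - s]]   # skip l: 1->stage3, 2->stage2, 3->stage1
    }
    blocks <- model$stages[[s]]
    gb <- vector("list", length(blocks))
    for (i in rev(seq_along(blocks))) {
      r <- .ssfeb_bw(blocks[[i]], cache$stages[[s]][[i]], gh)
      gb[[i]] <- r$g
      gh <- r$gx
    }
    g$stages[[s]] <- gb
  }
  gh <- maxpool_bw(cache$pool, gh)
  gh <- gh + gskips[[4L]]               # stem skip
  gh <- relu_bw(cache$stem_act, gh)
  bsb <- bn_bw(model$stem_bn, cache$stem_bn, gh)
  g$stem_bn <- bsb$g
  bst <- conv_bw(model$stem, cache$stem, bsb$gx)
  g$stem <- bst$g
  list(gx = bst$gx, g = g)
}

#' Run the model forward
#'
#' @param model a `segmentation_model` from [build_model()].
#' @param x input tiles, (b, in_bands, tile_size, tile_size) array.
#' @param training training mode (batch statistics in normalisation layers).
#' @return probability map, (b, 1, tile_size, tile_size) array in [0, 1].
#' @export
model_forward <- function(model, x, training = FALSE) {
  check_fmap(x)
  .net_fw(model, x, training)$y
}

#' Count scalar parameters of a model
#'
#' @param model a `segmentation_model`.
#' @return total number of trainable scalar parameters.
#' @export
count_parameters <- function(model) {
  sum(vapply(collect_params(model), length, integer(1)))
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds the configuration, all parameter and buffer arrays,
#' optimizer state, epoch/step counters and the RNG state, so training is
#' fully resumable. A plain-text sidecar (`<path>.meta.txt`) records the
#' format version and band order.
#'
#' @param model a `segmentation_model`.
#' @param path file path.
#' @param opt optional optimizer state.
#' @param epoch,step training progress counters.
#' @param rng RNG state (`.Random.seed`).
#' @param log training log data frame.
#' @export
save_checkpoint <- function(model, path, opt = NULL, epoch = 0L, step = 0L,
                            rng = NULL, log = NULL) {
  saveRDS(list(model = model, opt = opt, epoch = epoch, step = step,
               rng = rng, log = log), path)
  writeLines(c("mssfnet-checkpoint 1",
               paste("bands", "B2,B3,B4,B5,B6,B7,B8,B8A,B11,B12"),
               paste("epoch", epoch), paste("step", step)),
             paste0(path, ".meta.txt"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
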