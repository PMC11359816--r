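# Training loop (Adam, cosine annealing, BCE+Dice), pooled evaluation, and
# whole-raster prediction with overlap stitching.

#' Cosine-annealed learning rate
#'
#' `lr_min + 0.5 (lr0 - lr_min) (1 + cos(pi * step / total_steps))`:
#' exactly `lr0` at step 0 and `lr_min` at the final step.
#'
#' @param step current step in `[0, total_steps]`.
#' @param total_steps schedule length (> 0).
#' @param lr0 initial learning rate.
#' @param lr_min floor learning rate.
#' @return learning rate at `step`.
#' @export
cosine_lr <- function(step, total_steps, lr0 = 1e-4, lr_min = 0) {
  if (total_steps <= 0) stop("total_steps must be > 0")
  if (step < 0 || step > total_steps) stop("step must lie in [0, total_steps]")
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * step / total_steps))
}

#' Training configuration
#'
#' Defaults follow the full-scale recipe (Adam, batch 8, initial lr 1e-4,
#' cosine annealing to 0, 50 epochs, online random scaling / shear warping /
#' flips / contrast augmentation).
#'
#' @param lr0,lr_min initial / floor learning rate.
#' @param batch_size tiles per optimisation step.
#' @param epochs training epochs.
#' @param betas,weight_decay Adam hyperparameters.
#' @param augment enable online augmentation.
#' @param scale_range,shear_max_deg,flip_p,contrast_range augmentation
#'   parameter ranges (scaling factor; shear angle in degrees; per-axis flip
#'   probability; uniform per-tile contrast gain applied to all bands).
#' @param dice_smooth,bce_clamp loss constants.
#' @param seed training seed (shuffling, augmentation).
#' @param checkpoint_dir optional directory for best/last checkpoints.
#' @param log_csv optional CSV path for the epoch log.
#' @param verbose print one structured log line per epoch.
#' @return list of class `train_config`.
#' @export
train_config <- function(lr0 = 1e-4, lr_min = 0, batch_size = 8L, epochs = 50L,
                         betas = c(0.9, 0.999), weight_decay = 0,
                         augment = TRUE, scale_range = c(0.75, 1.25),
                         shear_max_deg = 5, flip_p = 0.5,
                         contrast_range = c(0.8, 1.2),
                         dice_smooth = 1.0, bce_clamp = 1e-7, seed = 1L,
                         checkpoint_dir = NULL, log_csv = NULL,
                         verbose = FALSE) {
  if (lr0 <= 0) stop("lr0 must be > 0")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(lr0 = lr0, lr_min = lr_min, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), betas = betas,
                 weight_decay = weight_decay, augment = augment,
                 scale_range = scale_range, shear_max_deg = shear_max_deg,
                 flip_p = flip_p, contrast_range = contrast_range,
                 dice_smooth = dice_smooth, bce_clamp = bce_clamp,
                 seed = as.integer(seed), checkpoint_dir = checkpoint_dir,
                 log_csv = log_csv, verbose = isTRUE(verbose)),
            class = "train_config")
}

# Affine warp (scale + shear about the tile centre) with edge-clamped
# bilinear sampling for the image and nearest-neighbour for the mask.
.affine_warp_tile <- function(img, msk, scale, shear_deg) {
  h <- dim(img)[2L]; w <- dim(img)[3L]
  sh <- tan(shear_deg * pi / 180)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rows <- matrix(seq_len(h), h, w) - cy
  cols <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  # inverse map: output pixel -> source location
  sr <- rows / scale + cy
  sc <- (cols - sh * rows) / scale + cx
  sr <- pmin(pmax(sr, 1), h); sc <- pmin(pmax(sc, 1), w)
  r0 <- pmin(floor(sr), h - 1); c0 <- pmin(floor(sc), w - 1)
  fr <- sr - r0; fc <- sc - c0
  i00 <- cbind(as.vector(r0), as.vector(c0))
  i10 <- cbind(as.vector(r0 + 1), as.vector(c0))
  i01 <- cbind(as.vector(r0), as.vector(c0 + 1))
  i11 <- cbind(as.vector(r0 + 1), as.vector(c0 + 1))
  wv <- list(as.vector((1 - fr) * (1 - fc)), as.vector(fr * (1 - fc)),
             as.vector((1 - fr) * fc), as.vector(fr * fc))
  for (b in seq_len(dim(img)[1L])) {
    p <- img[b, , ]
    img[b, , ] <- matrix(p[i00] * wv[[1L]] + p[i10] * wv[[2L]] +
                           p[i01] * wv[[3L]] + p[i11] * wv[[4L]], h, w)
  }
  rn <- cbind(as.vector(round(sr)), as.vector(round(sc)))
  msk <- matrix(msk[rn], h, w)
  list(image = img, mask = msk)
}

.augment_online <- function(img, msk, cfg) {
  if (stats::runif(1) < cfg$flip_p) {
    img <- img[, , rev(seq_len(dim(img)[3L])), drop = FALSE]
    msk <- msk[, rev(seq_len(ncol(msk)))]
  }
  if (stats::runif(1) < cfg$flip_p) {
    img <- img[, rev(seq_len(dim(img)[2L])), , drop = FALSE]
    msk <- msk[rev(seq_len(nrow(msk))), ]
  }
  sc <- stats::runif(1, cfg$scale_range[1L], cfg$scale_range[2L])
  sh <- stats::runif(1, -cfg$shear_max_deg, cfg$shear_max_deg)
  if (abs(sc - 1) > 1e-8 || abs(sh) > 1e-8) {
    wr <- .affine_warp_tile(img, msk, sc, sh)
    img <- wr$image; msk <- round(wr$mask)
  }
  gain <- stats::runif(1, cfg$contrast_range[1L], cfg$contrast_range[2L])
  img <- pmin(pmax(img * gain, 0), 1)
  list(image = img, mask = msk)
}

.batch_arrays <- function(tiles, idx, cfg = NULL) {
  b <- length(idx)
  d <- dim(tiles[[idx[1L]]]$image)
  x <- array(0, dim = c(b, d[1L], d[2L], d[3L]))
  y <- array(0, dim = c(b, 1L, d[2L], d[3L]))
  for (i in seq_len(b)) {
    tl <- tiles[[idx[i]]]
    img <- tl$image; msk <- tl$mask
    if (!is.null(cfg) && isTRUE(cfg$augment)) {
      au <- .augment_online(img, msk, cfg)
      img <- au$image; msk <- au$mask
    }
    x[i, , , ] <- img
    y[i, 1L, , ] <- msk
  }
  list(x = x, y = y)
}

#' Train a segmentation model
#'
#' Minimises the equally weighted BCE + Dice loss with Adam and per-step
#' cosine annealing; logs per-epoch training loss and validation metrics;
#' optionally saves best-validation-IoU and last checkpoints. Training is
#' fully seeded and resumable (optimizer and RNG state live in the
#' checkpoint).
#'
#' @param model a `segmentation_model` (or checkpoint list to resume from).
#' @param train_tiles,val_tiles lists of tile pairs (image + mask).
#' @param cfg a [train_config()].
#' @param stop_after optional epoch to pause at (the cosine schedule still
#'   spans `cfg$epochs`); resume by passing the saved checkpoint as `model`.
#' @return list: trained `model`, `log` (epoch, step, lr, train_loss,
#'   val_IoU, val_F1), `opt`, `best_iou`.
#' @export
train_model <- function(model, train_tiles, val_tiles = NULL,
                        cfg = train_config(), stop_after = NULL) {
  if (length(train_tiles) == 0L) stop("empty training set")
  resume <- !inherits(model, "segmentation_model")
  if (resume) {
    ck <- model
    model <- ck$model
    opt <- ck$opt
    start_epoch <- ck$epoch
    gstep <- ck$step
    log <- ck$log
    if (!is.null(ck$rng)) assign(".Random.seed", ck$rng, .GlobalEnv)
  } else {
    set.seed(cfg$seed)
    opt <- adam_new(collect_params(model), beta1 = cfg$betas[1L],
                    beta2 = cfg$betas[2L], weight_decay = cfg$weight_decay)
    start_epoch <- 0L
    gstep <- 0L
    log <- NULL
  }
  if (start_epoch >= cfg$epochs)
    return(list(model = model, log = log, opt = opt,
                best_iou = if (is.null(log)) -Inf else suppressWarnings(max(log$val_IoU, na.rm = TRUE))))
  nb <- max(1L, length(train_tiles) %/% cfg$batch_size)
  total_steps <- cfg$epochs * nb
  best_iou <- if (is.null(log) || !nrow(log)) -Inf else
    suppressWarnings(max(log$val_IoU, na.rm = TRUE))

  for (epoch in (start_epoch + 1L):cfg$epochs) {
    ord <- sample(length(train_tiles))
    ep_loss <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size,
                                                       length(train_tiles))]
      ba <- .batch_arrays(train_tiles, idx, cfg)
      fw <- .net_fw(model, ba$x, training = TRUE)
      model <- fw$mod
      loss <- combined_loss(fw$y, ba$y, cfg$dice_smooth, cfg$bce_clamp)
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d step %d", epoch, gstep))
      gy <- combined_loss_grad(fw$y, ba$y, cfg$dice_smooth, cfg$bce_clamp)
      dim(gy) <- dim(fw$y)
      bw <- .net_bw(model, fw$cache, gy)
      lr <- cosine_lr(gstep, total_steps, cfg$lr0, cfg$lr_min)
      st <- adam_step(opt, collect_params(model), collect_params(bw$g), lr)
      opt <- st$opt
      model <- set_params(model, st$params)
      gstep <- gstep + 1L
      ep_loss <- ep_loss + loss
    }
    ep_loss <- ep_loss / nb
    val_iou <- NA_real_; val_f1 <- NA_real_
    if (!is.null(val_tiles) && length(val_tiles)) {
      ev <- evaluate_model(model, val_tiles)
      val_iou <- ev$metrics$IoU; val_f1 <- ev$metrics$F1
    }
    row <- data.frame(epoch = epoch, step = gstep,
                      lr = cosine_lr(gstep - 1L, total_steps, cfg$lr0, cfg$lr_min),
                      train_loss = ep_loss, val_IoU = val_iou, val_F1 = val_f1)
    log <- rbind(log, row)
    if (isTRUE(cfg$verbose))
      message(sprintf("epoch %3d  step %5d  lr %.3e  loss %.4f  val_IoU %s",
                      epoch, gstep, row$lr, ep_loss,
                      ifelse(is.na(val_iou), "-", sprintf("%.4f", val_iou))))
    if (!is.null(cfg$log_csv)) {
      dir.create(dirname(cfg$log_csv), recursive = TRUE, showWarnings = FALSE)
      utils::write.table(row, cfg$log_csv, sep = ",",
                         append = file.exists(cfg$log_csv),
                         col.names = !file.exists(cfg$log_csv), row.names = FALSE)
    }
    if (!is.null(cfg$checkpoint_dir)) {
      dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      save_checkpoint(model, file.path(cfg$checkpoint_dir, "last.ckpt"),
                      opt = opt, epoch = epoch, step = gstep,
                      rng = get(".Random.seed", .GlobalEnv), log = log)
      if (!is.na(val_iou) && val_iou > best_iou)
        save_checkpoint(model, file.path(cfg$checkpoint_dir, "best.ckpt"),
                        opt = opt, epoch = epoch, step = gstep,
                        rng = get(".Random.seed", .GlobalEnv), log = log)
    }
    if (!is.na(val_iou) && val_iou > best_iou) best_iou <- val_iou
    if (!is.null(stop_after) && epoch >= stop_after) break
  }
  list(model = model, log = log, opt = opt, best_iou = best_iou)
}

#' Evaluate a model on labelled tiles
#'
#' Thresholds predictions at 0.5 (ties classified positive), pools confusion
#' counts over all tiles (micro-averaging), and computes the metric suite.
#'
#' @param model a `segmentation_model`, or a function `(b,10,T,T) -> (b,1,T,T)`
#'   (e.g. an oracle) for testing the harness.
#' @param tiles list of tile pairs with masks.
#' @param batch_size tiles per forward pass.
#' @return list of class `eval_report`: `metrics`, pooled `counts`,
#'   `n_tiles`, `config_fingerprint`.
#' @export
evaluate_model <- function(model, tiles, batch_size = 8L) {
  if (length(tiles) == 0L) stop("empty evaluation set")
  counts <- structure(list(TP = 0, FP = 0, FN = 0, TN = 0),
                      class = "confusion_counts")
  fwd <- if (is.function(model)) model else
    function(x) .net_fw(model, x, training = FALSE)$y
  i <- 1L
  while (i <= length(tiles)) {
    idx <- i:min(i + batch_size - 1L, length(tiles))
    ba <- .batch_arrays(tiles, idx, cfg = NULL)
    p <- fwd(ba$x)
    pm <- (p >= 0.5) * 1
    counts <- add_counts(counts, confusion_counts(pm, ba$y))
    i <- i + batch_size
  }
  fp <- if (is.function(model)) "oracle" else
    paste0("tile", model$config$tile_size, "_wm", model$config$width_multiplier)
  structure(list(metrics = compute_metrics(counts), counts = counts,
                 n_tiles = length(tiles), config_fingerprint = fp),
            class = "eval_report")
}

#' Predict a whole raster
#'
#' Tiles the raster with the model's tile size and half-tile step, forwards
#' each tile, stitches probabilities by overlap averaging, and thresholds at
#' 0.5 (ties positive). Nodata pixels are forced to background.
#'
#' @param model a `segmentation_model` or oracle function.
#' @param stack a [band_stack()] with normalised reflectance.
#' @param out_prefix optional path prefix: writes `<prefix>_prob.tif` and
#'   `<prefix>_mask.tif` with the source geotransform.
#' @param tile_size,step tiling geometry; default from the model config.
#' @return list: `prob` (H x W), `mask` (H x W binary).
#' @export
predict_raster <- function(model, stack, out_prefix = NULL,
                           tile_size = NULL, step = NULL) {
  if (!inherits(stack, "band_stack")) stop("stack must be a band_stack")
  if (dim(stack$data)[1L] != 10L) stop("band stack must have 10 bands")
  if (is.null(tile_size))
    tile_size <- if (is.function(model)) 64L else model$config$tile_size
  if (is.null(step)) step <- tile_size %/% 2L
  arr <- stack$data
  nod <- is.na(arr[1L, , ])
  arr[is.na(arr)] <- 0
  tiles <- sliding_window_tiles(band_stack(arr, transform = stack$transform,
                                           crs = stack$crs,
                                           source_id = stack$source_id),
                                window = tile_size, step = step)
  fwd <- if (is.function(model)) model else
    function(x) .net_fw(model, x, training = FALSE)$y
  probs <- vector("list", length(tiles))
  origins <- vector("list", length(tiles))
  for (i in seq_along(tiles)) {
    x <- array(tiles[[i]]$image, dim = c(1L, dim(tiles[[i]]$image)))
    probs[[i]] <- matrix(fwd(x)[1L, 1L, , ], tile_size, tile_size)
    origins[[i]] <- tiles[[i]]$origin
  }
  prob <- stitch_predictions(probs, origins, dim(arr)[2:3])
  prob[nod] <- 0
  mask <- (prob >= 0.5) * 1
  mask[nod] <- 0
  if (!is.null(out_prefix)) {
    write_raster(prob, paste0(out_prefix, "_prob.tif"),
                 transform = stack$transform, crs = stack$crs)
    write_raster(mask, paste0(out_prefix, "_mask.tif"),
                 transform = stack$transform, crs = stack$crs)
  }
  list(prob = prob, mask = mask)
}
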