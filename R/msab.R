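# Multiscale spatial attention block (MSAB): 1x1 QKV projection, per-scale
# depthwise aggregation, softmax-free ReLU linear attention over flattened
# tokens, 1x1 output projection with residual, then BatchNorm + GeLU MLP with
# a second residual.

#' MSAB configuration
#'
#' @param scales odd depthwise kernel sizes used for multiscale aggregation.
#' @param epsilon denominator guard of the attention row normaliser.
#' @param mlp_expansion expansion factor of the output MLP.
#' @param normalized if `FALSE`, skip the row normaliser and return the raw
#'   linear-attention association (scale-divergent; provided for reference).
#' @return a list of class `msab_config`.
#' @export
msab_config <- function(scales = c(3L, 5L), epsilon = 1e-6,
                        mlp_expansion = 4L, normalized = TRUE) {
  if (length(scales) < 1L) stop("scales must be non-empty")
  if (any(scales %% 2L != 1L)) stop("all scales must be odd")
  if (epsilon <= 0) stop("epsilon must be > 0")
  structure(list(scales = as.integer(scales), epsilon = epsilon,
                 mlp_expansion = as.integer(mlp_expansion),
                 normalized = isTRUE(normalized)),
            class = "msab_config")
}

#' Build an MSAB
#'
#' @param channels input/output channel count.
#' @param cfg an [msab_config()].
#' @return an MSAB module list.
#' @export
msab_new <- function(channels, cfg = msab_config()) {
  channels <- as.integer(channels)
  ns <- length(cfg$scales)
  e <- cfg$mlp_expansion
  list(kind = "msab", cfg = cfg, channels = channels,
       qkv = conv_new(channels, 3L * channels, 1L, 1L),
       dws = lapply(cfg$scales, function(s)
         conv_new(3L * channels, 3L * channels, s, s, groups = 3L * channels)),
       proj = conv_new(ns * channels, channels, 1L, 1L),
       bn = bn_new(channels),
       mlp1 = conv_new(channels, e * channels, 1L, 1L),
       mlp2 = conv_new(e * channels, channels, 1L, 1L))
}

#' QKV projection
#'
#' 1x1 convolution producing stacked query/key/value maps (3C channels).
#'
#' @param block an MSAB built by `msab_new()`.
#' @param x feature map with the block's channel count.
#' @return feature map with 3C channels and unchanged spatial extents.
#' @export
qkv_project <- function(block, x) {
  check_fmap(x)
  conv_fw(block$qkv, x)$y
}

#' Multiscale depthwise aggregation
#'
#' One depthwise convolution (scale x scale, same-padded) per configured
#' scale, applied to the stacked QKV map.
#'
#' @param block an MSAB built by `msab_new()`.
#' @param qkv stacked QKV feature map (3C channels).
#' @return list with one feature map per scale, shapes preserved.
#' @export
multiscale_aggregate <- function(block, qkv) {
  check_fmap(qkv)
  lapply(block$dws, function(dw) conv_fw(dw, qkv)$y)
}

#' ReLU linear attention over token matrices
#'
#' Rectifies queries and keys, then computes row-normalised linear attention
#' `A_i = q'_i (K'^T V) / (q'_i (K'^T 1) + epsilon)` in the O(N d^2)
#' association order (keys aggregated against values first). With a single
#' token the normaliser makes the output equal `v` exactly; all-nonpositive
#' queries give a zero output (the epsilon guards the denominator).
#'
#' @param q,k,v token matrices, each N x d (N = h*w tokens).
#' @param epsilon denominator guard, > 0.
#' @param normalized include the row normaliser (default). `FALSE` returns
#'   the raw association `Q'(K'^T V)`.
#' @return N x d matrix of attention outputs.
#' @export
relu_linear_attention <- function(q, k, v, epsilon = 1e-6, normalized = TRUE) {
  q <- as.matrix(q); k <- as.matrix(k); v <- as.matrix(v)
  if (!all(dim(q) == dim(k)) || nrow(k) != nrow(v))
    stop("q, k, v must agree in token count")
  if (epsilon <= 0) stop("epsilon must be > 0")
  qp <- pmax(q, 0)
  kp <- pmax(k, 0)
  s <- crossprod(kp, v)                 # d x d: K'^T V
  num <- qp %*% s
  if (!normalized) return(num)
  den <- drop(qp %*% colSums(kp)) + epsilon
  num / den
}

# Forward with cache for one (batch, scale) token attention; q,k,v N x d.
.attn_fw <- function(q, k, v, epsilon) {
  qp <- pmax(q, 0)
  kp <- pmax(k, 0)
  s <- crossprod(kp, v)
  z <- colSums(kp)
  num <- qp %*% s
  den <- drop(qp %*% z) + epsilon
  a <- num / den
  list(y = a, cache = list(q = q, k = k, v = v, qp = qp, kp = kp, s = s,
                           z = z, a = a, den = den))
}

.attn_bw <- function(cache, ga) {
  dnum <- ga / cache$den
  dden <- -rowSums(ga * cache$a) / cache$den
  dqp <- dnum %*% t(cache$s) + outer(dden, cache$z)
  ds <- crossprod(cache$qp, dnum)        # d x d
  dz <- drop(crossprod(cache$qp, dden))  # d
  dkp <- cache$v %*% t(ds) + matrix(dz, nrow = nrow(cache$kp),
                                    ncol = ncol(cache$kp), byrow = TRUE)
  dv <- cache$kp %*% ds
  list(gq = dqp * (cache$q > 0), gk = dkp * (cache$k > 0), gv = dv)
}

# Flatten (B, C, H, W) -> per-batch token matrices (N = H*W, C), tokens in
# column-major (h fastest) order; .tokens_to_fmap inverts it.
.fmap_to_tokens <- function(x) {
  d <- dim(x)
  lapply(seq_len(d[1L]), function(b) {
    m <- matrix(aperm(x[b, , , , drop = FALSE], c(3L, 4L, 2L, 1L)),
                nrow = d[3L] * d[4L], ncol = d[2L])
    m
  })
}

.tokens_to_fmap <- function(toks, d) {
  out <- array(0, dim = d)
  for (b in seq_along(toks)) {
    a <- array(toks[[b]], dim = c(d[3L], d[4L], d[2L]))
    out[b, , , ] <- aperm(a, c(3L, 1L, 2L))
  }
  out
}

.msab_fw <- function(mod, x, training = FALSE) {
  d <- dim(x)
  C <- mod$channels
  eps <- mod$cfg$epsilon
  qkv <- conv_fw(mod$qkv, x)
  scale_caches <- vector("list", length(mod$dws))
  scale_outs <- vector("list", length(mod$dws))
  for (si in seq_along(mod$dws)) {
    agg <- conv_fw(mod$dws[[si]], qkv$y)
    toks <- .fmap_to_tokens(agg$y)                 # each N x 3C
    att <- vector("list", d[1L])
    acache <- vector("list", d[1L])
    for (b in seq_len(d[1L])) {
      tm <- toks[[b]]
      r <- .attn_fw(tm[, 1:C, drop = FALSE],
                    tm[, (C + 1):(2 * C), drop = FALSE],
                    tm[, (2 * C + 1):(3 * C), drop = FALSE], eps)
      att[[b]] <- r$y
      acache[[b]] <- r$cache
    }
    scale_outs[[si]] <- .tokens_to_fmap(att, c(d[1L], C, d[3L], d[4L]))
    scale_caches[[si]] <- list(agg = agg$cache, attn = acache)
  }
  cat_out <- cat_channels(scale_outs)
  pr <- conv_fw(mod$proj, cat_out)
  o <- pr$y + x
  bnr <- bn_fw(mod$bn, o, training)
  mod$bn <- bnr$mod
  m1 <- conv_fw(mod$mlp1, bnr$y)
  ge <- gelu_fw(m1$y)
  m2 <- conv_fw(mod$mlp2, ge$y)
  y <- m2$y + o
  list(y = y, mod = mod,
       cache = list(qkv = qkv$cache, scales = scale_caches, proj = pr$cache,
                    bn = bnr$cache, m1 = m1$cache, ge = ge$cache,
                    m2 = m2$cache, d = d))
}

.msab_bw <- function(mod, cache, gy) {
  d <- cache$d
  C <- mod$channels
  b2 <- conv_bw(mod$mlp2, cache$m2, gy)
  gge <- gelu_bw(cache$ge, b2$gx)
  b1 <- conv_bw(mod$mlp1, cache$m1, gge)
  bbn <- bn_bw(mod$bn, cache$bn, b1$gx)
  go <- gy + bbn$gx                                # MLP residual + BN path
  bproj <- conv_bw(mod$proj, cache$proj, go)
  gcat <- split_channels(bproj$gx, rep(C, length(mod$dws)))
  gqkv_y <- NULL
  gdws <- vector("list", length(mod$dws))
  for (si in seq_along(mod$dws)) {
    gat <- .fmap_to_tokens(gcat[[si]])
    gtoks <- vector("list", d[1L])
    for (b in seq_len(d[1L])) {
      ab <- .attn_bw(cache$scales[[si]]$attn[[b]], gat[[b]])
      gtoks[[b]] <- cbind(ab$gq, ab$gk, ab$gv)
    }
    gagg <- .tokens_to_fmap(gtoks, c(d[1L], 3L * C, d[3L], d[4L]))
    bdw <- conv_bw(mod$dws[[si]], cache$scales[[si]]$agg, gagg)
    gdws[[si]] <- bdw$g
    gqkv_y <- if (is.null(gqkv_y)) bdw$gx else gqkv_y + bdw$gx
  }
  bqkv <- conv_bw(mod$qkv, cache$qkv, gqkv_y)
  gx <- go + bqkv$gx                               # attention-projection residual
  list(gx = gx,
       g = list(qkv = bqkv$g, dws = gdws, proj = bproj$g, bn = bbn$g,
                mlp1 = b1$g, mlp2 = b2$g))
}

#' MSAB forward pass
#'
#' QKV projection, per-scale depthwise aggregation, ReLU linear attention per
#' scale, channel concatenation of the scale outputs, 1x1 projection with a
#' residual to the input, then BatchNorm + GeLU MLP with a second residual.
#' Output shape equals input shape.
#'
#' @param block an MSAB built by `msab_new()`.
#' @param x feature map with the block's channel count.
#' @param training use batch statistics in the normalisation.
#' @return feature map with the same extents as `x`.
#' @export
msab_forward <- function(block, x, training = FALSE) {
  check_fmap(x)
  if (dim(x)[2L] != block$channels)
    stop(sprintf("expected %d channels, got %d", block$channels, dim(x)[2L]))
  .msab_fw(block, x, training)$y
}
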