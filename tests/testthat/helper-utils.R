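# Shared test helpers: numerical differentiation, naive convolution oracle,
# and small fixture builders. All fixtures are generated in code.

num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}

# Direct (quadruple-loop) 2-D cross-correlation with zero same-padding,
# stride 1, one group: independent oracle for the im2col kernel.
naive_conv2d <- function(x, w, bias) {
  B <- dim(x)[1]; C <- dim(x)[2]; H <- dim(x)[3]; W <- dim(x)[4]
  CO <- dim(w)[1]; KH <- dim(w)[3]; KW <- dim(w)[4]
  ph <- (KH - 1) %/% 2; pw <- (KW - 1) %/% 2
  out <- array(0, c(B, CO, H, W))
  for (b in 1:B) for (o in 1:CO) for (i in 1:H) for (j in 1:W) {
    acc <- bias[o]
    for (c in 1:C) for (kh in 1:KH) for (kw in 1:KW) {
      hi <- i + kh - 1 - ph; wi <- j + kw - 1 - pw
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
        acc <- acc + x[b, c, hi, wi] * w[o, c, kh, kw]
    }
    out[b, o, i, j] <- acc
  }
  out
}

# Quadratic-form ReLU attention oracle: full N x N weight matrix.
brute_relu_attention <- function(q, k, v, eps = 1e-6) {
  qp <- pmax(q, 0); kp <- pmax(k, 0)
  w <- qp %*% t(kp)                       # N x N
  (w %*% v) / (rowSums(w) + eps)
}

# MLP weights realising the exact identity x = gelu(x) - gelu(-x), used to
# freeze the perceptron of a spectral branch to the identity map.
identity_mlp_weights <- function(cin, expansion) {
  w1 <- array(0, c(cin * expansion, cin, 1, 1))
  for (i in seq_len(cin)) {
    w1[i, i, 1, 1] <- 1
    w1[cin + i, i, 1, 1] <- -1
  }
  w2 <- array(0, c(cin, cin * expansion, 1, 1))
  for (i in seq_len(cin)) {
    w2[i, i, 1, 1] <- 1
    w2[i, cin + i, 1, 1] <- -1
  }
  list(w1 = w1, w2 = w2)
}

# Freeze a batch-norm module to the exact identity in eval mode.
freeze_bn_identity <- function(bn) {
  bn$buf$rmean <- bn$buf$rmean * 0
  bn$buf$rvar <- bn$buf$rvar * 0 + 1
  bn$par$gamma <- bn$par$gamma * 0 + sqrt(1 + bn$eps)
  bn$par$beta <- bn$par$beta * 0
  bn
}

# A centred identity tap for a depthwise kernel array (CO, 1, KH, KW).
identity_tap <- function(w) {
  w[] <- 0
  kh <- dim(w)[3]; kw <- dim(w)[4]
  for (o in seq_len(dim(w)[1])) w[o, 1, (kh + 1) %/% 2, (kw + 1) %/% 2] <- 1
  w
}

tiny_net_config <- function(width_multiplier = 0.125) {
  network_config(tile_size = 64L, width_multiplier = width_multiplier)
}

# Tiles from seeded synthetic scenes, in the training interchange form.
synthetic_tiles <- function(n, seed, size = c(64L, 64L)) {
  scenes <- generate_dataset(n, seed = seed, size = size)
  lapply(scenes, function(sc) list(image = sc$stack$data, mask = sc$mask))
}
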