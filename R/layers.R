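# Primitive differentiable layers. Every module is a plain list with a $kind,
# trainable arrays under $par, non-trainable state under $buf, and child
# modules under other named fields. Forward functions return
# list(y, cache, mod) -- mod is threaded back out so batch-norm running
# statistics can be updated functionally. Backward functions take the cache
# and the upstream gradient and return list(gx, g) where g mirrors the
# module's structure with gradients in place of parameters.

he_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# ---- convolution -----------------------------------------------------------

conv_new <- function(cin, cout, kh, kw, stride = 1L, groups = 1L,
                     pad = c((kh - 1L) %/% 2L, (kw - 1L) %/% 2L)) {
  cg <- cin %/% groups
  if (cg * groups != cin) stop("conv: channels not divisible by groups")
  list(kind = "conv",
       par = list(w = he_uniform(c(cout, cg, kh, kw), fan_in = cg * kh * kw),
                  b = numeric(cout)),
       stride = as.integer(stride), pad = as.integer(pad),
       groups = as.integer(groups))
}

conv_fw <- function(mod, x) {
  y <- cpp_conv2d_fw(x, dim(x), mod$par$w, dim(mod$par$w), mod$par$b,
                     mod$stride, mod$pad[1L], mod$pad[2L], mod$groups)
  list(y = y, cache = list(x = x), mod = mod)
}

conv_bw <- function(mod, cache, gy) {
  g <- cpp_conv2d_bw(cache$x, dim(cache$x), mod$par$w, dim(mod$par$w), gy,
                     mod$stride, mod$pad[1L], mod$pad[2L], mod$groups)
  list(gx = g$gx, g = list(par = list(w = g$gw, b = g$gb)))
}

# ---- batch normalisation ---------------------------------------------------

bn_new <- function(c, eps = 1e-5, momentum = 0.1) {
  list(kind = "bn",
       par = list(gamma = rep(1, c), beta = numeric(c)),
       buf = list(rmean = numeric(c), rvar = rep(1, c)),
       eps = eps, momentum = momentum)
}

# View a (B,C,H,W) array as a (C, B*H*W) matrix and back.
.to_cmat <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(2L, 1L, 3L, 4L))
  dim(m) <- c(d[2L], d[1L] * d[3L] * d[4L])
  m
}
.from_cmat <- function(m, d) {
  dim(m) <- c(d[2L], d[1L], d[3L], d[4L])
  aperm(m, c(2L, 1L, 3L, 4L))
}

bn_fw <- function(mod, x, training) {
  d <- dim(x)
  m <- .to_cmat(x)
  n <- ncol(m)
  if (training) {
    mu <- rowMeans(m)
    xc <- m - mu
    va <- rowMeans(xc * xc)          # biased variance for normalisation
    mod$buf$rmean <- (1 - mod$momentum) * mod$buf$rmean + mod$momentum * mu
    mod$buf$rvar <- (1 - mod$momentum) * mod$buf$rvar +
      mod$momentum * va * n / max(1, n - 1)
  } else {
    mu <- mod$buf$rmean
    va <- mod$buf$rvar
    xc <- m - mu
  }
  istd <- 1 / sqrt(va + mod$eps)
  xhat <- xc * istd
  y <- xhat * mod$par$gamma + mod$par$beta
  list(y = .from_cmat(y, d), mod = mod,
       cache = list(xhat = xhat, istd = istd, d = d, training = training))
}

bn_bw <- function(mod, cache, gy) {
  gm <- .to_cmat(gy)
  n <- ncol(gm)
  ggamma <- rowSums(gm * cache$xhat)
  gbeta <- rowSums(gm)
  gxh <- gm * mod$par$gamma
  if (cache$training) {
    gx <- cache$istd * (gxh - rowMeans(gxh) - cache$xhat * rowMeans(gxh * cache$xhat))
  } else {
    gx <- gxh * cache$istd
  }
  list(gx = .from_cmat(gx, cache$d),
       g = list(par = list(gamma = ggamma, beta = gbeta)))
}

# ---- activations -----------------------------------------------------------

relu_fw <- function(x) list(y = pmax(x, 0), cache = list(pos = x > 0))
relu_bw <- function(cache, gy) gy * cache$pos

# Exact GeLU: x * Phi(x).
gelu_fw <- function(x) list(y = x * stats::pnorm(x), cache = list(x = x))
gelu_bw <- function(cache, gy)
  gy * (stats::pnorm(cache$x) + cache$x * stats::dnorm(cache$x))

sigmoid_fw <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(y = y, cache = list(y = y))
}
sigmoid_bw <- function(cache, gy) gy * cache$y * (1 - cache$y)

# ---- pooling / upsampling --------------------------------------------------

maxpool_fw <- function(x, k = 3L, stride = 2L, pad = 1L) {
  r <- cpp_maxpool_fw(x, dim(x), k, stride, pad)
  list(y = r$out, cache = list(argmax = r$argmax, xd = dim(x)))
}
maxpool_bw <- function(cache, gy) cpp_maxpool_bw(gy, cache$argmax, cache$xd)

upsample2x_fw <- function(x) list(y = cpp_upsample2x_fw(x, dim(x)),
                                  cache = list(xd = dim(x)))
upsample2x_bw <- function(cache, gy) cpp_upsample2x_bw(gy, cache$xd)

# ---- parameter tree utilities ---------------------------------------------

# Depth-first walk over a module tree collecting trainable arrays. Children
# are any list-valued fields other than par/buf; unnamed lists (e.g. block
# lists) are recursed with index names.
collect_params <- function(mod, path = "") {
  out <- list()
  if (is.list(mod)) {
    if (!is.null(mod$par)) {
      for (nm in names(mod$par))
        out[[paste0(path, "par.", nm)]] <- mod$par[[nm]]
    }
    nms <- names(mod)
    for (i in seq_along(mod)) {
      nm <- if (is.null(nms) || !nzchar(nms[i])) as.character(i) else nms[i]
      if (nm %in% c("par", "buf", "kind")) next
      el <- mod[[i]]
      if (is.list(el))
        out <- c(out, collect_params(el, paste0(path, nm, ".")))
    }
  }
  out
}

# Write a flat named list of arrays (as produced by collect_params) back into
# the module tree, preserving structure.
set_params <- function(mod, flat) {
  assign_one <- function(node, keys, value) {
    k <- keys[1L]
    if (k == "par") {
      node$par[[keys[2L]]] <- value
    } else {
      ki <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
      node[[ki]] <- assign_one(node[[ki]], keys[-1L], value)
    }
    node
  }
  for (nm in names(flat))
    mod <- assign_one(mod, strsplit(nm, ".", fixed = TRUE)[[1L]], flat[[nm]])
  mod
}

# ---- Adam ------------------------------------------------------------------

adam_new <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                     weight_decay = 0) {
  list(m = lapply(params, function(p) p * 0),   # clones shape/attributes
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = beta1, beta2 = beta2, eps = eps,
       weight_decay = weight_decay)
}

adam_step <- function(opt, params, grads, lr) {
  if (!identical(names(params), names(grads))) {
    if (!setequal(names(params), names(grads)))
      stop("parameter and gradient trees disagree")
    grads <- grads[names(params)]
  }
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (opt$weight_decay > 0) g <- g + opt$weight_decay * params[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  list(opt = opt, params = params)
}

# Sum two gradient trees with identical structure (for residual joins).
add_grad_trees <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- add_grad_trees(a[[nm]], b[[nm]])
    return(a)
  }
  a + b
}
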