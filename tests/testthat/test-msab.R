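# Multiscale spatial attention block: projection oracles, linear-attention
# equivalence with the quadratic oracle, residual identities, and invariants
# (convex combination, permutation equivariance).

ns <- asNamespace("mssfnet")

test_that("QKV projection triples channels and obeys a matrix oracle", {
  set.seed(10)
  blk <- ns$msab_new(8)
  x <- array(rnorm(1 * 8 * 16 * 16), c(1, 8, 16, 16))
  y <- qkv_project(blk, x)
  expect_equal(dim(y), c(1L, 24L, 16L, 16L))

  # identity-block weights: each third copies x
  blk2 <- blk
  blk2$qkv$par$w[] <- 0; blk2$qkv$par$b[] <- 0
  for (i in 1:8) for (s in 0:2) blk2$qkv$par$w[s * 8 + i, i, 1, 1] <- 1
  y2 <- qkv_project(blk2, x)
  for (s in 0:2)
    expect_equal(y2[, s * 8 + 1:8, , , drop = FALSE], x, tolerance = 1e-12)

  # hand-set weights on a single pixel: 6x2 matrix times the channel vector
  blk3 <- ns$msab_new(2)
  xm <- array(c(0.3, -1.2), c(1, 2, 1, 1))
  wmat <- matrix(rnorm(12), 6, 2)
  for (o in 1:6) blk3$qkv$par$w[o, , 1, 1] <- wmat[o, ]
  blk3$qkv$par$b <- rnorm(6)
  expect_equal(as.vector(qkv_project(blk3, xm)),
               as.vector(wmat %*% c(0.3, -1.2) + blk3$qkv$par$b),
               tolerance = 1e-12)
})

test_that("multiscale aggregation keeps shapes and identity kernels pass through", {
  set.seed(11)
  blk <- ns$msab_new(4)
  qkv <- array(rnorm(2 * 12 * 6 * 6), c(2, 12, 6, 6))
  branches <- multiscale_aggregate(blk, qkv)
  expect_length(branches, 2)
  for (br in branches) expect_equal(dim(br), dim(qkv))

  blk2 <- blk
  for (i in seq_along(blk2$dws)) {
    blk2$dws[[i]]$par$w <- identity_tap(blk2$dws[[i]]$par$w)
    blk2$dws[[i]]$par$b[] <- 0
  }
  for (br in multiscale_aggregate(blk2, qkv))
    expect_equal(br, qkv, tolerance = 1e-12)

  # hand-set 3x3 kernel on a 1-channel map equals the direct convolution
  blk1 <- ns$msab_new(1)        # 3C = 3 channels
  q1 <- array(rnorm(9 * 3), c(1, 3, 3, 3))
  got <- multiscale_aggregate(blk1, q1)[[1]]
  for (c in 1:3) {
    wfull <- array(0, c(1, 1, 3, 3))
    wfull[1, 1, , ] <- blk1$dws[[1]]$par$w[c, 1, , ]
    expect_equal(got[, c, , , drop = FALSE],
                 naive_conv2d(q1[, c, , , drop = FALSE], wfull,
                              blk1$dws[[1]]$par$b[c]),
                 tolerance = 1e-12)
  }
  expect_error(msab_config(scales = c(3, 4)), "odd")
})

test_that("relu linear attention matches the quadratic oracle and edge cases", {
  set.seed(12)
  # 20 random small instances
  for (i in 1:20) {
    n <- sample(2:16, 1); d <- sample(1:8, 1)
    q <- matrix(rnorm(n * d), n, d)
    k <- matrix(rnorm(n * d), n, d)
    v <- matrix(rnorm(n * d), n, d)
    expect_lt(max(abs(relu_linear_attention(q, k, v) -
                        brute_relu_attention(q, k, v))), 1e-5)
  }
  # single positive token attends to itself: output equals v exactly
  q1 <- matrix(runif(3, 0.1, 1), 1, 3)
  k1 <- matrix(runif(3, 0.1, 1), 1, 3)
  v1 <- matrix(rnorm(3), 1, 3)
  expect_equal(relu_linear_attention(q1, k1, v1, epsilon = 1e-12), v1,
               tolerance = 1e-9)
  # all-nonpositive queries are rectified away: zero output
  qn <- matrix(-abs(rnorm(12)), 4, 3)
  expect_equal(max(abs(relu_linear_attention(qn, k = matrix(rnorm(12), 4, 3),
                                             v = matrix(rnorm(12), 4, 3)))), 0)
})

test_that("attention outputs are convex combinations and permutation-equivariant", {
  set.seed(13)
  for (i in 1:5) {
    n <- 8; d <- 4
    q <- matrix(runif(n * d, 0.1, 2), n, d)
    k <- matrix(runif(n * d, 0.1, 2), n, d)
    v <- matrix(rnorm(n * d), n, d)
    a <- relu_linear_attention(q, k, v, epsilon = 1e-9)
    lo <- apply(v, 2, min); hi <- apply(v, 2, max)
    for (j in 1:d) {
      expect_gte(min(a[, j]), lo[j] - 1e-6)
      expect_lte(max(a[, j]), hi[j] + 1e-6)
    }
    perm <- sample(n)
    expect_equal(relu_linear_attention(q[perm, ], k, v, epsilon = 1e-9),
                 a[perm, ], tolerance = 1e-12)
  }
})

test_that("double residual: zeroed projections make the block an exact identity", {
  set.seed(14)
  blk <- ns$msab_new(8)
  blk$proj$par$w[] <- 0; blk$proj$par$b[] <- 0
  blk$mlp2$par$w[] <- 0; blk$mlp2$par$b[] <- 0
  x <- array(rnorm(2 * 8 * 4 * 4), c(2, 8, 4, 4))
  expect_identical(msab_forward(blk, x), x)
})

test_that("block forward equals a straight-line re-implementation", {
  set.seed(15)
  C <- 8
  blk <- ns$msab_new(C)
  x <- array(rnorm(1 * C * 4 * 4), c(1, C, 4, 4))
  qkv <- naive_conv2d(x, blk$qkv$par$w, blk$qkv$par$b)
  scale_out <- vector("list", 2)
  for (si in 1:2) {
    agg <- qkv * 0
    for (c in seq_len(3 * C)) {
      kd <- dim(blk$dws[[si]]$par$w)[3]
      wfull <- array(0, c(1, 1, kd, kd))
      wfull[1, 1, , ] <- blk$dws[[si]]$par$w[c, 1, , ]
      agg[, c, , ] <- naive_conv2d(qkv[, c, , , drop = FALSE], wfull,
                                   blk$dws[[si]]$par$b[c])
    }
    toks <- matrix(aperm(agg[1, , , , drop = FALSE], c(3, 4, 2, 1)), 16, 3 * C)
    a <- brute_relu_attention(toks[, 1:C], toks[, C + 1:C], toks[, 2 * C + 1:C],
                              eps = blk$cfg$epsilon)
    scale_out[[si]] <- aperm(array(a, c(4, 4, C)), c(3, 1, 2))
  }
  cat2 <- array(0, c(1, 2 * C, 4, 4))
  cat2[1, 1:C, , ] <- scale_out[[1]]; cat2[1, C + 1:C, , ] <- scale_out[[2]]
  o <- naive_conv2d(cat2, blk$proj$par$w, blk$proj$par$b) + x
  on <- o
  for (c in 1:C)
    on[, c, , ] <- (o[, c, , ] - blk$bn$buf$rmean[c]) /
      sqrt(blk$bn$buf$rvar[c] + blk$bn$eps) * blk$bn$par$gamma[c] +
      blk$bn$par$beta[c]
  m1 <- naive_conv2d(on, blk$mlp1$par$w, blk$mlp1$par$b)
  ge <- m1 * pnorm(m1)
  expected <- naive_conv2d(ge, blk$mlp2$par$w, blk$mlp2$par$b) + o
  expect_equal(msab_forward(blk, x), expected, tolerance = 1e-9)
  expect_equal(dim(msab_forward(blk, array(rnorm(2 * 8 * 8 * 8), c(2, 8, 8, 8)))),
               c(2L, 8L, 8L, 8L))
})

test_that("attention and block backward passes agree with central differences", {
  set.seed(16)
  q <- matrix(rnorm(18), 6, 3); k <- matrix(rnorm(18), 6, 3)
  v <- matrix(rnorm(18), 6, 3)
  fw <- ns$.attn_fw(q, k, v, 1e-6)
  ga <- matrix(rnorm(18), 6, 3)
  bw <- ns$.attn_bw(fw$cache, ga)
  expect_lt(max_rel_err(bw$gq, num_grad(function(z) sum(ns$.attn_fw(z, k, v, 1e-6)$y * ga), q)), 1e-6)
  expect_lt(max_rel_err(bw$gk, num_grad(function(z) sum(ns$.attn_fw(q, z, v, 1e-6)$y * ga), k)), 1e-6)
  expect_lt(max_rel_err(bw$gv, num_grad(function(z) sum(ns$.attn_fw(q, k, z, 1e-6)$y * ga), v)), 1e-6)

  blk <- ns$msab_new(4)
  x <- array(rnorm(2 * 4 * 3 * 3), c(2, 4, 3, 3))
  fwb <- ns$.msab_fw(blk, x, TRUE)
  gy <- array(rnorm(length(fwb$y)), dim(fwb$y))
  bwb <- ns$.msab_bw(fwb$mod, fwb$cache, gy)
  expect_lt(max_rel_err(bwb$gx,
                        num_grad(function(z) sum(ns$.msab_fw(blk, z, TRUE)$y * gy), x)),
            1e-5)
})
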