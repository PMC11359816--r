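# Spatial-spectral feature extraction block: permutation bookkeeping, group
# splitting, branch identities, shape preservation, and a step-by-step
# re-implementation oracle.

ns <- asNamespace("mssfnet")

test_that("spectral permutation swaps channel and width roles and inverts exactly", {
  x <- array(seq_len(1 * 8 * 4 * 6), c(1, 8, 4, 6))
  xp <- permute_spectral(x)
  expect_equal(dim(xp), c(1L, 6L, 4L, 8L))
  expect_identical(unpermute_spectral(xp), x)
  # index tracking on an arange-filled array: (b, c, h, w) -> (b, w, h, c)
  for (probe in list(c(1, 3, 2, 6), c(1, 8, 4, 1), c(1, 1, 1, 1))) {
    expect_identical(xp[probe[1], probe[4], probe[3], probe[2]],
                     x[probe[1], probe[2], probe[3], probe[4]])
  }
})

test_that("group splitting is an exact round trip and pads when allowed", {
  x <- array(rnorm(2 * 6 * 3 * 4), c(2, 6, 3, 4))
  parts <- split_groups(x, 3)
  expect_length(parts, 3)
  expect_equal(dim(parts[[1]])[2], 2L)
  expect_identical(ns$cat_channels(parts), x)

  x7 <- array(rnorm(1 * 7 * 2 * 2), c(1, 7, 2, 2))
  expect_error(split_groups(x7, 3), "divisible")
  padded <- split_groups(x7, 3, pad = TRUE)
  expect_equal(attr(padded, "padded_positions"), 8:9)
  expect_true(all(vapply(padded, function(p) dim(p)[2], integer(1)) == 3L))
  # padded columns are zero and dropped on fusion
  recon <- ns$cat_channels(padded)
  expect_equal(max(abs(recon[, 8:9, , ])), 0)
  expect_identical(recon[, 1:7, , , drop = FALSE], x7)
})

test_that("branch zeroing gives zero branches and an exact residual identity", {
  set.seed(4)
  blk <- ns$ssfeb_new(8, 12)
  x <- array(rnorm(2 * 8 * 6 * 12), c(2, 8, 6, 12))

  # zero final projections kill each branch
  blk0 <- blk
  blk0$spe$mlp2$par$w[] <- 0; blk0$spe$mlp2$par$b[] <- 0
  blk0$spa$exp$par$w[] <- 0; blk0$spa$exp$par$b[] <- 0
  expect_equal(max(abs(spefeb_forward(blk0, x))), 0)
  expect_equal(max(abs(spafeb_forward(blk0, x))), 0)
  expect_identical(ssfeb_forward(blk0, x), x)   # pure residual, max dev 0

  # additivity: output - input == spe + spa
  y <- ssfeb_forward(blk, x)
  expect_equal(y - x, spefeb_forward(blk, x) + spafeb_forward(blk, x),
               tolerance = 1e-6)
  expect_equal(dim(y), dim(x))
})

test_that("shape preservation holds across sizes and configs", {
  set.seed(5)
  for (cfg in list(list(c = 4, w = 6, h = 3), list(c = 8, w = 16, h = 16),
                   list(c = 12, w = 5, h = 4))) {
    blk <- ns$ssfeb_new(cfg$c, cfg$w)
    x <- array(rnorm(cfg$c * cfg$h * cfg$w), c(1, cfg$c, cfg$h, cfg$w))
    expect_equal(dim(ssfeb_forward(blk, x)), dim(x))
  }
  blk <- ns$ssfeb_new(4, 8)
  expect_error(ssfeb_forward(blk, array(0, c(1, 4, 8, 10))), "width")
})

test_that("spectral branch with identity taps, frozen norm and identity MLP is the identity", {
  set.seed(6)
  blk <- ns$ssfeb_new(3, 6, ssfeb_config(spectral_kernel = 5,
                                         spatial_reduction = 1))
  for (nm in c("dw1", "dw2", "dw3")) {
    blk$spe[[nm]]$par$w <- identity_tap(blk$spe[[nm]]$par$w)
    blk$spe[[nm]]$par$b[] <- 0
  }
  blk$spe$bn <- freeze_bn_identity(blk$spe$bn)
  mlpw <- identity_mlp_weights(6, blk$cfg$mlp_expansion)
  blk$spe$mlp1$par$w <- mlpw$w1; blk$spe$mlp1$par$b[] <- 0
  blk$spe$mlp2$par$w <- mlpw$w2; blk$spe$mlp2$par$b[] <- 0
  x <- array(rnorm(1 * 3 * 2 * 6), c(1, 3, 2, 6))
  expect_equal(spefeb_forward(blk, x), x, tolerance = 1e-12)
})

test_that("spatial branch on a single pixel equals hand matrix products", {
  set.seed(7)
  blk <- ns$ssfeb_new(4, 1)
  x <- array(rnorm(4), c(1, 4, 1, 1))
  wr <- matrix(blk$spa$red$par$w, 1, 4)     # (C/r=1) x C
  wd <- blk$spa$dw$par$w[1, 1, 2, 2]        # only the centre tap hits a 1x1 input
  we <- matrix(blk$spa$exp$par$w, 4, 1)     # C x (C/r)
  expected <- we %*% (wd * (wr %*% as.vector(x) + blk$spa$red$par$b) +
                        blk$spa$dw$par$b) + blk$spa$exp$par$b
  expect_equal(as.vector(spafeb_forward(blk, x)), as.vector(expected),
               tolerance = 1e-12)
})

test_that("block forward equals a straight-line re-implementation", {
  set.seed(8)
  blk <- ns$ssfeb_new(8, 16)
  x <- array(rnorm(1 * 8 * 16 * 16), c(1, 8, 16, 16))
  # independent composition: permute, split, depthwise convs via the naive
  # oracle, concat, BN (eval), MLP, crop, unpermute; plus bottleneck branch.
  xp <- aperm(x, c(1, 4, 3, 2))
  gs <- 16 %/% 3 + 1                          # wp = 18, group size 6
  xpp <- array(0, c(1, 18, 16, 8)); xpp[, 1:16, , ] <- xp
  pieces <- list(xpp[, 1:6, , , drop = FALSE], xpp[, 7:12, , , drop = FALSE],
                 xpp[, 13:18, , , drop = FALSE])
  dwo <- vector("list", 3)
  for (i in 1:3) {
    cv <- blk$spe[[c("dw1", "dw2", "dw3")[i]]]
    out <- pieces[[i]] * 0
    for (c in 1:6) {
      wfull <- array(0, c(1, 1, dim(cv$par$w)[3], dim(cv$par$w)[4]))
      wfull[1, 1, , ] <- cv$par$w[c, 1, , ]
      out[, c, , ] <- naive_conv2d(pieces[[i]][, c, , , drop = FALSE], wfull,
                                   cv$par$b[c])
    }
    dwo[[i]] <- out
  }
  f <- array(0, c(1, 18, 16, 8))
  f[, 1:6, , ] <- dwo[[1]]; f[, 7:12, , ] <- dwo[[2]]; f[, 13:18, , ] <- dwo[[3]]
  bn <- blk$spe$bn
  fn <- f
  for (c in 1:18)
    fn[, c, , ] <- (f[, c, , ] - bn$buf$rmean[c]) / sqrt(bn$buf$rvar[c] + bn$eps) *
      bn$par$gamma[c] + bn$par$beta[c]
  m1 <- naive_conv2d(fn, blk$spe$mlp1$par$w, blk$spe$mlp1$par$b)
  ge <- m1 * pnorm(m1)
  m2 <- naive_conv2d(ge, blk$spe$mlp2$par$w, blk$spe$mlp2$par$b)
  kspe <- aperm(m2[, 1:16, , , drop = FALSE], c(1, 4, 3, 2))

  red <- naive_conv2d(x, blk$spa$red$par$w, blk$spa$red$par$b)
  dwm <- red * 0
  for (c in seq_len(dim(red)[2])) {
    wfull <- array(0, c(1, 1, 3, 3)); wfull[1, 1, , ] <- blk$spa$dw$par$w[c, 1, , ]
    dwm[, c, , ] <- naive_conv2d(red[, c, , , drop = FALSE], wfull,
                                 blk$spa$dw$par$b[c])
  }
  kspa <- naive_conv2d(dwm, blk$spa$exp$par$w, blk$spa$exp$par$b)
  expect_equal(ssfeb_forward(blk, x), kspe + kspa + x, tolerance = 1e-9)
})

test_that("gradients flow to every input position of a probe", {
  set.seed(9)
  blk <- ns$ssfeb_new(4, 8)
  x <- array(rnorm(1 * 4 * 8 * 8), c(1, 4, 8, 8))
  fw <- ns$.ssfeb_fw(blk, x, TRUE)
  gy <- array(1, dim(fw$y))
  bw <- ns$.ssfeb_bw(fw$mod, fw$cache, gy)
  expect_true(all(bw$gx != 0))
  # and against central differences
  expect_lt(max_rel_err(bw$gx,
                        num_grad(function(z) sum(ns$.ssfeb_fw(blk, z, TRUE)$y), x)),
            1e-6)
})
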