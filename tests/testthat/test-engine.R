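# Checks of the compiled convolution engine against naive oracles and of the
# analytic backward passes against central-difference numerics. The engine
# accumulates in float32, so comparisons use float32-level tolerances.

test_that("GEMM convolution matches the direct-loop oracle", {
  set.seed(1)
  for (rep in 1:3) {
    x <- array(rnorm(5 * 6 * 4 * 3), c(5, 6, 4, 3))
    p <- digcsvnet:::init_conv(3L, 3L, 2L)
    out <- digcsvnet:::conv_fw(x, p, 3L)$out
    expect_equal(out, naive_conv3d(x, p$w, p$b, 3L), tolerance = 1e-5)
  }
  # strided 2x2x2 (the downsampling shape) and 1x1x1 (the head shape)
  x <- array(rnorm(6 * 6 * 4 * 2), c(6, 6, 4, 2))
  p2 <- digcsvnet:::init_conv(2L, 2L, 3L)
  out2 <- digcsvnet:::conv_fw(x, p2, 2L, stride = 2L, pad = 0L)$out
  expect_equal(out2, naive_conv3d(x, p2$w, p2$b, 2L, stride = 2L, pad = 0L),
               tolerance = 1e-5)
  p1 <- digcsvnet:::init_conv(1L, 2L, 4L)
  out1 <- digcsvnet:::conv_fw(x, p1, 1L, pad = 0L)$out
  expect_equal(out1, naive_conv3d(x, p1$w, p1$b, 1L, pad = 0L),
               tolerance = 1e-5)
})

test_that("transposed convolution scatters each voxel into its 2x2x2 block", {
  set.seed(2)
  x <- array(rnorm(3 * 2 * 2 * 2), c(3, 2, 2, 2))
  p <- digcsvnet:::init_deconv(2L, 3L)
  out <- digcsvnet:::deconv_fw(x, p)$out
  expect_identical(dim(out), c(6L, 4L, 4L, 3L))
  # direct oracle: output(2i-1+kx, 2j-1+ky, 2l-1+kz, co) =
  #   sum_ci x(i,j,l,ci) * w[ci, co*8 + kz*4 + ky*2 + kx] + b[co]
  ref <- array(0, c(6, 4, 4, 3))
  for (co in 1:3) {
    ref[, , , co] <- p$b[co]
    for (i in 1:3) for (j in 1:2) for (l in 1:2) {
      for (kz in 0:1) for (ky in 0:1) for (kx in 0:1) {
        col <- (co - 1L) * 8L + kz * 4L + ky * 2L + kx + 1L
        ref[2 * i - 1 + kx, 2 * j - 1 + ky, 2 * l - 1 + kz, co] <-
          ref[2 * i - 1 + kx, 2 * j - 1 + ky, 2 * l - 1 + kz, co] +
          sum(x[i, j, l, ] * p$w[, col])
      }
    }
  }
  expect_equal(out, ref, tolerance = 1e-5)
})

test_that("convolution gradients match central differences", {
  set.seed(3)
  x <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  p <- digcsvnet:::init_conv(3L, 2L, 2L)
  proj <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  loss <- function(w, b, xx) {
    sum(digcsvnet:::conv_fw(xx, list(w = w, b = b), 3L,
                            act = "elu", alpha = 1)$out * proj)
  }
  cache <- digcsvnet:::conv_fw(x, p, 3L, act = "elu", alpha = 1)
  bw <- digcsvnet:::conv_bw(proj, cache, p, act = "elu", alpha = 1)
  h <- 1e-3
  for (idx in sample(length(p$w), 5)) {
    wp <- p$w; wp[idx] <- wp[idx] + h
    wm <- p$w; wm[idx] <- wm[idx] - h
    num <- (loss(wp, p$b, x) - loss(wm, p$b, x)) / (2 * h)
    expect_equal(bw$g$w[idx], num, tolerance = 5e-2)
  }
  for (idx in sample(length(x), 3)) {
    xp <- x; xp[idx] <- xp[idx] + h
    xm <- x; xm[idx] <- xm[idx] - h
    num <- (loss(p$w, p$b, xp) - loss(p$w, p$b, xm)) / (2 * h)
    expect_equal(bw$gx[idx], num, tolerance = 5e-2)
  }
  bp <- p$b; bp[1] <- bp[1] + h
  bm <- p$b; bm[1] <- bm[1] - h
  num <- (loss(p$w, bp, x) - loss(p$w, bm, x)) / (2 * h)
  expect_equal(bw$g$b[1], num, tolerance = 5e-2)
})

test_that("whole-network weight gradients match central differences", {
  cfg <- network_config(base_channels = 8L, input_patch = c(16L, 16L, 16L))
  model <- build_network(cfg, seed = 4)
  set.seed(4)
  gray <- array(sample(0:255, 16^3, TRUE), c(16, 16, 16))
  target <- array(rbinom(16^3, 1, 0.1), c(16, 16, 16))
  xin <- digcsvnet:::input_block_internal(gray, cfg)
  ti <- aperm(target, c(3, 2, 1))
  loss_of <- function(m) {
    fw <- digcsvnet:::net_forward_internal(m, xin, keep_cache = FALSE)
    digcsvnet:::softmax_ce_internal(fw$logits, ti)$loss
  }
  fw <- digcsvnet:::net_forward_internal(model, xin, keep_cache = TRUE)
  ce <- digcsvnet:::softmax_ce_internal(fw$logits, ti)
  grads <- digcsvnet:::net_backward_internal(model, fw$cache, ce$glogits)

  get_leaf <- function(w, path) { for (kk in path) w <- w[[kk]]; w }
  bump_leaf <- function(w, path, idx, delta) {
    if (length(path) == 1L) {
      leaf <- w[[path[[1]]]]
      leaf[idx] <- leaf[idx] + delta
      w[[path[[1]]]] <- leaf
    } else {
      w[[path[[1]]]] <- bump_leaf(w[[path[[1]]]], path[-1], idx, delta)
    }
    w
  }
  # one representative weight from each part of the network
  picks <- list(list("enc", 2L, 1L, "w"), list("down", 1L, "w"),
                list("cbam", 2L, "cam", "w2"), list("cbam", 3L, "sam", "w"),
                list("up", 4L, "w"), list("dec", 1L, 1L, "w"),
                list("head", "w"))
  h <- 1e-3
  for (path in picks) {
    g <- get_leaf(grads, path)
    idx <- which.max(abs(g))           # check the largest-gradient entry
    mp <- model; mm <- model
    mp$weights <- bump_leaf(mp$weights, path, idx, h)
    mm$weights <- bump_leaf(mm$weights, path, idx, -h)
    num <- (loss_of(mp) - loss_of(mm)) / (2 * h)
    expect_equal(g[idx], num, tolerance = 0.05,
                 label = paste("gradient at",
                               paste(unlist(path), collapse = "/")))
  }
})

test_that("Adam takes bias-corrected steps of the expected first-step size", {
  w <- list(a = matrix(c(1, -2), 1))
  g <- list(a = matrix(c(0.5, -0.1), 1))
  st <- digcsvnet:::adam_state(w)
  up <- digcsvnet:::adam_step(w, g, st, lr = 0.01)
  # after bias correction the first step is lr * sign(g) (up to eps)
  expect_equal(as.vector(up$weights$a), c(1 - 0.01, -2 + 0.01),
               tolerance = 1e-4)
  expect_equal(up$state$t, 1L)
  # a second identical-gradient step continues in the same direction
  up2 <- digcsvnet:::adam_step(up$weights, g, up$state, lr = 0.01)
  expect_lt(up2$weights$a[1], up$weights$a[1])
  expect_gt(up2$weights$a[2], up$weights$a[2])
})
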