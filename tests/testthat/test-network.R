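test_that("the input block stacks normalized planes then gray copies", {
  cfg <- network_config(base_channels = 8L, input_patch = c(16L, 16L, 16L))
  g <- array(200L, c(4, 4, 4))
  x <- build_input_block(g, cfg)
  expect_identical(dim(x), c(1L, 8L, 4L, 4L, 4L))
  # 200 = 128 + 64 + 8: planes (normalized by their bit values) are 1, 1, 0, 0
  expect_equal(unique(as.vector(x[1, 1, , , ])), 1)
  expect_equal(unique(as.vector(x[1, 2, , , ])), 1)
  expect_true(all(x[1, 3:4, , , ] == 0))
  # remaining channels are gray / 255 copies
  for (j in 5:8) expect_equal(unique(as.vector(x[1, j, , , ])), 200 / 255)

  z <- build_input_block(array(0L, c(4, 4, 4)), cfg)
  expect_true(all(z == 0))
  expect_error(build_input_block(array(300L, c(4, 4, 4)), cfg), "\\[0, 255\\]")
})

test_that("disabling separation replicates the gray channel", {
  cfg <- network_config(base_channels = 8L, use_digsep = FALSE,
                        input_patch = c(16L, 16L, 16L))
  set.seed(2)
  g <- array(sample(0:255, 64, TRUE), c(4, 4, 4))
  x <- build_input_block(g, cfg)
  for (j in 1:8) {
    expect_equal(array(x[1, j, , , ], c(4, 4, 4)), g / 255, tolerance = 1e-12)
  }
})

test_that("the doubled layout repeats its first half of channels", {
  cfg <- network_config(base_channels = 16L, input_layout = "planes_orig_x2",
                        input_patch = c(16L, 16L, 16L))
  set.seed(3)
  g <- array(sample(0:255, 64, TRUE), c(4, 4, 4))
  x <- build_input_block(g, cfg)
  expect_equal(x[1, 1:8, , , ], x[1, 9:16, , , ], tolerance = 1e-12)
})

test_that("ELU matches its closed forms and is monotone", {
  expect_equal(elu(0), 0)
  expect_equal(elu(2), 2)
  expect_equal(elu(-1), exp(-1) - 1, tolerance = 1e-12)
  expect_equal(elu(-1e6), -1, tolerance = 1e-6)        # saturates at -alpha
  expect_equal(elu(-1, alpha = 0.5), 0.5 * (exp(-1) - 1), tolerance = 1e-12)
  g <- seq(-5, 5, by = 0.01)
  expect_true(all(diff(elu(g)) > 0))
  expect_true(all(elu(g) > -1))
})

test_that("forward pass has the right shape, is deterministic, sums to one", {
  cfg <- network_config(base_channels = 8L, input_patch = c(16L, 16L, 16L))
  model <- build_network(cfg, seed = 3)
  set.seed(8)
  g <- array(sample(0:255, 16^3, TRUE), c(16, 16, 16))
  logits <- net_forward(model, g)
  expect_identical(dim(logits), c(1L, 2L, 16L, 16L, 16L))
  expect_true(all(is.finite(logits)))
  expect_identical(net_forward(model, g), logits)       # repeat: bit-identical
  p <- softmax_classes(logits)
  expect_equal(apply(p, c(1, 3, 4, 5), sum),
               array(1, c(1, 16, 16, 16)), tolerance = 1e-6)
  expect_true(all(p > 0 & p < 1))
  expect_error(net_forward(model, array(0L, c(8, 8, 8))), "input_patch")
})

test_that("parameter count matches independent arithmetic", {
  cfg <- network_config(base_channels = 8L, input_patch = c(16L, 16L, 16L))
  model <- build_network(cfg, seed = 1)
  ch <- 8L * 2L^(0:4)
  sc <- c(1, 2, 3, 3, 3)
  expected <- 0
  for (li in 1:5) expected <- expected + sc[li] * (27 * ch[li]^2 + ch[li])
  for (li in 1:4) {
    expected <- expected + 8 * ch[li] * ch[li + 1] + ch[li + 1]      # down
    h <- max(1, ch[li + 1] %/% 16)                                    # cbam
    expected <- expected + 2 * h * ch[li + 1] + ch[li + 1] + 54 + 1
    cin <- if (li == 4) ch[5] else 2 * ch[li + 1]                     # up
    expected <- expected + cin * 8 * ch[li] + ch[li]
    expected <- expected + sc[li] * (27 * (2 * ch[li])^2 + 2 * ch[li]) # dec
  }
  expected <- expected + 2 * ch[1] * 2 + 2                            # head
  expect_equal(count_parameters(model), expected)

  # attention contributes exactly its own parameters
  no_cbam <- build_network(variant_config("vnet_elu_digsep", cfg), seed = 1)
  cbam_n <- sum(vapply(2:5, function(i)
    2 * max(1, ch[i] %/% 16) * ch[i] + ch[i] + 55, 0))
  expect_equal(count_parameters(model) - count_parameters(no_cbam), cbam_n)
  # doubling the width grows the count
  wide <- build_network(network_config(base_channels = 16L,
                                       input_patch = c(16L, 16L, 16L)))
  expect_gt(count_parameters(wide), count_parameters(model))
  # PReLU adds one slope per channel of every non-head conv
  vnet <- build_network(variant_config("vnet", cfg), seed = 1)
  slopes <- sum(sc * ch) + sum(ch[2:5]) + sum(ch[1:4]) +
    sum(sc[1:4] * 2 * ch[1:4])
  expect_equal(count_parameters(vnet) - count_parameters(no_cbam), slopes)
})

test_that("configuration invariants are enforced", {
  expect_error(network_config(base_channels = 4L), ">= n_planes_used \\+ 1")
  expect_error(network_config(input_patch = c(8L, 96L, 96L)), "collapses")
  expect_error(network_config(kernel_size = 4L), "odd")
  expect_error(network_config(stage_convs = c(1L, 2L)), "one entry per level")
  expect_error(network_config(elu_alpha = 0), "> 0")
  expect_error(variant_config("bogus"), "unknown variant")
  half_cfg <- network_config(base_channels = 6L,
                             input_layout = "planes_orig_x2",
                             input_patch = c(16L, 16L, 16L))
  expect_error(build_input_block(array(0L, c(4, 4, 4)), half_cfg),
               "base_channels >= 2")
})

test_that("one optimizer step on one cube reduces the loss", {
  cfg <- network_config(base_channels = 8L, input_patch = c(16L, 16L, 16L))
  model <- build_network(cfg, seed = 5)
  cube <- random_cube(41, shape = c(16L, 16L, 16L))
  tr <- train_network(model, list(cube),
                      train_config(batch_size = 1, max_steps = 3, seed = 5))
  expect_lt(tr$log$loss[3], tr$log$loss[1])
  expect_equal(tr$steps_run, 3)
})
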