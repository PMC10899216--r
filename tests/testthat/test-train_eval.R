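test_that("fold assignment is balanced, deterministic and seed-sensitive", {
  ids <- sprintf("s%03d", 1:100)
  f1 <- make_folds(ids, n_folds = 10, seed = 4)
  expect_equal(unname(table(f1$assignments)), rep(10L, 10),
               ignore_attr = TRUE)
  expect_setequal(names(f1$assignments), ids)
  f2 <- make_folds(ids, n_folds = 10, seed = 4)
  expect_identical(f1$assignments, f2$assignments)
  f3 <- make_folds(ids, n_folds = 10, seed = 5)
  expect_false(identical(f1$assignments, f3$assignments))
})

test_that("grouped folds keep all variants of a nodule together", {
  groups <- rep(sprintf("nod%02d", 1:12), each = 8)   # 12 nodules x 8 variants
  ids <- paste0(groups, "_v", rep(1:8, 12))
  fs <- make_folds(ids, n_folds = 4, seed = 2, groups = groups)
  for (g in unique(groups)) {
    folds <- fs$assignments[groups == g]
    expect_length(unique(folds), 1)
  }
  # group-level fold sizes differ by at most one (here: exactly 3 each)
  gf <- tapply(fs$assignments, groups, unique)
  expect_true(max(table(gf)) - min(table(gf)) <= 1)
  expect_error(make_folds(ids[1:8], n_folds = 4, groups = groups[1:8]),
               "at least 4 groups")
  expect_error(make_folds(ids, n_folds = 4, groups = groups[1:5]), "length")
})

test_that("the plateau schedule restores, drops the rate and stops on budget", {
  cfg <- network_config(base_channels = 8L, input_patch = c(16L, 16L, 16L))
  model <- build_network(cfg, seed = 2)
  cube <- random_cube(19, shape = c(16L, 16L, 16L))
  # min_delta so large that no epoch ever counts as an improvement after the
  # first, forcing the drop at epoch patience + 1 and the post-drop budget
  tc <- train_config(init_lr = 0.001, batch_size = 1, plateau_patience = 2,
                     plateau_min_delta = 10, post_restart_iterations = 3,
                     max_steps = 50, seed = 2)
  tr <- train_network(model, list(cube), tc)
  expect_equal(tr$stop_reason, "post_restart_budget")
  expect_equal(tr$steps_run, 6)                # 3 epochs + 3 budget steps
  expect_equal(tr$log$lr, c(rep(0.001, 3), rep(1e-4, 3)))
})

test_that("early stopping fires once the per-cube Dice target is met", {
  cfg <- network_config(base_channels = 8L, input_patch = c(16L, 16L, 16L))
  model <- build_network(cfg, seed = 2)
  cube <- random_cube(19, shape = c(16L, 16L, 16L))
  tc <- train_config(batch_size = 1, max_steps = 5, early_stop_dice = 0,
                     seed = 2)
  tr <- train_network(model, list(cube), tc)   # threshold 0: stops at once
  expect_equal(tr$stop_reason, "early_stop_dice")
  expect_equal(tr$steps_run, 1)
})

test_that("checkpoints restore a bit-identical forward pass", {
  cfg <- network_config(base_channels = 8L, input_patch = c(16L, 16L, 16L))
  model <- build_network(cfg, seed = 11)
  path <- file.path(tempdir(), "ck.rds")
  save_checkpoint(model, path, extra = list(note = "t"))
  back <- load_checkpoint(path)
  expect_identical(back$config, model$config)
  set.seed(1)
  g <- array(sample(0:255, 16^3, TRUE), c(16, 16, 16))
  expect_identical(net_forward(back, g), net_forward(model, g))
  expect_equal(count_parameters(back), count_parameters(model))
})

test_that("evaluation reports per-cube ids and mean aggregation", {
  cfg <- network_config(base_channels = 8L, input_patch = c(16L, 16L, 16L))
  model <- build_network(cfg, seed = 6)
  cubes <- list(random_cube(1, shape = c(16L, 16L, 16L)),
                random_cube(2, shape = c(16L, 16L, 16L)))
  rep <- evaluate_model(model, cubes)
  expect_s3_class(rep, "metrics_report")
  expect_equal(nrow(rep$per_sample), 2)
  expect_equal(rep$per_sample$id, c("rc1_nodule1", "rc2_nodule1"))
  expect_equal(rep$aggregate[["dice"]], mean(rep$per_sample$dice),
               tolerance = 1e-12)
  pm <- predict_mask(model, cubes[[1]]$image)
  expect_identical(dim(pm), c(16L, 16L, 16L))
  expect_true(is_binary_array(pm))
})

test_that("the ablation harness trains every variant under a shared setup", {
  cfg <- network_config(base_channels = 8L, input_patch = c(16L, 16L, 16L))
  cube <- random_cube(33, shape = c(16L, 16L, 16L))
  tc <- train_config(batch_size = 1, max_steps = 1, seed = 3)
  tab <- run_ablation(list(cube), cfg, tc, seed = 3)
  expect_equal(tab$model, c("vnet", "vnet_elu", "vnet_elu_digsep",
                            "vnet_elu_cbam", "full"))
  for (col in c("iou", "dsc", "sen", "ppv"))
    expect_true(all(tab[[col]] >= 0 & tab[[col]] <= 1))
  # the per-sample identity Dice = 2 IoU / (1 + IoU) holds row-wise here
  # because evaluation used a single cube
  expect_equal(tab$dsc, 2 * tab$iou / (1 + tab$iou), tolerance = 1e-12)
})

test_that("training configuration rejects invalid settings", {
  expect_error(train_config(init_lr = 0), "> 0")
  expect_error(train_config(batch_size = 0), ">= 1")
  expect_error(train_config(n_folds = 1), ">= 2")
  cfg <- network_config(base_channels = 8L, input_patch = c(16L, 16L, 16L))
  expect_error(train_network(build_network(cfg), list(), train_config()),
               "at least one")
})
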