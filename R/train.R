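#' Training configuration
#'
#' Optimization hyper-parameters: Adam at initial learning rate 0.001, batch
#' size 16, and a plateau schedule that automates the otherwise manual
#' procedure — when the monitored training loss stops improving, the best
#' weights are restored, the learning rate drops to 0.1x, and training
#' continues for a fixed 300 further iterations before stopping.
#'
#' @param init_lr initial learning rate (> 0).
#' @param batch_size cubes per optimizer step (>= 1). Memory scales with
#'   batch size; the scaled-down test profiles use 1.
#' @param plateau_patience epochs without improvement before the learning-rate
#'   drop fires.
#' @param plateau_factor multiplier applied to the learning rate at the drop.
#' @param plateau_min_delta minimum loss improvement that counts.
#' @param post_restart_iterations optimizer steps to run after the drop
#'   ("iterations" are read as optimizer steps, not epochs).
#' @param max_steps hard cap on total optimizer steps.
#' @param n_folds folds for cross-validation (>= 2).
#' @param seed RNG seed for batch sampling.
#' @param early_stop_dice optional: stop once every training cube's most
#'   recent within-batch Dice reaches this value (computed from the forward
#'   passes already made, so it costs nothing extra).
#' @param verbose print a line per epoch.
#' @return Object of class `train_config`.
#' @export
train_config <- function(init_lr = 0.001, batch_size = 16L,
                         plateau_patience = 10L, plateau_factor = 0.1,
                         plateau_min_delta = 1e-4,
                         post_restart_iterations = 300L,
                         max_steps = 300L, n_folds = 10L, seed = 1L,
                         early_stop_dice = NULL, verbose = FALSE) {
  if (init_lr <= 0) stopf("init_lr must be > 0")
  if (batch_size < 1) stopf("batch_size must be >= 1")
  if (n_folds < 2) stopf("n_folds must be >= 2")
  structure(list(init_lr = init_lr, batch_size = as.integer(batch_size),
                 plateau_patience = as.integer(plateau_patience),
                 plateau_factor = plateau_factor,
                 plateau_min_delta = plateau_min_delta,
                 post_restart_iterations = as.integer(post_restart_iterations),
                 max_steps = as.integer(max_steps),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 early_stop_dice = early_stop_dice, verbose = verbose),
            class = "train_config")
}

#' Grouped k-fold assignment
#'
#' Seeded shuffle of the group keys followed by round-robin assignment, so
#' fold sizes (in groups) differ by at most one and the split is deterministic
#' per seed. All samples sharing a group key — e.g. every augmented variant of
#' one source nodule — land in the same fold, preventing augmentation leakage
#' between training and test folds.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param n_folds number of folds (default 10).
#' @param seed shuffle seed.
#' @param groups optional group key per sample (default: each sample is its
#'   own group).
#' @return Object of class `fold_split`: list with `assignments` (named
#'   integer vector, fold index 1..n_folds per sample) and `n_folds`.
#' @export
make_folds <- function(sample_ids, n_folds = 10L, seed = 1L, groups = NULL) {
  groups <- groups %||% sample_ids
  if (length(groups) != length(sample_ids))
    stopf("groups must match sample_ids in length")
  ug <- unique(groups)
  if (length(ug) < n_folds)
    stopf("need at least %d groups for %d folds (have %d)",
          n_folds, n_folds, length(ug))
  set.seed(seed)
  ug <- ug[sample.int(length(ug))]
  gf <- setNames(rep_len(seq_len(n_folds), length(ug)), ug)
  assignments <- setNames(as.integer(gf[as.character(groups)]), sample_ids)
  structure(list(assignments = assignments, n_folds = as.integer(n_folds)),
            class = "fold_split")
}

# Dice of an argmax prediction against a target, both in internal layout.
dice_from_logits <- function(logits, target) {
  d <- dim(logits)
  nv <- prod(d[1:3])
  lm <- matrix(logits, nv, d[4])
  pred <- lm[, 2] > lm[, 1]
  tv <- as.logical(target)
  tp <- sum(pred & tv); fp <- sum(pred & !tv); fn <- sum(!pred & tv)
  if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
}

#' Train the segmentation network
#'
#' Minimizes per-voxel softmax cross-entropy with Adam. Epochs are defined as
#' `ceiling(n_cubes / batch_size)` steps; the epoch-mean training loss is the
#' plateau monitor. When it fails to improve by `plateau_min_delta` for
#' `plateau_patience` consecutive epochs, the best weights are restored, the
#' learning rate is multiplied by `plateau_factor`, and training continues for
#' `post_restart_iterations` further steps (once). Training always stops at
#' `max_steps`.
#'
#' @param model a [build_network()] model.
#' @param cubes list of [nodule_cube()] training samples.
#' @param config a [train_config()].
#' @return Object of class `train_result`: list with the trained `model`,
#'   `log` (data.frame: step, epoch, loss, lr, batch_dice), `steps_run` and
#'   `stop_reason`.
#' @export
train_network <- function(model, cubes, config = train_config()) {
  n <- length(cubes)
  if (n < 1) stopf("need at least one training cube")
  cf <- model$config
  targets <- lapply(cubes, function(cb) aperm(cb$label, c(3, 2, 1)))
  set.seed(config$seed)
  state <- adam_state(model$weights)
  lr <- config$init_lr
  B <- min(config$batch_size, n)
  steps_per_epoch <- ceiling(n / B)
  best_loss <- Inf; best_weights <- model$weights
  bad_epochs <- 0L; dropped <- FALSE; post_budget <- NA_integer_
  last_dice <- rep(NA_real_, n)
  log_rows <- vector("list", config$max_steps)
  epoch <- 1L; epoch_losses <- c()
  stop_reason <- "max_steps"
  step <- 0L

  while (step < config$max_steps) {
    step <- step + 1L
    batch <- if (B == n) seq_len(n) else sample.int(n, B)
    grads <- NULL
    loss <- 0
    bdice <- 0
    for (i in batch) {
      xin <- input_block_internal(cubes[[i]]$image$voxels, cf)
      fw <- net_forward_internal(model, xin, keep_cache = TRUE)
      ce <- softmax_ce_internal(fw$logits, targets[[i]])
      if (!is.finite(ce$loss))
        stopf("non-finite loss at step %d (sample %d); aborting", step, i)
      loss <- loss + ce$loss / length(batch)
      last_dice[i] <- dice_from_logits(fw$logits, targets[[i]])
      bdice <- bdice + last_dice[i] / length(batch)
      g <- net_backward_internal(model, fw$cache, ce$glogits)
      g <- map_leaves(g, function(x) x / length(batch))
      grads <- if (is.null(grads)) g else map2_leaves(grads, g, `+`)
    }
    upd <- adam_step(model$weights, grads, state, lr)
    model$weights <- upd$weights
    state <- upd$state
    log_rows[[step]] <- data.frame(step = step, epoch = epoch, loss = loss,
                                   lr = lr, batch_dice = bdice)
    epoch_losses <- c(epoch_losses, loss)

    if (!is.null(config$early_stop_dice) && !anyNA(last_dice) &&
        min(last_dice) >= config$early_stop_dice) {
      stop_reason <- "early_stop_dice"
      break
    }
    if (dropped) {
      post_budget <- post_budget - 1L
      if (post_budget <= 0L) { stop_reason <- "post_restart_budget"; break }
    }
    if (step %% steps_per_epoch == 0L) {
      eloss <- mean(epoch_losses)
      if (config$verbose)
        message(sprintf("epoch %d  loss %.5f  lr %g", epoch, eloss, lr))
      if (eloss < best_loss - config$plateau_min_delta) {
        best_loss <- eloss
        best_weights <- model$weights
        bad_epochs <- 0L
      } else if (!dropped) {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= config$plateau_patience) {
          model$weights <- best_weights
          lr <- lr * config$plateau_factor
          dropped <- TRUE
          post_budget <- config$post_restart_iterations
        }
      }
      epoch <- epoch + 1L
      epoch_losses <- c()
    }
  }
  structure(list(model = model,
                 log = do.call(rbind, log_rows[seq_len(step)]),
                 steps_run = step, stop_reason = stop_reason),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("<train_result> %d step(s), final loss %.5f, final batch Dice %.4f (%s)\n",
              x$steps_run, x$log$loss[x$steps_run],
              x$log$batch_dice[x$steps_run], x$stop_reason))
  invisible(x)
}

#' Predict a binary mask for one gray patch
#'
#' Argmax over the class channel of the network output.
#'
#' @param model a [build_network()] model.
#' @param gray a [gray_volume()] (or bare (z, y, x) gray array) matching the
#'   configured patch shape.
#' @return Binary 3D array (z, y, x).
#' @export
predict_mask <- function(model, gray) {
  g <- if (inherits(gray, "gray_volume")) gray$voxels else gray
  xin <- input_block_internal(g, model$config)
  fw <- net_forward_internal(model, xin, keep_cache = FALSE)
  d <- dim(fw$logits)
  lm <- matrix(fw$logits, prod(d[1:3]), d[4])
  pred <- array(as.double(lm[, 2] > lm[, 1]), d[1:3])   # (nx, ny, nz)
  aperm(pred, c(3, 2, 1))
}

#' Evaluate a model on nodule cubes
#'
#' Argmax prediction per cube, voxel confusion counts, and the four metrics
#' per sample plus their unweighted mean.
#'
#' @param model a [build_network()] model.
#' @param cubes list of [nodule_cube()].
#' @return A [metrics_report()].
#' @export
evaluate_model <- function(model, cubes) {
  if (length(cubes) < 1) stopf("need at least one cube")
  preds <- lapply(cubes, function(cb) predict_mask(model, cb$image))
  truths <- lapply(cubes, function(cb) cb$label)
  ids <- vapply(cubes, function(cb)
    sprintf("%s_nodule%d", cb$source_case, cb$nodule_index), "")
  metrics_report(preds, truths, ids)
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds the weights, the network configuration and the package
#' version; loading restores a model whose forward pass is bit-identical to
#' the saved one.
#'
#' @param model a [build_network()] model.
#' @param path checkpoint file path (RDS).
#' @param extra optional list stored alongside (e.g. optimizer state or a run
#'   manifest).
#' @return `path` invisibly (save); the restored `seg_network` (load).
#' @export
save_checkpoint <- function(model, path, extra = NULL) {
  saveRDS(list(weights = model$weights, config = model$config,
               version = as.character(utils::packageVersion("digcsvnet")),
               extra = extra), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  structure(list(config = ck$config, weights = ck$weights),
            class = "seg_network")
}

#' Ablation harness
#'
#' Trains and evaluates the standard model variants under identical seeds and
#' training configuration: the plain V-Net baseline (PReLU activations, gray
#' replication input, no attention), the ELU swap, ELU + threshold separation,
#' ELU + attention, and the full model.
#'
#' @param cubes training cubes.
#' @param base_config a [network_config()] supplying everything except the
#'   variant flags.
#' @param tconf a [train_config()].
#' @param variants subset of `c("vnet", "vnet_elu", "vnet_elu_digsep",
#'   "vnet_elu_cbam", "full")`.
#' @param eval_cubes cubes to evaluate on (default: the training cubes).
#' @param seed weight-initialization seed shared by all variants.
#' @return data.frame with one row per variant: model, iou, dsc, sen, ppv
#'   (fractions in \[0, 1\]).
#' @export
run_ablation <- function(cubes, base_config = network_config(),
                         tconf = train_config(),
                         variants = c("vnet", "vnet_elu", "vnet_elu_digsep",
                                      "vnet_elu_cbam", "full"),
                         eval_cubes = NULL, seed = 1L) {
  eval_cubes <- eval_cubes %||% cubes
  rows <- lapply(variants, function(v) {
    cfg <- variant_config(v, base_config)
    model <- build_network(cfg, seed = seed)
    tr <- train_network(model, cubes, tconf)
    rep <- evaluate_model(tr$model, eval_cubes)
    a <- rep$aggregate
    data.frame(model = v, iou = a[["iou"]], dsc = a[["dice"]],
               sen = a[["sen"]], ppv = a[["ppv"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Variant flags for the ablation harness
#'
#' @param variant one of `"vnet"`, `"vnet_elu"`, `"vnet_elu_digsep"`,
#'   `"vnet_elu_cbam"`, `"full"`.
#' @param base a [network_config()] to modify.
#' @return The modified [network_config()].
#' @export
variant_config <- function(variant, base = network_config()) {
  flags <- switch(variant,
    vnet            = list(activation = "prelu", use_digsep = FALSE, use_cbam = FALSE),
    vnet_elu        = list(activation = "elu",   use_digsep = FALSE, use_cbam = FALSE),
    vnet_elu_digsep = list(activation = "elu",   use_digsep = TRUE,  use_cbam = FALSE),
    vnet_elu_cbam   = list(activation = "elu",   use_digsep = FALSE, use_cbam = TRUE),
    full            = list(activation = "elu",   use_digsep = TRUE,  use_cbam = TRUE),
    stopf("unknown variant '%s'", variant))
  args <- unclass(base)
  args[names(flags)] <- flags
  do.call(network_config, args)
}
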