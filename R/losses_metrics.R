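#' Multi-class cross-entropy loss
#'
#' `L = -(1/N) * sum_i sum_j y_ij * log(p_ij)` over N voxel-samples and C
#' classes, where `y` is the one-hot truth and `p` the predicted class
#' probabilities. Probabilities are clamped at 1e-12 inside the log for
#' numerical safety, so an (incorrect) zero-probability prediction yields a
#' large finite loss rather than `Inf`.
#'
#' @param probs N x C matrix (or array whose last dimension is the class axis)
#'   of per-sample class probabilities, rows summing to 1.
#' @param targets integer vector of N true class indices in `0..C-1`
#'   (class 1 = foreground for binary segmentation, matching label masks).
#' @return Non-negative scalar loss; 0 iff the prediction is exactly one-hot
#'   correct everywhere.
#' @export
cross_entropy_loss <- function(probs, targets) {
  if (!is.matrix(probs)) {
    d <- dim(probs)
    probs <- matrix(probs, ncol = d[length(d)])
  }
  targets <- as.integer(targets)
  n <- nrow(probs); C <- ncol(probs)
  if (length(targets) != n)
    stopf("probs has %d rows but targets has %d entries", n, length(targets))
  if (any(targets < 0) || any(targets >= C))
    stopf("targets must lie in 0..%d", C - 1)
  p_true <- probs[cbind(seq_len(n), targets + 1L)]
  -mean(log(pmax(p_true, 1e-12)))
}

#' Voxel-wise confusion counts between two binary masks
#'
#' @param pred,truth binary 3D arrays (or vectors) of equal shape.
#' @return Object of class `confusion_counts`: list with integer `TP`, `FP`,
#'   `FN`, `TN` summing to the voxel count.
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stopf("pred and truth shapes differ")
  if (!is_binary_array(pred) || !is_binary_array(truth))
    stopf("masks must be binary (0/1)")
  p <- as.logical(pred); t <- as.logical(truth)
  structure(list(TP = sum(p & t), FP = sum(p & !t),
                 FN = sum(!p & t), TN = sum(!p & !t)),
            class = "confusion_counts")
}

#' Segmentation metrics from confusion counts
#'
#' Dice = 2TP/(2TP+FP+FN), IoU = TP/(TP+FP+FN), SEN = TP/(TP+FN),
#' PPV = TP/(TP+FP); all in \[0, 1\]. Zero-denominator convention: if truth
#' and prediction are both empty every metric is 1 (the masks agree
#' perfectly); if exactly one is empty, Dice and IoU are 0 and the undefined
#' ratio (SEN or PPV) is 0, so degenerate samples never inject NaN into
#' aggregate means.
#'
#' @param counts a `confusion_counts` (or list with TP/FP/FN fields).
#' @return Named numeric vector `c(dice, iou, sen, ppv)`.
#' @export
metrics_from_counts <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN
  if (any(c(TP, FP, FN) < 0)) stopf("confusion counts must be non-negative")
  if (TP + FP + FN == 0) return(c(dice = 1, iou = 1, sen = 1, ppv = 1))
  ratio <- function(num, den) if (den == 0) 0 else num / den
  c(dice = ratio(2 * TP, 2 * TP + FP + FN),
    iou  = ratio(TP, TP + FP + FN),
    sen  = ratio(TP, TP + FN),
    ppv  = ratio(TP, TP + FP))
}

#' Per-sample and aggregated metrics for paired mask lists
#'
#' Computes confusion counts and the four metrics for each prediction/truth
#' pair and an unweighted mean over samples. Aggregation is a mean of
#' per-sample ratios, not a pooled-voxel metric, and Dice = 2 IoU / (1 + IoU)
#' holds per sample but not for the aggregate means.
#'
#' @param preds,truths lists of binary 3D arrays, pairwise congruent.
#' @param sample_ids optional identifiers (defaults to 1..n).
#' @return Object of class `metrics_report`: list with `per_sample`
#'   (data.frame: id, dice, iou, sen, ppv, TP, FP, FN, TN) and `aggregate`
#'   (named means of the four metrics).
#' @export
metrics_report <- function(preds, truths, sample_ids = NULL) {
  if (length(preds) != length(truths)) stopf("pred/truth counts differ")
  n <- length(preds)
  sample_ids <- sample_ids %||% as.character(seq_len(n))
  rows <- lapply(seq_len(n), function(i) {
    cc <- confusion_counts(preds[[i]], truths[[i]])
    m <- metrics_from_counts(cc)
    data.frame(id = sample_ids[i], dice = m["dice"], iou = m["iou"],
               sen = m["sen"], ppv = m["ppv"], TP = cc$TP, FP = cc$FP,
               FN = cc$FN, TN = cc$TN, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  per_sample <- do.call(rbind, rows)
  aggregate <- colMeans(per_sample[, c("dice", "iou", "sen", "ppv")])
  structure(list(per_sample = per_sample, aggregate = aggregate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<metrics_report> %d sample(s); mean Dice %.4f, IoU %.4f, SEN %.4f, PPV %.4f\n",
              nrow(x$per_sample), a["dice"], a["iou"], a["sen"], a["ppv"]))
  invisible(x)
}

#' Write a metrics report to CSV and JSON
#'
#' CSV holds one row per sample plus an `aggregate` row (unweighted mean over
#' samples, noted in the header comment); the JSON summary holds the
#' aggregate metrics and sample count.
#'
#' @param report a [metrics_report()].
#' @param csv_path,json_path destinations (either may be `NULL` to skip).
#' @return `report`, invisibly.
#' @export
write_metrics <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    agg <- data.frame(id = "aggregate",
                      dice = report$aggregate["dice"], iou = report$aggregate["iou"],
                      sen = report$aggregate["sen"], ppv = report$aggregate["ppv"],
                      TP = NA, FP = NA, FN = NA, TN = NA, row.names = NULL)
    con <- file(csv_path, "w")
    writeLines("# aggregate row = unweighted mean of per-sample metrics", con)
    utils::write.csv(rbind(report$per_sample, agg), con, row.names = FALSE)
    close(con)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(n_samples = nrow(report$per_sample),
                              aggregate = as.list(report$aggregate)),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
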