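#' Pixel-wise cross-entropy loss
#'
#' For a pixel with score vector x and true class c the loss is
#' `-x[c] + log(sum_j exp(x[j]))`, averaged over all pixels of the batch.
#' Evaluated with the log-sum-exp stabilization, so arbitrarily large logits
#' do not overflow. The loss is invariant to adding a constant to all logits
#' of a pixel.
#'
#' @param logits either a length-K numeric vector (single pixel) or an
#'   H x W x K (x N) array of per-pixel class scores.
#' @param labels integer class labels in 0..K-1; a scalar for the vector
#'   form, an H x W (x N) array otherwise.
#' @return non-negative scalar, the mean per-pixel loss.
#' @export
cross_entropy_loss <- function(logits, labels) {
  if (is.null(dim(logits))) {
    logits <- array(logits, c(1, 1, length(logits), 1))
    labels <- array(as.integer(labels), c(1, 1, 1))
  }
  d <- dim(logits)
  if (length(d) == 3L) dim(logits) <- c(d, 1L)
  d <- dim(logits)
  if (length(labels) != d[1] * d[2] * d[4])
    stop("labels do not match logits shape", call. = FALSE)
  lab <- as.integer(labels)
  if (any(lab < 0L | lab >= d[3]))
    stop("labels must lie in 0..", d[3] - 1L, call. = FALSE)
  M <- matrix(aperm(logits, c(1, 2, 4, 3)), ncol = d[3])
  mx <- as.vector(Reduce(pmax, asplit(M, 2)))
  lse <- mx + log(rowSums(exp(M - mx)))
  mean(lse - M[cbind(seq_len(nrow(M)), lab + 1L)])
}

#' Confusion counts for one class
#'
#' Exact pixel tallies of true/false positives/negatives of `pred` against
#' `truth`, treating `positive_class` as the positive label.
#'
#' @param pred,truth integer mask matrices over \{0, 1\}, same shape.
#' @param positive_class the label counted as positive (default 1, ridge).
#' @return a `confusion_counts` list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, truth, positive_class = 1L) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must have identical shape", call. = FALSE)
  check_labels(pred); check_labels(truth)
  pp <- pred == positive_class
  tp_ <- truth == positive_class
  structure(list(
    tp = sum(pp & tp_), fp = sum(pp & !tp_),
    fn = sum(!pp & tp_), tn = sum(!pp & !tp_)
  ), class = "confusion_counts")
}

check_labels <- function(m) {
  if (!all(m %in% c(0L, 1L)))
    stop("mask labels must be in {0, 1}", call. = FALSE)
  invisible(m)
}

#' Segmentation metrics from confusion counts
#'
#' Overall pixel accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`,
#' recall `TP/(TP+FN)`, and intersection-over-union `TP/(TP+FP+FN)`, each
#' as a percentage.
#'
#' When a class is entirely absent from both prediction and truth
#' (`TP+FP+FN = 0`) its precision, recall, and IoU are defined as 100
#' (the class is perfectly absent); this keeps per-image averaging
#' well-defined on background-only tiles. A zero precision or recall
#' denominator with disagreement present yields 0.
#'
#' @param c a `confusion_counts` object (or list with tp/fp/fn/tn).
#' @return named list `acc`, `pr`, `re`, `iou`, percentages in `[0, 100]`.
#' @export
metrics_from_counts <- function(c) {
  tp <- c$tp; fp <- c$fp; fn <- c$fn; tn <- c$tn
  total <- tp + fp + fn + tn
  if (total <= 0) stop("no pixels evaluated", call. = FALSE)
  acc <- 100 * (tp + tn) / total
  if (tp + fp + fn == 0) {
    pr <- re <- iou <- 100
  } else {
    pr <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
    re <- if (tp + fn == 0) 0 else 100 * tp / (tp + fn)
    iou <- 100 * tp / (tp + fp + fn)
  }
  list(acc = acc, pr = pr, re = re, iou = iou)
}

# per-image metric row: both-class IoU (mIoU) plus ridge-class pr/re/iou
image_metrics <- function(pred, truth) {
  pos <- metrics_from_counts(confusion_counts(pred, truth, 1L))
  neg <- metrics_from_counts(confusion_counts(pred, truth, 0L))
  c(acc = pos$acc, pr = pos$pr, re = pos$re, iou = pos$iou,
    miou = (pos$iou + neg$iou) / 2)
}

#' Evaluate a model over a dataset
#'
#' Computes accuracy, precision, recall, IoU (ridge class), and mIoU (mean
#' IoU over background and ridge) for every image, then aggregates. The
#' default `per_image_mean` aggregation averages the per-image metrics;
#' `pooled` sums confusion counts over all pixels first.
#'
#' @param model an [aspnet()] model, or a function `f(image) -> mask` (used
#'   as an oracle predictor in tests).
#' @param dataset a `dataset_index`, or a list of entries each holding
#'   `image` and `mask`.
#' @param split which dataset split to evaluate (`"val"`, `"train"`, or
#'   `"all"`); ignored for plain entry lists.
#' @param aggregation `"per_image_mean"` or `"pooled"`.
#' @return a `metric_report`: `per_image` data frame plus `aggregate` named
#'   vector, and the aggregation used.
#' @export
evaluate_dataset <- function(model, dataset, split = "val",
                             aggregation = c("per_image_mean", "pooled")) {
  aggregation <- match.arg(aggregation)
  entries <- dataset_entries(dataset, split)
  if (length(entries) == 0L) stop("no images to evaluate", call. = FALSE)
  predictor <- if (is.function(model)) model else
    function(img) predict(model, img)
  rows <- matrix(NA_real_, length(entries), 5,
                 dimnames = list(NULL, c("acc", "pr", "re", "iou", "miou")))
  pooled <- list(pos = c(tp = 0, fp = 0, fn = 0, tn = 0),
                 neg = c(tp = 0, fp = 0, fn = 0, tn = 0))
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    pred <- predictor(e$image)
    rows[i, ] <- image_metrics(pred, e$mask)
    for (cls in c("pos", "neg")) {
      cc <- confusion_counts(pred, e$mask, if (cls == "pos") 1L else 0L)
      pooled[[cls]] <- pooled[[cls]] +
        c(tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn)
    }
  }
  aggregate <- if (aggregation == "per_image_mean") {
    colMeans(rows)
  } else {
    mp <- metrics_from_counts(as.list(pooled$pos))
    mn <- metrics_from_counts(as.list(pooled$neg))
    c(acc = mp$acc, pr = mp$pr, re = mp$re, iou = mp$iou,
      miou = (mp$iou + mn$iou) / 2)
  }
  structure(list(per_image = as.data.frame(rows), aggregate = aggregate,
                 aggregation = aggregation, n_images = length(entries)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(
    "<metric_report> %d images (%s)\n  Acc %.1f%% | Pr %.1f%% | Re %.1f%% | IoU %.1f%% | mIoU %.1f%%\n",
    x$n_images, x$aggregation, a["acc"], a["pr"], a["re"], a["iou"],
    a["miou"]))
  invisible(x)
}

#' Write a metric report as a machine-readable table
#'
#' One row per image plus an `aggregate` row, full precision.
#'
#' @param report a `metric_report`.
#' @param path output CSV path.
#' @export
write_metric_report <- function(report, path) {
  df <- report$per_image
  df$image <- seq_len(nrow(df))
  agg <- as.data.frame(as.list(report$aggregate))
  agg$image <- NA_integer_
  out <- rbind(df, agg)
  out$row <- c(as.character(seq_len(nrow(df))), "aggregate")
  utils::write.csv(out[, c("row", "acc", "pr", "re", "iou", "miou")], path,
                   row.names = FALSE)
  invisible(path)
}

# normalize dataset-ish things into a list of in-memory entries
dataset_entries <- function(dataset, split = "all") {
  if (inherits(dataset, "dataset_index")) {
    idx <- seq_len(nrow(dataset$entries))
    if (split != "all") idx <- idx[dataset$entries$split == split]
    lapply(idx, function(i) load_entry(dataset, i))
  } else if (is.list(dataset)) {
    keep <- if (split == "all") dataset else
      Filter(function(e) is.null(e$split) || e$split == split, dataset)
    keep
  } else stop("unsupported dataset object", call. = FALSE)
}
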