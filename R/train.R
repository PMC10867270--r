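#' Training configuration
#'
#' The training protocol: plain stochastic gradient descent minimizing the
#' pixel-wise cross-entropy, starting learning rate 0.01, batch size 4,
#' 100 epochs, 512x512 inputs. Momentum, weight decay, and learning-rate
#' scheduling are off by default (exposed but not part of the protocol).
#'
#' @param learning_rate SGD step size (> 0; 0 allowed for a null-update
#'   sanity run).
#' @param batch_size images per SGD step.
#' @param epochs passes over the training split.
#' @param input_size expected tile edge length in pixels.
#' @param seed integer seed fixing the shuffling stream.
#' @param checkpoint_dir directory for `last.ckpt` / `best.ckpt` and the
#'   history table; `NULL` disables checkpointing.
#' @param momentum,weight_decay optional SGD extensions, default 0.
#' @return a `train_config` object.
#' @export
train_config <- function(learning_rate = 0.01, batch_size = 4L,
                         epochs = 100L, input_size = 512L, seed = 42L,
                         checkpoint_dir = NULL, momentum = 0,
                         weight_decay = 0) {
  if (learning_rate < 0) stop("learning_rate must be >= 0", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 input_size = as.integer(input_size),
                 seed = as.integer(seed), checkpoint_dir = checkpoint_dir,
                 momentum = momentum, weight_decay = weight_decay),
            class = "train_config")
}

sgd_step <- function(params, lr, momentum = 0, weight_decay = 0,
                     buffers = NULL) {
  for (n in names(params)) {
    p <- params[[n]]
    if (is.null(p$grad)) next
    g <- p$grad
    if (weight_decay > 0) g <- g + weight_decay * p$value
    if (momentum > 0) {
      b <- buffers[[n]]
      b <- if (is.null(b)) g else momentum * b + g
      buffers[[n]] <- b
      g <- b
    }
    p$value <- p$value - lr * g
    p$grad <- NULL
  }
  buffers
}

stack_batch <- function(entries) {
  d <- dim(entries[[1]]$image)
  n <- length(entries)
  imgs <- array(0, c(d[1], d[2], d[3], n))
  labs <- array(0L, c(d[1], d[2], n))
  for (i in seq_len(n)) {
    imgs[, , , i] <- entries[[i]]$image
    labs[, , i] <- entries[[i]]$mask
  }
  list(images = imgs, labels = labs)
}

#' Train the segmentation network
#'
#' SGD on the pixel-wise cross-entropy over the training split, with
#' per-epoch validation. Each epoch records the mean training loss and the
#' validation accuracy/mIoU; the epoch with the highest validation mIoU is
#' tracked as the best model. Runs are deterministic given the config seed.
#'
#' @param model an [aspnet()] model (updated in place and also returned).
#' @param dataset a `dataset_index` from [generate_dataset()] /
#'   [read_dataset_index()], or a list of entries with `image`, `mask`,
#'   `split` fields; must contain non-empty `train` and `val` splits.
#' @param cfg a [train_config()].
#' @param verbose print a one-line summary per epoch.
#' @return list with `model` (final weights), `best_model` (weights at the
#'   best validation mIoU), and `history` (data frame: epoch, train_loss,
#'   val_acc, val_miou; attribute `best_epoch`).
#' @export
train <- function(model, dataset, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "aspnet"), inherits(cfg, "train_config"))
  train_set <- dataset_entries(dataset, "train")
  val_set <- dataset_entries(dataset, "val")
  if (length(train_set) == 0L || length(val_set) == 0L)
    stop("dataset needs non-empty train and val splits", call. = FALSE)
  params <- model_parameters(model)
  buffers <- if (cfg$momentum > 0) new.env(parent = emptyenv()) else NULL
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_acc = numeric(), val_miou = numeric())
  best <- list(miou = -Inf, epoch = NA_integer_)
  ck_dir <- cfg$checkpoint_dir
  if (!is.null(ck_dir)) dir.create(ck_dir, recursive = TRUE,
                                   showWarnings = FALSE)
  best_path <- if (!is.null(ck_dir)) file.path(ck_dir, "best.ckpt") else
    tempfile(fileext = ".ckpt")
  with_preserved_rng(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      order <- sample.int(length(train_set))
      losses <- c()
      for (b0 in seq(1L, length(order), by = cfg$batch_size)) {
        ids <- order[b0:min(b0 + cfg$batch_size - 1L, length(order))]
        batch <- stack_batch(train_set[ids])
        loss <- ag_softmax_ce(
          forward_nodes(model, ag_const(batch$images / 255), training = TRUE),
          batch$labels)
        if (!is.finite(loss$value))
          stop(sprintf("non-finite training loss at epoch %d, batch %d",
                       epoch, (b0 - 1L) %/% cfg$batch_size + 1L),
               call. = FALSE)
        ag_backward(loss)
        buffers <- sgd_step(params, cfg$learning_rate, cfg$momentum,
                            cfg$weight_decay, buffers)
        losses <- c(losses, loss$value)
      }
      ev <- evaluate_dataset(model, val_set, split = "all")
      rec <- data.frame(epoch = epoch, train_loss = mean(losses),
                        val_acc = unname(ev$aggregate["acc"]),
                        val_miou = unname(ev$aggregate["miou"]))
      history <- rbind(history, rec)
      if (rec$val_miou > best$miou) {
        best <- list(miou = rec$val_miou, epoch = epoch)
        save_checkpoint(model, best_path)
      }
      if (verbose)
        message(sprintf(
          "epoch %3d | train loss %.4f | val acc %.2f%% | val mIoU %.2f%%",
          epoch, rec$train_loss, rec$val_acc, rec$val_miou))
    }
  })
  attr(history, "best_epoch") <- best$epoch
  if (!is.null(ck_dir)) {
    save_checkpoint(model, file.path(ck_dir, "last.ckpt"))
    utils::write.csv(history, file.path(ck_dir, "history.csv"),
                     row.names = FALSE)
  }
  list(model = model, best_model = load_checkpoint(best_path),
       history = history)
}

#' Plot training curves
#'
#' Writes the loss-versus-epoch and validation-accuracy-versus-epoch curves
#' as two PNG files (`loss_curve.png`, `accuracy_curve.png`).
#'
#' @param history the history data frame returned by [train()].
#' @param dir output directory (created if missing).
#' @return invisibly, the two file paths.
#' @export
fit_accuracy_curve <- function(history, dir) {
  if (is.null(history) || nrow(history) == 0L)
    stop("history is empty; train first", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("loss_curve.png", "accuracy_curve.png"))
  grDevices::png(paths[1], width = 640, height = 480)
  plot(history$epoch, history$train_loss, type = "b", pch = 16,
       xlab = "epoch", ylab = "mean training loss", main = "Training loss")
  grDevices::dev.off()
  grDevices::png(paths[2], width = 640, height = 480)
  plot(history$epoch, history$val_acc, type = "b", pch = 16,
       xlab = "epoch", ylab = "validation accuracy (%)",
       main = "Validation accuracy")
  grDevices::dev.off()
  invisible(paths)
}
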