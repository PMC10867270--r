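#' Network configuration
#'
#' Hyperparameters of the ridge-segmentation network: a five-block
#' encoder (each block a pair of 3x3 convolutions with batch normalization
#' and ReLU, blocks separated by 2x2 max pooling), an atrous-spatial-pyramid
#' bottleneck on the deepest feature map, and a four-stage decoder that
#' upsamples, fuses each encoder skip, and applies strip pooling before the
#' next stage.
#'
#' @param in_channels number of input image channels (RGB = 3).
#' @param n_classes number of output classes (2: background, ridge).
#' @param base_channels width of the first encoder block; the full schedule
#'   defaults to `base_channels * c(1, 2, 4, 8, 8)`. Reduce for desk-scale
#'   experiments.
#' @param channel_schedule optional explicit 5-vector of block widths.
#' @param aspp_rates dilation rates of the three 3x3 pyramid branches;
#'   strictly increasing positive integers.
#' @param aspp_out_channels channels of the fused pyramid output; defaults to
#'   the deepest encoder width.
#' @param upsample_mode `"bilinear"` (interpolation, default) or
#'   `"transposed"` (learned 2x2 stride-2 transposed convolution).
#' @param fusion_mode how decoder and skip features are fused: `"concat"`
#'   (channel concatenation then 3x3 convolution, default) or `"add"`.
#' @param seed integer seed fixing the Kaiming weight initialization.
#' @return an object of class `aspnet_config`.
#' @export
model_config <- function(in_channels = 3L, n_classes = 2L,
                         base_channels = 64L, channel_schedule = NULL,
                         aspp_rates = c(6L, 12L, 18L),
                         aspp_out_channels = NULL,
                         upsample_mode = c("bilinear", "transposed"),
                         fusion_mode = c("concat", "add"),
                         seed = 1L) {
  upsample_mode <- match.arg(upsample_mode)
  fusion_mode <- match.arg(fusion_mode)
  if (is.null(channel_schedule))
    channel_schedule <- as.integer(base_channels * c(1, 2, 4, 8, 8))
  if (length(channel_schedule) != 5L)
    stop("channel_schedule must have length 5", call. = FALSE)
  aspp_rates <- as.integer(aspp_rates)
  if (length(aspp_rates) != 3L || any(aspp_rates <= 0L) ||
      any(diff(aspp_rates) <= 0L))
    stop("aspp_rates must be 3 strictly increasing positive integers",
         call. = FALSE)
  if (is.null(aspp_out_channels))
    aspp_out_channels <- channel_schedule[5]
  structure(list(
    in_channels = as.integer(in_channels),
    n_classes = as.integer(n_classes),
    base_channels = as.integer(base_channels),
    channel_schedule = as.integer(channel_schedule),
    aspp_rates = aspp_rates,
    aspp_out_channels = as.integer(aspp_out_channels),
    upsample_mode = upsample_mode,
    fusion_mode = fusion_mode,
    seed = as.integer(seed)
  ), class = "aspnet_config")
}

kaiming_conv <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

#' Build the segmentation network
#'
#' Allocates and initializes all trainable parameters. Initialization is
#' deterministic given `config$seed` and does not disturb the caller's RNG
#' stream.
#'
#' @param config an [model_config()] object.
#' @return an object of class `aspnet` holding parameters, batch-norm
#'   running statistics, and the configuration.
#' @export
aspnet <- function(config = model_config()) {
  stopifnot(inherits(config, "aspnet_config"))
  params <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())
  add_conv <- function(name, kh, kw, cin, cout) {
    params[[paste0(name, ".w")]] <- ag_param(kaiming_conv(kh, kw, cin, cout))
    params[[paste0(name, ".b")]] <- ag_param(numeric(cout))
  }
  add_bn <- function(name, c) {
    params[[paste0(name, ".gamma")]] <- ag_param(rep(1, c))
    params[[paste0(name, ".beta")]] <- ag_param(numeric(c))
    st <- new.env(parent = emptyenv())
    st$mean <- numeric(c)
    st$var <- rep(1, c)
    state[[name]] <- st
  }
  with_preserved_rng(config$seed, {
    s <- config$channel_schedule
    cin <- config$in_channels
    for (i in 1:5) {
      add_conv(sprintf("enc%d.conv1", i), 3, 3, cin, s[i])
      add_bn(sprintf("enc%d.bn1", i), s[i])
      add_conv(sprintf("enc%d.conv2", i), 3, 3, s[i], s[i])
      add_bn(sprintf("enc%d.bn2", i), s[i])
      cin <- s[i]
    }
    a <- config$aspp_out_channels
    add_conv("aspp.branch1", 1, 1, s[5], a)
    for (k in 2:4) add_conv(sprintf("aspp.branch%d", k), 3, 3, s[5], a)
    for (k in 1:4) add_bn(sprintf("aspp.bn%d", k), a)
    add_conv("aspp.proj", 1, 1, 4 * a, a)
    add_bn("aspp.projbn", a)
    cup <- a
    for (i in 4:1) {
      if (config$upsample_mode == "transposed")
        add_conv(sprintf("dec%d.up", i), 2, 2, cup, cup)
      if (config$fusion_mode == "concat") {
        add_conv(sprintf("dec%d.fuse", i), 3, 3, cup + s[i], s[i])
      } else {
        add_conv(sprintf("dec%d.proj", i), 1, 1, cup, s[i])
        add_conv(sprintf("dec%d.fuse", i), 3, 3, s[i], s[i])
      }
      add_bn(sprintf("dec%d.fusebn", i), s[i])
      add_conv(sprintf("dec%d.sp.convh", i), 3, 1, s[i], s[i])
      add_conv(sprintf("dec%d.sp.convw", i), 1, 3, s[i], s[i])
      add_conv(sprintf("dec%d.sp.post", i), 1, 1, s[i], s[i])
      cup <- s[i]
    }
    add_conv("head", 1, 1, s[1], config$n_classes)
  })
  structure(list(config = config, params = params, state = state),
            class = "aspnet")
}

model_parameters <- function(model) {
  nms <- sort(ls(model$params))
  stats::setNames(lapply(nms, function(n) model$params[[n]]), nms)
}

#' @export
print.aspnet <- function(x, ...) {
  np <- sum(vapply(model_parameters(x), function(p) length(p$value),
                   numeric(1)))
  cat(sprintf(
    "<aspnet> encoder widths %s | ASPP rates %s -> %d ch | %s upsampling, %s fusion | %s parameters\n",
    paste(x$config$channel_schedule, collapse = "-"),
    paste(x$config$aspp_rates, collapse = "/"),
    x$config$aspp_out_channels, x$config$upsample_mode,
    x$config$fusion_mode, format(np, big.mark = ",")))
  invisible(x)
}

conv_bn_relu <- function(m, x, conv, bn, training, pad = 1L, dilation = 1L) {
  p <- m$params
  h <- ag_conv2d(x, p[[paste0(conv, ".w")]], p[[paste0(conv, ".b")]],
                 pad = pad, dilation = dilation)
  h <- ag_batchnorm(h, p[[paste0(bn, ".gamma")]], p[[paste0(bn, ".beta")]],
                    m$state[[bn]], training)
  ag_relu(h)
}

strip_pool_node <- function(m, x, stage, training) {
  p <- m$params
  nm <- function(s) sprintf("dec%d.sp.%s", stage, s)
  d <- dim(ag_value(x))
  ph <- ag_conv2d(ag_rowmean(x), p[[paste0(nm("convh"), ".w")]],
                  p[[paste0(nm("convh"), ".b")]], pad = c(1L, 0L))
  pw <- ag_conv2d(ag_colmean(x), p[[paste0(nm("convw"), ".w")]],
                  p[[paste0(nm("convw"), ".b")]], pad = c(0L, 1L))
  s <- ag_add(ag_expand_w(ph, d[2]), ag_expand_h(pw, d[1]))
  gate <- ag_sigmoid(ag_conv2d(s, p[[paste0(nm("post"), ".w")]],
                               p[[paste0(nm("post"), ".b")]]))
  ag_mul(x, gate)
}

aspp_node <- function(m, x, training) {
  p <- m$params
  rates <- m$config$aspp_rates
  b1 <- conv_bn_relu(m, x, "aspp.branch1", "aspp.bn1", training, pad = 0L)
  branches <- list(b1)
  for (k in 2:4) {
    r <- rates[k - 1]
    branches[[k]] <- conv_bn_relu(m, x, sprintf("aspp.branch%d", k),
                                  sprintf("aspp.bn%d", k), training,
                                  pad = r, dilation = r)
  }
  conv_bn_relu(m, ag_concat(branches), "aspp.proj", "aspp.projbn", training,
               pad = 0L)
}

check_input_size <- function(h, w) {
  if (h %% 16L != 0L || w %% 16L != 0L)
    stop(sprintf(
      "input spatial size %dx%d must be divisible by 16 (five encoder scales)",
      h, w), call. = FALSE)
}

encode_nodes <- function(m, x, training) {
  d <- dim(ag_value(x))
  check_input_size(d[1], d[2])
  skips <- vector("list", 4)
  h <- x
  for (i in 1:5) {
    if (i > 1) h <- ag_maxpool2(h)
    h <- conv_bn_relu(m, h, sprintf("enc%d.conv1", i),
                      sprintf("enc%d.bn1", i), training)
    h <- conv_bn_relu(m, h, sprintf("enc%d.conv2", i),
                      sprintf("enc%d.bn2", i), training)
    if (i < 5) skips[[i]] <- h
  }
  list(skips = skips, deepest = h)
}

decode_nodes <- function(m, skips, bottom, training) {
  p <- m$params
  h <- bottom
  for (i in 4:1) {
    h <- if (m$config$upsample_mode == "transposed") {
      ag_conv_transpose2(h, p[[sprintf("dec%d.up.w", i)]],
                         p[[sprintf("dec%d.up.b", i)]])
    } else {
      ag_upsample2(h)
    }
    skip <- skips[[i]]
    ds <- dim(ag_value(skip))
    dh <- dim(ag_value(h))
    if (!all(dh[c(1, 2)] == ds[c(1, 2)]))
      stop(sprintf("decoder stage %d: upsampled %dx%d does not match skip %dx%d",
                   i, dh[1], dh[2], ds[1], ds[2]), call. = FALSE)
    fused <- if (m$config$fusion_mode == "concat") {
      ag_concat(list(h, skip))
    } else {
      ag_add(ag_conv2d(h, p[[sprintf("dec%d.proj.w", i)]],
                       p[[sprintf("dec%d.proj.b", i)]]), skip)
    }
    h <- conv_bn_relu(m, fused, sprintf("dec%d.fuse", i),
                      sprintf("dec%d.fusebn", i), training)
    h <- strip_pool_node(m, h, i, training)
  }
  ag_conv2d(h, p[["head.w"]], p[["head.b"]])
}

forward_nodes <- function(m, x, training = FALSE) {
  enc <- encode_nodes(m, x, training)
  bottom <- aspp_node(m, enc$deepest, training)
  decode_nodes(m, enc$skips, bottom, training)
}

as_batch <- function(images) {
  # accept H x W x 3 or H x W x 3 x N, values in 0..255; scale to [0,1]
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  if (length(dim(images)) != 4L)
    stop("images must be H x W x C or H x W x C x N arrays", call. = FALSE)
  images / 255
}

#' Encoder forward pass
#'
#' Runs the five encoder blocks on a batch of images and returns the four
#' skip feature maps (full, 1/2, 1/4, 1/8 resolution) plus the deepest
#' (1/16) map that feeds the pyramid bottleneck.
#'
#' @param model an [aspnet()] model.
#' @param images H x W x 3 (or H x W x 3 x N) array with values in 0..255;
#'   H and W must be divisible by 16.
#' @return list with `skips` (list of 4 H x W x C x N arrays) and `deepest`.
#' @export
encoder_forward <- function(model, images) {
  enc <- encode_nodes(model, ag_const(as_batch(images)), training = FALSE)
  list(skips = lapply(enc$skips, ag_value), deepest = ag_value(enc$deepest))
}

#' Decoder forward pass
#'
#' Upsamples the bottleneck output through four stages, fusing each encoder
#' skip and applying strip pooling after every fusion, then emits per-pixel
#' class logits at full resolution.
#'
#' @param model an [aspnet()] model.
#' @param skips list of 4 skip feature maps as returned by
#'   [encoder_forward()].
#' @param bottleneck the pyramid-fused deepest feature map.
#' @return logits array H x W x n_classes x N.
#' @export
decoder_forward <- function(model, skips, bottleneck) {
  out <- decode_nodes(model, lapply(skips, ag_const), ag_const(bottleneck),
                      training = FALSE)
  ag_value(out)
}

#' Full forward pass to logits
#'
#' @inheritParams encoder_forward
#' @return logits array H x W x n_classes x N.
#' @export
forward_logits <- function(model, images) {
  ag_value(forward_nodes(model, ag_const(as_batch(images)), training = FALSE))
}

#' Segment an image
#'
#' Per-pixel argmax over the class logits. Exact ties are assigned to the
#' background class (conservative: never hallucinate a ridge on a tie).
#'
#' @param object an [aspnet()] model.
#' @param images H x W x 3 image (values 0..255), H, W divisible by 16.
#' @param ... unused.
#' @return integer H x W matrix over \{0, 1\}.
#' @export
predict.aspnet <- function(object, images, ...) {
  lg <- forward_logits(object, images)
  logits_to_mask(lg[, , , 1, drop = FALSE])
}

logits_to_mask <- function(logits) {
  d <- dim(logits)
  scores <- matrix(aperm(logits, c(1, 2, 4, 3)), ncol = d[3])
  lab <- integer(nrow(scores))
  best <- scores[, 1]
  for (k in seq_len(d[3])[-1]) {
    better <- scores[, k] > best  # strict: ties keep the lower label
    lab[better] <- k - 1L
    best[better] <- scores[better, k]
  }
  matrix(lab, d[1], d[2])
}

#' Strip pooling
#'
#' Gates a feature map by its long-range row and column context: the map is
#' average-pooled along entire rows (H x 1) and entire columns (1 x W), each
#' pooled profile is refined by a length-3 one-dimensional convolution,
#' both are broadcast back to H x W and summed pixel-wise, passed through a
#' 1x1 convolution and a sigmoid, and the resulting gate multiplies the
#' original input element-wise. Output shape equals input shape.
#'
#' @param f feature map, H x W x C or H x W x C x N array.
#' @param params list with elements `conv_h` (weights `w` of shape
#'   3 x 1 x C x C and bias `b`), `conv_w` (1 x 3 x C x C), and `post`
#'   (1 x 1 x C x C); all channel-preserving.
#' @return array of the same shape as `f`.
#' @export
strip_pool <- function(f, params) {
  squeeze <- FALSE
  if (length(dim(f)) == 3L) {
    dim(f) <- c(dim(f), 1L)
    squeeze <- TRUE
  }
  d <- dim(f)
  for (nm in c("conv_h", "conv_w", "post")) {
    wd <- dim(params[[nm]]$w)
    if (wd[3] != d[3] || wd[4] != d[3])
      stop(sprintf("strip_pool: %s maps %d->%d channels but input has %d",
                   nm, wd[3], wd[4], d[3]), call. = FALSE)
  }
  x <- ag_const(f)
  ph <- ag_conv2d(ag_rowmean(x), params$conv_h$w, params$conv_h$b,
                  pad = c(1L, 0L))
  pw <- ag_conv2d(ag_colmean(x), params$conv_w$w, params$conv_w$b,
                  pad = c(0L, 1L))
  s <- ag_add(ag_expand_w(ph, d[2]), ag_expand_h(pw, d[1]))
  gate <- ag_sigmoid(ag_conv2d(s, params$post$w, params$post$b))
  out <- ag_value(ag_mul(x, gate))
  if (squeeze) dim(out) <- d[1:3]
  out
}

#' Atrous spatial pyramid pooling
#'
#' Four parallel branches over the same input — one 1x1 convolution and
#' three 3x3 convolutions dilated at the configured rates, all padded to
#' preserve H x W — concatenated along channels and fused by a 1x1
#' projection. Used on the deepest encoder output to aggregate multi-scale
#' context.
#'
#' @param f feature map, H x W x C or H x W x C x N array.
#' @param params list with `branch1`..`branch4` (each `w`, `b`; branch 1 is
#'   1x1, branches 2-4 are 3x3) and `proj` (1x1 over the concatenation).
#' @param rates the three dilation rates of branches 2-4.
#' @return array H x W x Cout (x N), Cout = output channels of `proj`.
#' @export
aspp <- function(f, params, rates = c(6L, 12L, 18L)) {
  squeeze <- FALSE
  if (length(dim(f)) == 3L) {
    dim(f) <- c(dim(f), 1L)
    squeeze <- TRUE
  }
  x <- ag_const(f)
  branches <- list(ag_conv2d(x, params$branch1$w, params$branch1$b))
  for (k in 2:4) {
    r <- as.integer(rates[k - 1])
    bp <- params[[paste0("branch", k)]]
    branches[[k]] <- ag_conv2d(x, bp$w, bp$b, pad = r, dilation = r)
  }
  out <- ag_value(ag_conv2d(ag_concat(branches), params$proj$w,
                            params$proj$b))
  if (squeeze) dim(out) <- dim(out)[1:3]
  out
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file containing the configuration, all parameter
#' arrays, and batch-norm running statistics; loading reconstructs a model
#' whose predictions are identical to the saved one.
#'
#' @param model an [aspnet()] model.
#' @param path file path.
#' @return `load_checkpoint` returns the restored `aspnet` model.
#' @export
save_checkpoint <- function(model, path) {
  nms <- ls(model$params)
  saveRDS(list(
    config = model$config,
    params = stats::setNames(lapply(nms, function(n) model$params[[n]]$value),
                             nms),
    state = stats::setNames(lapply(ls(model$state), function(n)
      list(mean = model$state[[n]]$mean, var = model$state[[n]]$var)),
      ls(model$state))
  ), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  m <- aspnet(ck$config)
  for (n in names(ck$params)) m$params[[n]]$value <- ck$params[[n]]
  for (n in names(ck$state)) {
    m$state[[n]]$mean <- ck$state[[n]]$mean
    m$state[[n]]$var <- ck$state[[n]]$var
  }
  m
}

# evaluate `expr` under a fixed seed without disturbing the caller's RNG
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
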