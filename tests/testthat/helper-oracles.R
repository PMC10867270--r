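# Independent brute-force oracles used to validate the vectorized /
# compiled implementations. Everything here is plain R loops on purpose.

# explicit per-pixel strip pooling: row/column means, length-3 1-D convs
# (cross-correlation, zero-padded), broadcast, sum, 1x1 conv + sigmoid, gate
strip_pool_oracle <- function(f, p) {
  d <- dim(f)
  H <- d[1]; W <- d[2]; C <- d[3]
  rowm <- matrix(0, H, C)
  colm <- matrix(0, W, C)
  for (c in seq_len(C)) {
    for (h in seq_len(H)) rowm[h, c] <- mean(f[h, , c])
    for (w in seq_len(W)) colm[w, c] <- mean(f[, w, c])
  }
  ph <- matrix(0, H, C)
  pw <- matrix(0, W, C)
  for (co in seq_len(C)) {
    for (h in seq_len(H)) {
      acc <- p$conv_h$b[co]
      for (i in 1:3) for (ci in seq_len(C)) {
        hi <- h + i - 2L
        if (hi >= 1L && hi <= H) acc <- acc + rowm[hi, ci] * p$conv_h$w[i, 1, ci, co]
      }
      ph[h, co] <- acc
    }
    for (w in seq_len(W)) {
      acc <- p$conv_w$b[co]
      for (j in 1:3) for (ci in seq_len(C)) {
        wi <- w + j - 2L
        if (wi >= 1L && wi <= W) acc <- acc + colm[wi, ci] * p$conv_w$w[1, j, ci, co]
      }
      pw[w, co] <- acc
    }
  }
  out <- array(0, d)
  for (h in seq_len(H)) for (w in seq_len(W)) for (co in seq_len(C)) {
    s <- p$post$b[co]
    for (ci in seq_len(C)) s <- s + (ph[h, ci] + pw[w, ci]) * p$post$w[1, 1, ci, co]
    out[h, w, co] <- f[h, w, co] / (1 + exp(-s))
  }
  out
}

# random channel-preserving strip-pool parameters
random_sp_params <- function(C, seed) {
  set.seed(seed)
  list(conv_h = list(w = array(rnorm(3 * C * C, 0, 0.5), c(3, 1, C, C)),
                     b = rnorm(C, 0, 0.2)),
       conv_w = list(w = array(rnorm(3 * C * C, 0, 0.5), c(1, 3, C, C)),
                     b = rnorm(C, 0, 0.2)),
       post = list(w = array(rnorm(C * C, 0, 0.5), c(1, 1, C, C)),
                   b = rnorm(C, 0, 0.2)))
}

# identity strip-pool parameters (single channel): 1-D convs pass the
# center tap, the 1x1 projection is unit weight, all biases zero
identity_sp_params <- function() {
  wh <- array(0, c(3, 1, 1, 1)); wh[2, 1, 1, 1] <- 1
  ww <- array(0, c(1, 3, 1, 1)); ww[1, 2, 1, 1] <- 1
  list(conv_h = list(w = wh, b = 0),
       conv_w = list(w = ww, b = 0),
       post = list(w = array(1, c(1, 1, 1, 1)), b = 0))
}

# per-pixel confusion tallies by explicit double loop
confusion_oracle <- function(pred, truth, positive = 1L) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j] == positive
    t <- truth[i, j] == positive
    if (p && t) tp <- tp + 1L
    else if (p && !t) fp <- fp + 1L
    else if (!p && t) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# unstabilized cross-entropy, valid only when exp() does not overflow
naive_ce <- function(x, class) -x[class + 1] + log(sum(exp(x)))

# ASPP parameters that pass through exactly one branch: all-ones kernels,
# zero biases, projection selecting branch `k` with unit weight
aspp_probe_params <- function(k) {
  proj_w <- array(0, c(1, 1, 4, 1))
  proj_w[1, 1, k, 1] <- 1
  list(branch1 = list(w = array(1, c(1, 1, 1, 1)), b = 0),
       branch2 = list(w = array(1, c(3, 3, 1, 1)), b = 0),
       branch3 = list(w = array(1, c(3, 3, 1, 1)), b = 0),
       branch4 = list(w = array(1, c(3, 3, 1, 1)), b = 0),
       proj = list(w = proj_w, b = 0))
}

# scaled-down study conditions shared by the learning / robustness checks:
# 64-pixel tiles, two ridges of width 5-9 in mixed orientation
reduced_scene <- function(difficulty, seed) {
  scene_spec(height = 64L, width = 64L, orientation = "mixed", n_ridges = 2L,
             ridge_width_range = c(5L, 9L), difficulty = difficulty,
             seed = seed)
}

tiny_model_config <- function(seed = 5L) {
  model_config(base_channels = 4L, seed = seed)
}
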