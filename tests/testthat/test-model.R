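# Architecture contracts: strip pooling, the dilated pyramid, encoder /
# decoder shapes, prediction semantics, checkpointing.

test_that("strip pooling matches the per-pixel loop oracle", {
  cases <- expand.grid(C = c(1L, 3L, 8L), rep = 1:2)
  for (k in seq_len(nrow(cases))) {
    C <- cases$C[k]
    set.seed(200 + k)
    H <- sample(3:16, 1); W <- sample(3:16, 1)
    f <- array(rnorm(H * W * C), c(H, W, C))
    p <- random_sp_params(C, seed = 300 + k)
    expect_equal(strip_pool(f, p), strip_pool_oracle(f, p),
                 tolerance = 1e-5)
  }
})

test_that("strip pooling closed forms: zero input and 1x1 gate algebra", {
  p1 <- random_sp_params(3, seed = 1)
  p1$conv_h$b <- p1$conv_w$b <- p1$post$b <- numeric(3)
  z <- array(0, c(5, 7, 3))
  expect_equal(strip_pool(z, p1), z)
  # 1x1 spatial input, identity convolutions: both pooled paths return v,
  # the summed map is 2v, so the output is v * sigmoid(2v)
  for (v in c(0, -1.3, 0.7, 25)) {
    out <- strip_pool(array(v, c(1, 1, 1)), identity_sp_params())
    expect_equal(out[1, 1, 1], v / (1 + exp(-2 * v)), tolerance = 1e-12)
  }
})

test_that("strip pooling rejects channel mismatch", {
  expect_error(strip_pool(array(0, c(4, 4, 2)), random_sp_params(3, 1)),
               "channel")
})

test_that("dilated pyramid branches touch exactly the offsets of their rate", {
  rates <- c(6L, 12L, 18L)
  n <- 2L * max(rates) + 7L
  mid <- (n + 1L) %/% 2L
  x <- array(0, c(n, n, 1))
  x[mid, mid, 1] <- 1
  for (k in 2:4) {
    r <- rates[k - 1]
    out <- aspp(x, aspp_probe_params(k), rates = rates)
    hit <- which(abs(out[, , 1]) > 1e-12, arr.ind = TRUE)
    expected <- expand.grid(row = mid + c(-r, 0L, r), col = mid + c(-r, 0L, r))
    expect_equal(nrow(hit), 9L)
    expect_setequal(paste(hit[, 1], hit[, 2]),
                    paste(expected$row, expected$col))
  }
  # the 1x1 branch touches only the perturbed pixel itself
  out1 <- aspp(x, aspp_probe_params(1), rates = rates)
  expect_equal(which(abs(out1[, , 1]) > 1e-12), mid + (mid - 1L) * n)
})

test_that("pyramid output preserves spatial size and zero maps to zero", {
  cfg <- tiny_model_config()
  m <- aspnet(cfg)
  f <- array(rnorm(8 * 8 * cfg$channel_schedule[5] * 1),
             c(8, 8, cfg$channel_schedule[5], 1))
  out <- ridgeseg:::ag_value(ridgeseg:::aspp_node(m, ridgeseg:::ag_const(f),
                                                  training = FALSE))
  expect_equal(dim(out), c(8L, 8L, cfg$aspp_out_channels, 1L))
  pz <- aspp_probe_params(2)
  expect_equal(aspp(array(0, c(10, 10, 1)), pz), array(0, c(10, 10, 1)))
})

test_that("encoder produces the stated scale and channel schedule", {
  cfg <- tiny_model_config()
  m <- aspnet(cfg)
  img <- array(sample(0:255, 64 * 64 * 3, TRUE), c(64, 64, 3))
  enc <- encoder_forward(m, img)
  s <- cfg$channel_schedule
  expect_length(enc$skips, 4)
  for (i in 1:4)
    expect_equal(dim(enc$skips[[i]]), c(64L / 2^(i - 1), 64L / 2^(i - 1),
                                        s[i], 1L))
  expect_equal(dim(enc$deepest), c(4L, 4L, s[5], 1L))
})

test_that("indivisible input sizes are rejected with the divisibility rule", {
  m <- aspnet(tiny_model_config())
  img <- array(0L, c(60, 64, 3))
  expect_error(forward_logits(m, img), "divisible by 16")
})

test_that("full forward emits 2-class logits at input resolution, finite, deterministic", {
  m <- aspnet(tiny_model_config())
  for (sz in c(32L, 48L)) {
    img <- array(sample(0:255, sz * sz * 3, TRUE), c(sz, sz, 3))
    lg <- forward_logits(m, img)
    expect_equal(dim(lg), c(sz, sz, 2L, 1L))
    expect_true(all(is.finite(lg)))
    expect_identical(lg, forward_logits(m, img))
  }
})

test_that("decoder_forward on encoder output reproduces the full forward", {
  m <- aspnet(tiny_model_config())
  img <- array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3))
  enc <- encoder_forward(m, img)
  bottom <- ridgeseg:::ag_value(ridgeseg:::aspp_node(
    m, ridgeseg:::ag_const(enc$deepest), training = FALSE))
  lg <- decoder_forward(m, enc$skips, bottom)
  expect_equal(lg, forward_logits(m, img), tolerance = 1e-12)
})

test_that("prediction is the argmax of the logits with ties to background", {
  expect_equal(ridgeseg:::logits_to_mask(array(c(0, 1), c(1, 1, 2, 1))[rep(1, 3), rep(1, 4), , , drop = FALSE]),
               matrix(1L, 3, 4))
  ties <- array(0.7, c(3, 4, 2, 1))
  expect_equal(ridgeseg:::logits_to_mask(ties), matrix(0L, 3, 4))
  m <- aspnet(tiny_model_config())
  img <- array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3))
  lg <- forward_logits(m, img)
  expect_equal(predict(m, img), ridgeseg:::logits_to_mask(lg))
})

test_that("every parameter receives a nonzero gradient (no dead branches)", {
  for (up in c("bilinear", "transposed")) {
    m <- aspnet(model_config(base_channels = 4L, upsample_mode = up,
                             seed = 11L))
    set.seed(42)
    img <- array(sample(0:255, 32 * 32 * 3 * 2, TRUE), c(32, 32, 3, 2))
    lab <- array(sample(0:1, 32 * 32 * 2, TRUE), c(32, 32, 2))
    loss <- ridgeseg:::ag_softmax_ce(
      ridgeseg:::forward_nodes(m, ridgeseg:::ag_const(img / 255),
                               training = TRUE), lab)
    ridgeseg:::ag_backward(loss)
    mags <- vapply(ridgeseg:::model_parameters(m), function(p)
      if (is.null(p$grad)) 0 else max(abs(p$grad)), numeric(1))
    expect_true(all(mags > 0), info = up)
  }
})

test_that("an all-zero parameterization emits all-zero logits", {
  m <- aspnet(tiny_model_config())
  for (p in ridgeseg:::model_parameters(m)) p$value <- p$value * 0
  img <- array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3))
  expect_true(all(forward_logits(m, img) == 0))
})

test_that("checkpoints round-trip configuration, weights, and predictions", {
  m <- aspnet(tiny_model_config(seed = 99L))
  img <- array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3))
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(m2$config, m$config)
  expect_identical(predict(m2, img), predict(m, img))
})

test_that("model config validates its invariants", {
  expect_error(model_config(aspp_rates = c(6, 6, 12)), "increasing")
  expect_error(model_config(channel_schedule = c(8, 16, 32)), "length 5")
})
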