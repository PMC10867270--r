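# Loss and metric machinery against hand arithmetic and loop oracles.

test_that("cross-entropy reproduces closed-form single-pixel values", {
  expect_equal(cross_entropy_loss(c(0, 0), 0L), log(2), tolerance = 1e-9)
  expect_equal(cross_entropy_loss(c(0, 0), 1L), log(2), tolerance = 1e-9)
  expect_equal(cross_entropy_loss(c(2, 1), 0L), log(1 + exp(-1)),
               tolerance = 1e-9)
  expect_equal(cross_entropy_loss(c(2, 1), 1L), 1 + log(1 + exp(-1)),
               tolerance = 1e-9)
})

test_that("cross-entropy is shift invariant and matches the naive form", {
  set.seed(400)
  for (rep in 1:20) {
    x <- rnorm(2, 0, 3)
    cls <- sample(0:1, 1)
    expect_equal(cross_entropy_loss(x, cls), naive_ce(x, cls),
                 tolerance = 1e-6)
    expect_equal(cross_entropy_loss(x + 57.3, cls),
                 cross_entropy_loss(x, cls), tolerance = 1e-9)
  }
  # stabilized form survives logits where the naive form overflows
  expect_true(is.finite(cross_entropy_loss(c(1000, 999), 0L)))
})

test_that("batched cross-entropy averages per-pixel losses", {
  lg <- array(0, c(2, 2, 2, 1))
  lg[1, 1, , 1] <- c(2, 1)
  lab <- array(0L, c(2, 2, 1))
  expected <- (log(1 + exp(-1)) + 3 * log(2)) / 4
  expect_equal(cross_entropy_loss(lg, lab), expected, tolerance = 1e-9)
  expect_error(cross_entropy_loss(lg, array(2L, c(2, 2, 1))), "labels")
})

test_that("confusion counts match hand cases and the loop oracle", {
  truth <- matrix(0L, 10, 10)
  truth[1:3, ] <- 1L
  cc <- confusion_counts(truth, truth)
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 30L, fp = 0L, fn = 0L, tn = 70L))
  comp <- 1L - truth
  cc2 <- confusion_counts(comp, truth)
  expect_equal(cc2$tp, 0L)
  expect_equal(cc2$tn, 0L)
  set.seed(401)
  for (rep in 1:10) {
    p <- matrix(sample(0:1, 64, TRUE), 8, 8)
    t <- matrix(sample(0:1, 64, TRUE), 8, 8)
    for (pos in 0:1)
      expect_equal(unclass(confusion_counts(p, t, pos))[c("tp","fp","fn","tn")],
                   confusion_oracle(p, t, pos)[c("tp","fp","fn","tn")])
  }
  expect_error(confusion_counts(matrix(0L, 2, 2), matrix(0L, 3, 3)),
               "shape")
})

test_that("metrics from counts reproduce the defining arithmetic", {
  m <- metrics_from_counts(list(tp = 50, fp = 10, fn = 10, tn = 30))
  expect_equal(m$acc, 80)
  expect_equal(m$pr, 100 * 50 / 60, tolerance = 1e-9)
  expect_equal(m$re, 100 * 50 / 60, tolerance = 1e-9)
  expect_equal(m$iou, 100 * 50 / 70, tolerance = 1e-9)
  perfect <- metrics_from_counts(list(tp = 40, fp = 0, fn = 0, tn = 60))
  expect_equal(unlist(perfect), c(acc = 100, pr = 100, re = 100, iou = 100))
  # empty-class policy: class absent from prediction and truth
  empty <- metrics_from_counts(list(tp = 0, fp = 0, fn = 0, tn = 25))
  expect_equal(unlist(empty), c(acc = 100, pr = 100, re = 100, iou = 100))
})

test_that("metric identities hold on random masks", {
  set.seed(402)
  for (rep in 1:20) {
    p <- matrix(sample(0:1, 100, TRUE), 10, 10)
    t <- matrix(sample(0:1, 100, TRUE), 10, 10)
    m <- metrics_from_counts(confusion_counts(p, t, 1L))
    expect_true(all(unlist(m) >= 0 & unlist(m) <= 100))
    expect_lte(m$iou, m$pr + 1e-9)
    expect_lte(m$iou, m$re + 1e-9)
    # accuracy is symmetric in the positive class
    m0 <- metrics_from_counts(confusion_counts(p, t, 0L))
    expect_equal(m$acc, m0$acc)
  }
})

test_that("dataset evaluation averages per-image metrics", {
  img <- array(0L, c(4, 4, 3))
  truth_a <- matrix(0L, 4, 4)
  truth_b <- matrix(c(rep(0L, 8), rep(1L, 8)), 4, 4)
  predictor <- function(image) matrix(0L, 4, 4)  # constant background
  ds <- list(list(image = img, mask = truth_a),
             list(image = img, mask = truth_b))
  rep_mean <- evaluate_dataset(predictor, ds, split = "all")
  # per-image accuracy 100 and 50 -> mean 75
  expect_equal(unname(rep_mean$aggregate["acc"]), 75)
  # single-image dataset: per-image mean equals pooled aggregation
  one <- list(list(image = img, mask = truth_b))
  expect_equal(evaluate_dataset(predictor, one, split = "all")$aggregate,
               evaluate_dataset(predictor, one, split = "all",
                                aggregation = "pooled")$aggregate)
  # constant-background predictor on an all-background dataset is perfect
  allbg <- evaluate_dataset(predictor, list(list(image = img, mask = truth_a)),
                            split = "all")
  expect_equal(unname(allbg$aggregate["acc"]), 100)
  expect_equal(unname(allbg$aggregate["miou"]), 100)
  expect_error(evaluate_dataset(predictor, list(), split = "all"), "no images")
})

test_that("metric reports serialize with per-image and aggregate rows", {
  predictor <- function(image) matrix(0L, 4, 4)
  ds <- list(list(image = array(0L, c(4, 4, 3)), mask = matrix(0L, 4, 4)))
  rep <- evaluate_dataset(predictor, ds, split = "all")
  path <- tempfile(fileext = ".csv")
  write_metric_report(rep, path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$row[2], "aggregate")
})
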