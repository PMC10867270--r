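# Synthetic ridge-scene generator: determinism, geometry, labels, splits.

test_that("scenes are deterministic and use only labels {0,1}", {
  spec <- scene_spec(height = 96, width = 96, n_ridges = 3,
                     ridge_width_range = c(4, 8), difficulty = "hard",
                     seed = 5)
  a <- generate_scene(spec)
  b <- generate_scene(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_true(all(a$mask %in% c(0L, 1L)))
  expect_equal(dim(a$image), c(96L, 96L, 3L))
  # vacancies are distractors: always labeled background
  expect_true(all(a$mask[a$vacancy] == 0L))
})

test_that("a spec with no ridges yields an all-zero mask", {
  s <- generate_scene(scene_spec(height = 64, width = 64, n_ridges = 0,
                                 seed = 2))
  expect_equal(sum(s$mask), 0)
})

test_that("straight vertical stripes cover exactly width x height pixels", {
  spec <- scene_spec(height = 512, width = 512, orientation = "vertical",
                     n_ridges = 3, ridge_width_range = c(12, 20),
                     difficulty = "easy", seed = 7)
  s <- generate_scene(spec)
  col_counts <- colSums(s$mask)
  # with zero roughness every ridge column is full height, others empty
  expect_true(all(col_counts %in% c(0L, 512L)))
  ridge_cols <- sum(col_counts == 512L)
  expect_equal(sum(s$mask), ridge_cols * 512)
  # run-length analysis recovers exactly 3 stripes with widths in range
  runs <- rle(col_counts > 0)
  widths <- runs$lengths[runs$values]
  expect_length(widths, 3)
  expect_true(all(widths >= 12 & widths <= 20))
})

test_that("ridge fraction grows with ridge count at fixed width", {
  fractions <- vapply(1:5, function(n) {
    s <- generate_scene(scene_spec(height = 128, width = 128,
                                   orientation = "vertical", n_ridges = n,
                                   ridge_width_range = c(6, 6), seed = 3))
    mean(s$mask)
  }, numeric(1))
  expect_true(all(diff(fractions) >= 0))
  expect_equal(fractions, (1:5) * 6 / 128)
})

test_that("impossible stripe geometry is rejected", {
  expect_error(scene_spec(height = 64, width = 64, n_ridges = 8,
                          ridge_width_range = c(8, 10)),
               "impossible geometry")
  expect_error(scene_spec(ridge_width_range = c(0, 4)), "min >= 1")
})

test_that("dataset generation honors the 5:1 split and remainder policy", {
  root <- file.path(tempdir(), "ds-small")
  spec <- scene_spec(height = 32, width = 32, n_ridges = 1,
                     ridge_width_range = c(3, 5), seed = 9)
  idx <- generate_dataset(6, c(5, 1), root, spec)
  expect_equal(sum(idx$entries$split == "train"), 5)
  expect_equal(sum(idx$entries$split == "val"), 1)
  # remainder tiles go to the training split
  idx7 <- generate_dataset(7, c(5, 1), file.path(tempdir(), "ds-7"), spec)
  expect_equal(sum(idx7$entries$split == "train"), 6)
  expect_equal(sum(idx7$entries$split == "val"), 1)
  # every image has exactly one mask; all tiles share the tile size
  expect_equal(anyDuplicated(idx$entries$mask), 0)
  e <- ridgeseg:::load_entry(idx, 3)
  expect_equal(dim(e$image), c(32L, 32L, 3L))
  expect_equal(dim(e$mask), c(32L, 32L))
  # manifest round trip
  idx2 <- read_dataset_index(root)
  expect_equal(idx2$entries, idx$entries)
  expect_equal(idx2$tile_size, 32L)
})

test_that("datasets are reproducible tile-by-tile from the master seed", {
  spec <- scene_spec(height = 32, width = 32, n_ridges = 1,
                     ridge_width_range = c(3, 5), seed = 77)
  r1 <- file.path(tempdir(), "ds-a")
  r2 <- file.path(tempdir(), "ds-b")
  generate_dataset(4, c(3, 1), r1, spec)
  generate_dataset(4, c(3, 1), r2, spec)
  for (f in list.files(r1, recursive = TRUE)) {
    expect_identical(readBin(file.path(r1, f), "raw", 1e6),
                     readBin(file.path(r2, f), "raw", 1e6), label = f)
  }
})

test_that("large scenes follow the template rendering at arbitrary size", {
  spec <- scene_spec(height = 64, width = 64, orientation = "vertical",
                     n_ridges = 2, ridge_width_range = c(5, 9), seed = 13)
  big <- generate_large_scene(1024, 768, spec)
  expect_equal(dim(big$image), c(1024L, 768L, 3L))
  expect_equal(dim(big$mask), c(1024L, 768L))
  # any 512x512 crop is a valid mask
  crop <- big$mask[200:711, 100:611]
  expect_true(all(crop %in% c(0L, 1L)))
  # determinism
  expect_identical(generate_large_scene(1024, 768, spec)$mask, big$mask)
  expect_error(generate_large_scene(256, 256, spec), "at least 512")
})
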