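test_that("image generator honours counts, labels and determinism", {
  spec <- fixture_spec(n_per_class = 3, seed = 7)
  imgs <- make_images(spec)
  expect_equal(length(imgs), 6L)
  expect_equal(imgs$manifest$label, c(0L, 0L, 0L, 1L, 1L, 1L))
  # bit-identical under the same spec + seed
  again <- make_images(spec)
  expect_identical(imgs$images, again$images)
  # a different seed changes the pixels
  other <- make_images(fixture_spec(n_per_class = 3, seed = 8))
  expect_false(identical(imgs$images, other$images))
})

test_that("image classes are statistically separated by blob density", {
  imgs <- make_images(fixture_spec(n_per_class = 25, image_size = 32,
                                   class_separation = 4, seed = 21))
  # class-1 tiles carry more dark blobs, so their mean intensity is lower
  means <- vapply(imgs$images, mean, 0)
  lab <- imgs$manifest$label
  expect_lt(mean(means[lab == 1]), mean(means[lab == 0]))
  expect_lt(t.test(means[lab == 1], means[lab == 0])$p.value, 0.01)
})

test_that("invalid fixture specs are rejected", {
  expect_error(fixture_spec(n_per_class = 0), class = "fuzzyhisto_config_error")
  expect_error(fixture_spec(image_size = 16), class = "fuzzyhisto_config_error")
  expect_error(fixture_spec(n_features = 1), class = "fuzzyhisto_config_error")
  expect_error(fixture_spec(noise_sd = 0), class = "fuzzyhisto_config_error")
  expect_error(fixture_spec(n_features = 4, n_informative = 5),
               class = "fuzzyhisto_config_error")
})

test_that("feature table: geometry, determinism, informative metadata", {
  spec <- fixture_spec(n_per_class = 40, n_features = 15, n_informative = 4,
                       class_separation = 3, seed = 5)
  tbl <- make_feature_table(spec)
  expect_equal(dim(tbl), c(80L, 16L))
  expect_equal(sum(tbl$label == 0), 40L)
  expect_identical(tbl, make_feature_table(spec))
  inf <- informative_features(tbl)
  expect_length(inf, 4L)
  # informative dimensions separate the classes; shuffling labels kills it
  for (cn in inf) {
    gap <- abs(mean(tbl[[cn]][tbl$label == 1]) - mean(tbl[[cn]][tbl$label == 0]))
    expect_gt(gap, 1.5)
    shuffled <- withr::with_seed(1, sample(tbl$label))
    gap_null <- abs(mean(tbl[[cn]][shuffled == 1]) - mean(tbl[[cn]][shuffled == 0]))
    expect_lt(gap_null, gap)
  }
})

test_that("zero separation carries no class signal", {
  tbl <- make_feature_table(fixture_spec(n_per_class = 50, n_features = 8,
                                         n_informative = 2,
                                         class_separation = 0, seed = 9))
  # permutation test on each nominally informative feature at alpha = 0.01
  for (cn in informative_features(tbl)) {
    obs <- abs(mean(tbl[[cn]][tbl$label == 1]) - mean(tbl[[cn]][tbl$label == 0]))
    null <- withr::with_seed(3, replicate(999, {
      p <- sample(tbl$label)
      abs(mean(tbl[[cn]][p == 1]) - mean(tbl[[cn]][p == 0]))
    }))
    expect_gt(mean(c(obs, null) >= obs), 0.01)
  }
})

test_that("strong separation is recoverable by a single threshold", {
  tbl <- make_feature_table(fixture_spec(n_per_class = 50, n_features = 5,
                                         n_informative = 1,
                                         class_separation = 10, noise_sd = 1,
                                         seed = 13))
  cn <- informative_features(tbl)
  # oracle: depth-1 split at the midpoint between class means
  thr <- (mean(tbl[[cn]][tbl$label == 0]) + mean(tbl[[cn]][tbl$label == 1])) / 2
  acc <- mean((tbl[[cn]] > thr) == (tbl$label == 1))
  expect_gte(acc, 0.99)
})

test_that("feature tables round-trip through CSV", {
  tbl <- sep_table(n_per_class = 10, n_features = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(tbl, path)
  back <- read_feature_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl[, names(back)]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(names(back)[ncol(back)], "label")
})

test_that("image sets round-trip through PNG + labels CSV", {
  imgs <- tiny_images(n_per_class = 2, seed = 30)
  dir <- withr::local_tempdir()
  write_image_set(imgs, dir)
  back <- read_image_set(dir)
  expect_equal(length(back), length(imgs))
  expect_equal(back$manifest$label, imgs$manifest$label)
  # 8-bit quantization on disk
  expect_lt(max(abs(back$images[[1]] - imgs$images[[1]])), 1 / 255)
})
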