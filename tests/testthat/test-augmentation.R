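test_that("augmentation emits original + scaled + flipped + rotations per image", {
  imgs <- tiny_images(n_per_class = 1, seed = 3)
  aug <- augment(imgs, augmentation_config(seed = 1))
  # 2 inputs x (1 original + 1 scaled + 1 flipped + 3 rotated)
  expect_equal(length(aug), 12L)
  prov <- aug$manifest$provenance[1:6]
  expect_identical(prov[1:3], c("original", "scaled", "flipped"))
  expect_match(prov[4:6], "^rotated\\(")
  # original-first ordering: first block image is the untouched input
  expect_identical(aug$images[[1]], imgs$images[[1]])
  # labels propagate unchanged
  expect_equal(aug$manifest$label, rep(imgs$manifest$label, each = 6))
})

test_that("output counts follow N x (include_original + 2 + n_rotations)", {
  imgs <- tiny_images(n_per_class = 2, seed = 4)
  cases <- list(
    list(cfg = augmentation_config(seed = 1), per = 6L),
    list(cfg = augmentation_config(n_rotations = 0, include_original = FALSE,
                                   seed = 1), per = 2L),
    list(cfg = augmentation_config(n_rotations = 5, seed = 1), per = 8L)
  )
  for (cs in cases) {
    aug <- augment(imgs, cs$cfg)
    expect_equal(length(aug), 4L * cs$per)
    cnt <- augmentation_counts(4L, cs$cfg)
    expect_equal(cnt$n_total, 4L * cs$per)
  }
})

test_that("augmented-only tallies match the per-class bookkeeping", {
  cfg <- augmentation_config()
  expect_equal(augmentation_counts(481, cfg)$n_new, 2405L)
  expect_equal(augmentation_counts(506, cfg)$n_new, 2530L)
})

test_that("label multiset is preserved up to multiplicity", {
  imgs <- tiny_images(n_per_class = 3, seed = 8)
  aug <- augment(imgs, augmentation_config(seed = 2))
  expect_equal(unname(table(aug$manifest$label)),
               unname(table(imgs$manifest$label)) * 6L)
})

test_that("vertical flip is an involution and zero rotation is an exact copy", {
  img <- tiny_images(1, seed = 5)$images[[1]]
  flip2 <- fuzzyhisto:::flip_vertical(fuzzyhisto:::flip_vertical(img))
  expect_identical(flip2, img)
  expect_equal(fuzzyhisto:::rotate_reflect(img, 0), img, tolerance = 1e-12)
})

test_that("rotation angles are seeded, nonzero, and inside the range", {
  imgs <- tiny_images(n_per_class = 1, seed = 6)
  a1 <- augment(imgs, augmentation_config(seed = 99))
  a2 <- augment(imgs, augmentation_config(seed = 99))
  expect_identical(a1$images, a2$images)
  angles <- as.numeric(sub("rotated\\((.*)\\)", "\\1",
                           grep("rotated", a1$manifest$provenance, value = TRUE)))
  expect_true(all(angles != 0))
  expect_true(all(abs(angles) <= 50))
})

test_that("empty input yields empty output; degenerate images are rejected", {
  empty <- image_set(list(), integer())
  expect_equal(length(augment(empty)), 0L)
  expect_error(image_set(list(array(0, dim = c(0, 4, 3))), 0L),
               class = "fuzzyhisto_input_error")
})

test_that("scaled copies keep the input geometry and magnify the center", {
  img <- tiny_images(1, seed = 12)$images[[1]]
  aug <- augment(image_set(list(img), 0L),
                 augmentation_config(n_rotations = 0, include_original = FALSE,
                                     seed = 1))
  scaled <- aug$images[[which(aug$manifest$provenance == "scaled")]]
  expect_equal(dim(scaled), dim(img))
  # cross-check the resize path against an established implementation
  ref <- EBImage::resize(EBImage::Image(aperm(img, c(2, 1, 3)),
                                        colormode = "Color"),
                         w = round(dim(img)[2] * 1.2))
  ref <- aperm(ref@.Data, c(2, 1, 3))
  own <- fuzzyhisto:::resize_bilinear(img, round(dim(img)[1] * 1.2),
                                      round(dim(img)[2] * 1.2))
  expect_lt(mean(abs(own - ref)), 0.02)
})
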