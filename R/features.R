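#' Feature extractor configuration
#'
#' The extractor resizes every image to `input_size` x `input_size`,
#' subtracts a per-channel mean intensity, and pushes the batch through a
#' backbone. Two backbones are understood:
#'
#' * `"resnet50"` — the published 50-layer residual network, consumed as an
#'   architecture behind this interface. Its final convolutional map at
#'   input 224 is 7 x 7 x 2048, i.e. a flattened 100,352-vector per image.
#'   Running it requires a deep-learning runtime; without one the extractor
#'   raises an environment error (the dimensionality contract is still
#'   available through [backbone_output_dim()]).
#' * `"stub"` — a deterministic, dependency-free extractor (grid-pooled
#'   channel intensities) of configurable width, which makes the whole
#'   pipeline runnable and testable on any machine.
#'
#' @param input_size square side in pixels images are resized to
#'   (default 224).
#' @param backbone `"resnet50"` or `"stub"`.
#' @param pretrained whether pretrained weights would be requested from the
#'   backbone runtime (ignored by the stub).
#' @param batch_size images per processing batch (>= 1).
#' @param mean_subtraction per-channel mean intensities in \[0,1\] to
#'   subtract, or `"dataset"` to recompute the per-channel means from the
#'   batch itself. Default: fixed reference constants
#'   `c(0.485, 0.456, 0.406)`.
#' @param stub_width feature-vector length produced by the stub backbone.
#' @return A `feature_extractor_config` object.
#' @export
feature_extractor_config <- function(input_size = 224,
                                     backbone = c("stub", "resnet50"),
                                     pretrained = FALSE,
                                     batch_size = 32,
                                     mean_subtraction = c(0.485, 0.456, 0.406),
                                     stub_width = 48) {
  backbone <- match.arg(backbone)
  if (!(identical(mean_subtraction, "dataset") ||
        (is.numeric(mean_subtraction) && length(mean_subtraction) == 3L))) {
    stop_config("`mean_subtraction` must be 3 channel means or \"dataset\"")
  }
  structure(
    list(
      input_size = check_count(input_size, "input_size"),
      backbone = backbone,
      pretrained = isTRUE(pretrained),
      batch_size = check_count(batch_size, "batch_size"),
      mean_subtraction = mean_subtraction,
      stub_width = check_count(stub_width, "stub_width", min = 3L)
    ),
    class = "feature_extractor_config"
  )
}

#' Output dimensionality of a backbone
#'
#' A pure function of (backbone, input size): the ResNet-50 trunk halves
#' the spatial resolution five times (stem convolution, stem pooling, and
#' the three stride-2 stage transitions) and ends with 2048 channels, so
#' input 224 gives a 7 x 7 x 2048 = 100,352-long flattened map. The stub
#' backbone's width is whatever the config requests.
#'
#' @param backbone `"resnet50"` or `"stub"`.
#' @param input_size input side in pixels.
#' @param stub_width stub width (only used for `backbone = "stub"`).
#' @return Integer feature-vector length.
#' @export
#' @examples
#' backbone_output_dim("resnet50", 224)  # 100352
backbone_output_dim <- function(backbone, input_size = 224, stub_width = 48) {
  backbone <- match.arg(backbone, c("resnet50", "stub"))
  if (backbone == "stub") return(as.integer(stub_width))
  side <- check_count(input_size, "input_size")
  for (i in 1:5) side <- ceiling(side / 2)
  as.integer(side * side * 2048L)
}

#' Preprocess images for feature extraction
#'
#' Resizes every image to `input_size` square (bilinear) and subtracts the
#' per-channel mean intensity. Order and labels are preserved. After mean
#' subtraction intensities are centered and may be negative.
#'
#' @param images an [image_set()].
#' @param cfg a [feature_extractor_config()].
#' @return An [image_set()] of `input_size` x `input_size` images.
#' @export
preprocess_images <- function(images, cfg = feature_extractor_config()) {
  stopifnot(inherits(images, "image_set"), inherits(cfg, "feature_extractor_config"))
  if (length(images$images) == 0L) stop_input("empty image set")
  mu <- cfg$mean_subtraction
  if (identical(mu, "dataset")) {
    mu <- vapply(1:3, function(ch) {
      mean(vapply(images$images, function(im) mean(im[, , ch]), 0))
    }, 0)
  }
  out <- map(images$images, function(im) {
    if (length(dim(im)) != 3L || dim(im)[3] != 3L) stop_input("non-RGB image")
    rs <- resize_bilinear(im, cfg$input_size, cfg$input_size)
    for (ch in 1:3) rs[, , ch] <- rs[, , ch] - mu[ch]
    rs
  })
  res <- images
  res$images <- out
  attr(res, "preprocessed") <- TRUE
  res
}

#' Extract per-image deep features
#'
#' Runs each (preprocessed) image through the configured backbone and
#' returns one feature row per image in tidy form, with stable feature ids
#' as column names and the class label as the final `label` column.
#'
#' @param images an [image_set()], ideally from [preprocess_images()].
#' @param cfg a [feature_extractor_config()].
#' @return A tibble with `length(images)` rows and
#'   `backbone_output_dim(...) + 1` columns.
#' @export
#' @examples
#' imgs <- make_images(fixture_spec(n_per_class = 2, seed = 5))
#' cfg <- feature_extractor_config(input_size = 64, stub_width = 27)
#' extract_features(preprocess_images(imgs, cfg), cfg)
extract_features <- function(images, cfg = feature_extractor_config()) {
  stopifnot(inherits(images, "image_set"), inherits(cfg, "feature_extractor_config"))
  if (length(images$images) == 0L) stop_input("empty image set")
  if (cfg$backbone == "resnet50") {
    stop_environment(paste(
      "the `resnet50` backbone needs a deep-learning runtime (e.g. torch or",
      "tensorflow/keras), which is not installed. Install one and register",
      "it, or use `backbone = \"stub\"` for a dependency-free extractor.",
      "The resnet50 output length for this config would be",
      backbone_output_dim("resnet50", cfg$input_size)
    ))
  }
  w <- cfg$stub_width
  rows <- t(vapply(images$images, stub_features, numeric(w), width = w))
  colnames(rows) <- feature_ids(w)
  tbl <- as_tibble(rows)
  tbl$label <- images$manifest$label
  tbl
}

# Deterministic cheap extractor: average-pool each channel over a g x g
# grid (g chosen so 3 g^2 >= width) and keep the first `width` values,
# channel-major. Purely a function of pixel values, so identical images
# give identical rows.
stub_features <- function(img, width) {
  g <- ceiling(sqrt(width / 3))
  h <- dim(img)[1]; w <- dim(img)[2]
  ybin <- pmin(ceiling(seq_len(h) / (h / g)), g)
  xbin <- pmin(ceiling(seq_len(w) / (w / g)), g)
  feats <- numeric(0)
  for (ch in 1:3) {
    pooled <- tapply(as.vector(img[, , ch]),
                     list(ybin[row(img[, , ch])], xbin[col(img[, , ch])]),
                     mean)
    feats <- c(feats, as.vector(pooled))
  }
  feats[seq_len(width)]
}
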