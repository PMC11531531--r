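#' Augmentation configuration
#'
#' Controls the geometric augmentation applied to each input image: one
#' scaled copy (resize by `scale_factor`, then center-crop back to the
#' original geometry), one vertically flipped copy, and `n_rotations`
#' copies rotated by random angles drawn uniformly from
#' `[-rotation_range_deg, +rotation_range_deg]` (exact zero is re-drawn).
#'
#' @param scale_factor ratio for the scaled copy (default 1.20, i.e.
#'   scaling by 20%).
#' @param rotation_range_deg half-width in degrees of the rotation range
#'   (default 50).
#' @param n_rotations number of randomly rotated copies per image
#'   (default 3).
#' @param include_original whether the original image is emitted first
#'   (default TRUE).
#' @param seed integer seed for the rotation angle draws.
#' @return An `augmentation_config` object.
#' @export
augmentation_config <- function(scale_factor = 1.2, rotation_range_deg = 50,
                                n_rotations = 3, include_original = TRUE,
                                seed = 1L) {
  cfg <- list(
    scale_factor = check_positive(scale_factor, "scale_factor"),
    rotation_range_deg = check_positive(rotation_range_deg, "rotation_range_deg"),
    n_rotations = check_count(n_rotations, "n_rotations", min = 0L),
    include_original = isTRUE(include_original),
    seed = check_count(seed, "seed", min = 0L)
  )
  structure(cfg, class = "augmentation_config")
}

#' Augment a labeled image set
#'
#' For each input image emits, in order: the original (if configured), one
#' scaled copy, one vertically flipped copy, and `n_rotations` randomly
#' rotated copies. Labels propagate unchanged; provenance tags record the
#' transform (rotations include the drawn angle). All outputs share the
#' input geometry: the scaled copy is center-cropped back and rotations
#' use reflection padding so no black corners enter the feature extractor.
#'
#' With the defaults this yields 6 images per input (1 original + 5
#' augmented), so e.g. 481 inputs produce 2,405 new images.
#'
#' @param images an [image_set()].
#' @param cfg an [augmentation_config()].
#' @return An [image_set()] with
#'   `N * (include_original + 2 + n_rotations)` images, grouped
#'   original-first per input image.
#' @export
#' @examples
#' imgs <- make_images(fixture_spec(n_per_class = 1, seed = 1))
#' aug <- augment(imgs, augmentation_config(seed = 9))
#' glance(aug)
augment <- function(images, cfg = augmentation_config()) {
  stopifnot(inherits(images, "image_set"), inherits(cfg, "augmentation_config"))
  n <- length(images$images)
  if (n == 0L) return(image_set(list(), integer()))
  out_imgs <- list()
  out_lab <- integer()
  out_prov <- character()
  local_rng(cfg$seed, {
    for (i in seq_len(n)) {
      img <- images$images[[i]]
      lab <- images$manifest$label[i]
      h <- dim(img)[1]; w <- dim(img)[2]
      block_imgs <- list()
      block_prov <- character()
      if (cfg$include_original) {
        block_imgs <- c(block_imgs, list(img))
        block_prov <- c(block_prov, "original")
      }
      scaled <- center_crop(
        resize_bilinear(img, round(h * cfg$scale_factor), round(w * cfg$scale_factor)),
        h, w
      )
      block_imgs <- c(block_imgs, list(scaled), list(flip_vertical(img)))
      block_prov <- c(block_prov, "scaled", "flipped")
      if (cfg$n_rotations > 0L) {
        angles <- draw_angles(cfg$n_rotations, cfg$rotation_range_deg)
        for (a in angles) {
          block_imgs <- c(block_imgs, list(rotate_reflect(img, a)))
          block_prov <- c(block_prov, sprintf("rotated(%.2f)", a))
        }
      }
      out_imgs <- c(out_imgs, block_imgs)
      out_lab <- c(out_lab, rep(lab, length(block_imgs)))
      out_prov <- c(out_prov, block_prov)
    }
  })
  image_set(out_imgs, out_lab, out_prov)
}

# Uniform draws on [-range, range]; an exact 0 is re-drawn so every
# "rotated" copy really is rotated.
draw_angles <- function(k, range) {
  a <- runif(k, -range, range)
  while (any(a == 0)) a[a == 0] <- runif(sum(a == 0), -range, range)
  a
}

#' Count augmentation outputs without running the transforms
#'
#' Bookkeeping helper mirroring the augmentation arithmetic: with
#' `n_inputs` images the stage emits
#' `n_inputs * (include_original + 2 + n_rotations)` images in total, of
#' which `n_inputs * (2 + n_rotations)` are newly synthesized. Both counts
#' are exposed because "after augmentation" tallies in the literature
#' sometimes exclude the originals.
#'
#' @param n_inputs number of input images.
#' @param cfg an [augmentation_config()].
#' @return A one-row tibble with `n_inputs`, `n_total`, `n_new`.
#' @export
augmentation_counts <- function(n_inputs, cfg = augmentation_config()) {
  n_inputs <- check_count(n_inputs, "n_inputs", min = 0L)
  per <- as.integer(cfg$include_original) + 2L + cfg$n_rotations
  tibble(
    n_inputs = n_inputs,
    n_total = n_inputs * per,
    n_new = n_inputs * (2L + cfg$n_rotations)
  )
}
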