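#' Specification for synthetic fixtures
#'
#' Bundles the knobs of the synthetic image and feature-table generators:
#' how many samples per class, image geometry, feature-space dimensionality,
#' and how strongly the two classes are separated. The same spec drives both
#' generators so a whole pipeline run can be described by one object.
#'
#' @param n_per_class number of samples generated for each of the two
#'   classes (>= 1).
#' @param image_size side length in pixels of the square synthetic images
#'   (>= 32).
#' @param n_features number of columns in the synthetic feature table
#'   (>= 2).
#' @param n_informative how many feature dimensions carry class signal;
#'   the rest are pure noise. Must not exceed `n_features`.
#' @param class_separation dimensionless effect size: class means of the
#'   informative dimensions differ by `class_separation * noise_sd`.
#'   For images it scales the difference in blob density between classes.
#' @param noise_sd standard deviation of the Gaussian noise (> 0).
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   output.
#'
#' @return A `fixture_spec` object (a validated named list).
#' @export
#' @examples
#' fixture_spec(n_per_class = 10, class_separation = 4)
fixture_spec <- function(n_per_class = 50, image_size = 64, n_features = 50,
                         n_informative = 5, class_separation = 2,
                         noise_sd = 1, seed = 1L) {
  spec <- list(
    n_per_class = check_count(n_per_class, "n_per_class"),
    image_size = check_count(image_size, "image_size", min = 32L),
    n_features = check_count(n_features, "n_features", min = 2L),
    n_informative = check_count(n_informative, "n_informative", min = 1L),
    class_separation = as.numeric(class_separation),
    noise_sd = check_positive(noise_sd, "noise_sd"),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (spec$class_separation < 0) stop_config("`class_separation` must be >= 0")
  if (spec$n_informative > spec$n_features) {
    stop_config("`n_informative` exceeds `n_features`")
  }
  structure(spec, class = "fixture_spec")
}

#' Generate synthetic labeled images
#'
#' Produces blob/texture fields standing in for histopathology tiles:
#' class 1 ("cancer") images contain more dark nucleus-like blobs than
#' class 0, with the density gap scaled by `class_separation`. Only the
#' statistical separability matters; no attempt is made to mimic H&E stain
#' statistics.
#'
#' @param spec a [fixture_spec()].
#' @return An [image_set()] with `n_per_class` images per class, class-0
#'   images first, labels `c(0, ..., 0, 1, ..., 1)`.
#' @export
#' @examples
#' imgs <- make_images(fixture_spec(n_per_class = 3, seed = 7))
#' glance(imgs)
make_images <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  s <- spec$image_size
  base_blobs <- 6
  extra <- spec$class_separation * 4
  local_rng(spec$seed, {
    labels <- rep(c(0L, 1L), each = spec$n_per_class)
    imgs <- map(labels, function(lab) {
      lambda <- base_blobs + lab * extra
      n_blobs <- rpois(1L, lambda)
      # pale eosin-like background with pixel noise
      bg <- 0.82 + matrix(rnorm(s * s, 0, 0.02 * spec$noise_sd), s, s)
      canvas <- bg
      if (n_blobs > 0) {
        cy <- runif(n_blobs, 1, s); cx <- runif(n_blobs, 1, s)
        r <- runif(n_blobs, s / 24, s / 10)
        amp <- runif(n_blobs, 0.35, 0.6)
        yy <- matrix(seq_len(s), s, s)
        xx <- t(yy)
        for (b in seq_len(n_blobs)) {
          d2 <- (yy - cy[b])^2 + (xx - cx[b])^2
          canvas <- canvas - amp[b] * exp(-d2 / (2 * r[b]^2))
        }
      }
      canvas <- clip01(canvas)
      # darker blue-purple blobs on a pink field: channel-weighted copies
      arr <- array(0, dim = c(s, s, 3L))
      arr[, , 1] <- clip01(canvas * 0.95 + 0.05)
      arr[, , 2] <- clip01(canvas * 0.80)
      arr[, , 3] <- clip01(canvas * 0.90 + 0.03)
      arr
    })
    image_set(imgs, labels)
  })
}

#' Generate a synthetic feature table
#'
#' Gaussian class-conditional features in tidy form: one row per sample,
#' feature columns `f<k>` plus an integer `label` column. Exactly
#' `n_informative` randomly chosen dimensions carry class signal (their
#' class means differ by `class_separation * noise_sd`); the rest are pure
#' noise. Which dimensions are informative is recorded in the
#' `"informative"` attribute (see [informative_features()]).
#'
#' @param spec a [fixture_spec()].
#' @return A tibble with `2 * n_per_class` rows and `n_features + 1`
#'   columns, rows in class order (all class 0, then all class 1).
#' @export
#' @examples
#' tbl <- make_feature_table(fixture_spec(n_per_class = 20, seed = 3))
#' informative_features(tbl)
make_feature_table <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- 2L * spec$n_per_class
  p <- spec$n_features
  delta <- spec$class_separation * spec$noise_sd
  local_rng(spec$seed, {
    informative <- sort(sample.int(p, spec$n_informative))
    labels <- rep(c(0L, 1L), each = spec$n_per_class)
    m <- matrix(rnorm(n * p, 0, spec$noise_sd), n, p)
    m[labels == 1L, informative] <- m[labels == 1L, informative] + delta
    colnames(m) <- feature_ids(p)
    tbl <- as_tibble(m)
    tbl$label <- labels
    attr(tbl, "informative") <- feature_ids(p)[informative]
    tbl
  })
}

#' Informative dimensions of a synthetic feature table
#'
#' @param table a tibble produced by [make_feature_table()].
#' @return Character vector of column names that carry class signal.
#' @export
informative_features <- function(table) {
  attr(table, "informative", exact = TRUE)
}

feature_ids <- function(p) sprintf("f%04d", seq_len(p))

#' Write / read a feature table as CSV
#'
#' The on-disk format is a plain CSV whose final column is `label`; all
#' other columns are numeric features.
#'
#' @param table tibble with feature columns and a `label` column.
#' @param path file path.
#' @return `write_feature_csv()` returns `path` invisibly;
#'   `read_feature_csv()` returns the tibble.
#' @export
write_feature_csv <- function(table, path) {
  stopifnot("label" %in% names(table))
  ord <- c(setdiff(names(table), "label"), "label")
  readr::write_csv(table[, ord], path)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  if (!"label" %in% names(tbl)) stop_input("feature CSV must have a `label` column")
  tbl$label <- as.integer(tbl$label)
  tbl
}
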