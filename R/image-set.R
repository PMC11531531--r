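#' Labeled image sets
#'
#' The container moved between the augmentation and feature-extraction
#' stages. Images are stored as numeric arrays of shape height x width x 3
#' with intensities in \[0, 1\] (8-bit on disk); the manifest is a tibble
#' with one row per image carrying its binary class label (0 = non-cancer,
#' 1 = cancer) and a provenance tag (`"original"`, `"scaled"`, `"flipped"`,
#' or `"rotated(<deg>)"`).
#'
#' @param images list of height x width x 3 numeric arrays.
#' @param labels integer vector of class labels in \{0, 1\}, one per image.
#' @param provenance character vector of per-image provenance tags
#'   (defaults to `"original"`).
#'
#' @return An `image_set`: a list with elements `images` (list of arrays)
#'   and `manifest` (tibble with columns `id`, `label`, `provenance`).
#' @export
#' @examples
#' img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
#' image_set(list(img), labels = 1L)
image_set <- function(images, labels, provenance = NULL) {
  if (!is.list(images)) stop_input("`images` must be a list of arrays")
  labels <- as.integer(labels)
  if (length(images) != length(labels)) {
    stop_input("`images` and `labels` must have equal length")
  }
  if (length(labels) && !all(labels %in% c(0L, 1L))) {
    stop_input("labels must be 0 (non-cancer) or 1 (cancer)")
  }
  for (im in images) {
    if (!is.array(im) || length(dim(im)) != 3L || dim(im)[3] != 3L) {
      stop_input("each image must be a height x width x 3 array (RGB)")
    }
    if (any(dim(im)[1:2] == 0L)) stop_input("degenerate image with 0 pixels")
  }
  provenance <- provenance %||% rep("original", length(images))
  structure(
    list(
      images = images,
      manifest = tibble(
        id = seq_along(images),
        label = labels,
        provenance = as.character(provenance)
      )
    ),
    class = "image_set"
  )
}

#' @export
print.image_set <- function(x, ...) {
  n <- length(x$images)
  cat(sprintf("<image_set> %d images", n))
  if (n) {
    d <- dim(x$images[[1]])
    cat(sprintf(" (first %dx%dx%d); labels: %s", d[1], d[2], d[3],
                paste(sprintf("%d x class %s", table(x$manifest$label),
                              names(table(x$manifest$label))),
                      collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.image_set <- function(x) length(x$images)

#' Number of images and label counts
#'
#' @param x an `image_set`.
#' @param ... unused.
#' @return A one-row tibble with `n_images`, `n_class0`, `n_class1` and the
#'   number of distinct provenance tags.
#' @method glance image_set
#' @export
glance.image_set <- function(x, ...) {
  tibble(
    n_images = length(x$images),
    n_class0 = sum(x$manifest$label == 0L),
    n_class1 = sum(x$manifest$label == 1L),
    n_provenance = length(unique(x$manifest$provenance))
  )
}

#' Write an image set to a directory of PNGs plus a labels table
#'
#' Files are named `img_<id>.png`; the labels table is a CSV with columns
#' `filename,label,provenance`.
#'
#' @param x an `image_set`.
#' @param dir output directory (created if missing).
#' @param labels_file name of the labels CSV inside `dir`.
#' @return The manifest tibble (invisibly), with the written filenames.
#' @export
write_image_set <- function(x, dir, labels_file = "labels.csv") {
  stopifnot(inherits(x, "image_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fns <- sprintf("img_%05d.png", x$manifest$id)
  for (i in seq_along(x$images)) {
    png::writePNG(clip01(x$images[[i]]), file.path(dir, fns[i]))
  }
  man <- mutate(x$manifest, filename = fns)[, c("filename", "label", "provenance")]
  readr::write_csv(man, file.path(dir, labels_file))
  invisible(man)
}

#' Read an image set from a directory of PNGs plus a labels table
#'
#' @param dir directory containing the images and the labels CSV.
#' @param labels_file name of the labels CSV (columns `filename,label`,
#'   optionally `provenance`).
#' @return An [image_set()].
#' @export
read_image_set <- function(dir, labels_file = "labels.csv") {
  man <- readr::read_csv(file.path(dir, labels_file), show_col_types = FALSE)
  if (!all(c("filename", "label") %in% names(man))) {
    stop_input("labels table must have columns `filename` and `label`")
  }
  imgs <- map(man$filename, function(fn) {
    im <- png::readPNG(file.path(dir, fn))
    if (length(dim(im)) == 2L) im <- array(rep(im, 3L), dim = c(dim(im), 3L))
    im[, , 1:3, drop = FALSE]
  })
  image_set(imgs, man$label, man$provenance %||% NULL)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
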