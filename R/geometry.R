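# Geometric primitives for the augmentation stage: bilinear resampling with
# reflection padding. Kept internal; augment() and preprocess_images() are
# the public surface.

# Reflect a continuous 1-based coordinate into [1, n] (mirror boundary).
reflect_coord <- function(t, n) {
  if (n == 1L) return(rep(1, length(t)))
  period <- 2 * (n - 1)
  u <- (t - 1) %% period
  u <- ifelse(u > (n - 1), period - u, u)
  u + 1
}

# Sample img (h x w x 3) at continuous coordinates given by the outer grid
# of sy (length H) rows x sx columns, or full H x W matrices. Bilinear
# interpolation; out-of-range coordinates are mirrored.
bilinear_grid_sample <- function(img, sy, sx) {
  h <- dim(img)[1]; w <- dim(img)[2]
  H <- nrow(sy); W <- ncol(sy)
  ys <- reflect_coord(as.vector(sy), h)
  xs <- reflect_coord(as.vector(sx), w)
  y0 <- pmin(floor(ys), max(h - 1L, 1L)); y1 <- pmin(y0 + 1L, h)
  x0 <- pmin(floor(xs), max(w - 1L, 1L)); x1 <- pmin(x0 + 1L, w)
  wy <- ys - y0; wx <- xs - x0
  out <- array(0, dim = c(H, W, 3L))
  for (ch in 1:3) {
    plane <- img[, , ch]
    v <- (1 - wy) * (1 - wx) * plane[cbind(y0, x0)] +
         (1 - wy) * wx       * plane[cbind(y0, x1)] +
         wy       * (1 - wx) * plane[cbind(y1, x0)] +
         wy       * wx       * plane[cbind(y1, x1)]
    out[, , ch] <- matrix(v, H, W)
  }
  out
}

# Bilinear resize to out_h x out_w, aligning pixel centers so that the
# identity size is an exact copy.
resize_bilinear <- function(img, out_h, out_w) {
  h <- dim(img)[1]; w <- dim(img)[2]
  ys <- (seq_len(out_h) - 0.5) * (h / out_h) + 0.5
  xs <- (seq_len(out_w) - 0.5) * (w / out_w) + 0.5
  sy <- matrix(ys, out_h, out_w)
  sx <- matrix(xs, out_h, out_w, byrow = TRUE)
  bilinear_grid_sample(img, sy, sx)
}

center_crop <- function(img, out_h, out_w) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (out_h > h || out_w > w) stop_input("crop larger than image")
  r0 <- floor((h - out_h) / 2)
  c0 <- floor((w - out_w) / 2)
  img[r0 + seq_len(out_h), c0 + seq_len(out_w), , drop = FALSE]
}

flip_vertical <- function(img) {
  img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
}

# Rotate about the image center by angle_deg (counter-clockwise), same
# output geometry, reflection padding at the borders. A forced angle of 0
# reproduces the input exactly (interpolation weights collapse to 1).
rotate_reflect <- function(img, angle_deg) {
  h <- dim(img)[1]; w <- dim(img)[2]
  a <- angle_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  dy <- seq_len(h) - cy
  dx <- seq_len(w) - cx
  sy <- cy + outer(dy * cos(a), dx * sin(a), "+")
  sx <- cx + outer(-dy * sin(a), dx * cos(a), "+")
  bilinear_grid_sample(img, sy, sx)
}
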