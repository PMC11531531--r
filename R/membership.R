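#' Membership functions
#'
#' Constructors for the membership-function kinds used throughout the
#' fuzzy stages. All evaluate into \[0, 1\] for every finite input.
#'
#' * `mf_triangular(a, b, c)` — 0 below `a`, rises linearly to 1 at the
#'   apex `b`, falls linearly to 0 at `c`, 0 beyond; compact support
#'   `[a, c]`.
#' * `mf_trapezoidal(a, b, c, d)` — linear rise on `[a, b]`, flat top 1 on
#'   `[b, c]`, linear fall on `[c, d]`.
#' * `mf_gaussian(center, sigma)` — `exp(-(x - center)^2 / (2 sigma^2))`.
#' * `mf_bell(center, a, b)` — generalized bell
#'   `1 / (1 + |(x - center) / a|^(2b))`.
#' * `mf_piecewise_linear(x, y)` — interpolates the knots `(x, y)` with
#'   `y` in \[0, 1\]; constant extension outside the knot range.
#'
#' @param a,b,c,d shape parameters (see above; for the triangle
#'   `a <= b <= c`).
#' @param center,sigma Gaussian center and width (`sigma > 0`).
#' @param x,y knot coordinates for the piecewise-linear kind
#'   (`x` strictly increasing, `y` in \[0, 1\]).
#' @return A `membership_fn` object.
#' @name membership
#' @examples
#' eval_mf(mf_triangular(0, 1, 2), c(0.5, 1, 5))
NULL

new_mf <- function(kind, params) {
  structure(list(kind = kind, params = params), class = "membership_fn")
}

#' @rdname membership
#' @export
mf_triangular <- function(a, b, c) {
  if (!(a <= b && b <= c)) stop_config("triangular mf needs a <= b <= c")
  new_mf("triangular", list(a = a, b = b, c = c))
}

#' @rdname membership
#' @export
mf_trapezoidal <- function(a, b, c, d) {
  if (!(a <= b && b <= c && c <= d)) stop_config("trapezoidal mf needs a <= b <= c <= d")
  new_mf("trapezoidal", list(a = a, b = b, c = c, d = d))
}

#' @rdname membership
#' @export
mf_gaussian <- function(center, sigma) {
  if (sigma <= 0) stop_config("gaussian mf needs sigma > 0")
  new_mf("gaussian", list(center = center, sigma = sigma))
}

#' @rdname membership
#' @export
mf_bell <- function(center, a, b) {
  if (a <= 0 || b <= 0) stop_config("bell mf needs a > 0 and b > 0")
  new_mf("bell", list(center = center, a = a, b = b))
}

#' @rdname membership
#' @export
mf_piecewise_linear <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop_config("piecewise-linear mf needs matching knot vectors of length >= 2")
  }
  if (any(diff(x) <= 0)) stop_config("knot x values must be strictly increasing")
  if (any(y < 0 | y > 1)) stop_config("knot y values must lie in [0, 1]")
  new_mf("piecewise_linear", list(x = x, y = y))
}

#' Evaluate a membership function
#'
#' Total on the reals; vectorized over `x`; always returns values in
#' \[0, 1\].
#'
#' @param mf a `membership_fn`.
#' @param x numeric vector.
#' @return Numeric vector of membership degrees.
#' @export
eval_mf <- function(mf, x) {
  stopifnot(inherits(mf, "membership_fn"))
  p <- mf$params
  out <- switch(
    mf$kind,
    triangular = {
      v <- numeric(length(x))
      if (p$b > p$a) {
        up <- x >= p$a & x <= p$b
        v[up] <- (x[up] - p$a) / (p$b - p$a)
      } else v[x == p$b] <- 1
      if (p$c > p$b) {
        dn <- x > p$b & x <= p$c
        v[dn] <- (p$c - x[dn]) / (p$c - p$b)
      }
      v[x == p$b] <- 1
      v
    },
    trapezoidal = {
      v <- numeric(length(x))
      if (p$b > p$a) {
        up <- x >= p$a & x < p$b
        v[up] <- (x[up] - p$a) / (p$b - p$a)
      }
      v[x >= p$b & x <= p$c] <- 1
      if (p$d > p$c) {
        dn <- x > p$c & x <= p$d
        v[dn] <- (p$d - x[dn]) / (p$d - p$c)
      }
      v
    },
    gaussian = exp(-(x - p$center)^2 / (2 * p$sigma^2)),
    bell = 1 / (1 + abs((x - p$center) / p$a)^(2 * p$b)),
    piecewise_linear = stats::approx(p$x, p$y, xout = x, rule = 2)$y,
    stop_config(sprintf("unknown membership kind `%s`", mf$kind))
  )
  pmin(pmax(out, 0), 1)
}

#' @export
print.membership_fn <- function(x, ...) {
  cat(sprintf("<membership_fn: %s> %s\n", x$kind,
              paste(names(x$params),
                    vapply(x$params, function(v) paste(signif(v, 4), collapse = ","), ""),
                    sep = "=", collapse = " ")))
  invisible(x)
}

# Center (apex / location) of an mf; used to order partitions.
mf_center <- function(mf) {
  p <- mf$params
  switch(mf$kind,
    triangular = p$b,
    trapezoidal = (p$b + p$c) / 2,
    gaussian = p$center,
    bell = p$center,
    piecewise_linear = p$x[which.max(p$y)]
  )
}
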