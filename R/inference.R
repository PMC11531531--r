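#' Max-min rule aggregation
#'
#' Combines rule firing strengths into one output fuzzy set on a grid:
#' per grid point, the maximum over rules of
#' `min(activation_i, consequent-membership_i)` — each rule's consequent
#' set is clipped at the rule's activation and the clipped sets are
#' union-ed pointwise.
#'
#' @param activations per-rule firing strengths in \[0, 1\].
#' @param consequent_mfs list of `membership_fn`, one consequent set per
#'   rule (same length as `activations`).
#' @param grid numeric grid of output values on which the aggregated set
#'   is evaluated.
#' @return A tibble with columns `y` (the grid) and `membership`.
#' @export
#' @examples
#' out <- aggregate_maxmin(c(0.7, 0.3),
#'                         list(mf_triangular(0, 1, 2), mf_triangular(1, 2, 3)),
#'                         seq(0, 3, length.out = 101))
#' defuzz_centroid(out)
aggregate_maxmin <- function(activations, consequent_mfs, grid) {
  if (length(activations) != length(consequent_mfs)) {
    stop_input("`activations` and `consequent_mfs` must have equal length")
  }
  if (any(activations < 0 | activations > 1)) {
    stop_input("activations must lie in [0, 1]")
  }
  mu <- numeric(length(grid))
  for (i in seq_along(activations)) {
    mu <- pmax(mu, pmin(activations[i], eval_mf(consequent_mfs[[i]], grid)))
  }
  tibble(y = grid, membership = mu)
}

#' Centroid defuzzification
#'
#' Collapses a fuzzy set given on a discretized grid to its center of
#' gravity `int y mu(y) dy / int mu(y) dy`, with the integrals evaluated
#' by the trapezoidal rule on the grid.
#'
#' @param fuzzy_set a tibble with columns `y` and `membership` (as
#'   returned by [aggregate_maxmin()]), or a list with those elements.
#' @return The crisp centroid value.
#' @export
defuzz_centroid <- function(fuzzy_set) {
  y <- fuzzy_set$y
  mu <- fuzzy_set$membership
  if (is.null(y) || is.null(mu) || length(y) != length(mu)) {
    stop_input("`fuzzy_set` needs matching `y` and `membership` vectors")
  }
  area <- pracma::trapz(y, mu)
  if (area <= 0) stop_input("cannot defuzzify an identically zero fuzzy set")
  pracma::trapz(y, y * mu) / area
}
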