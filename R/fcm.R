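#' Fuzzy c-means clustering of a numeric vector
#'
#' Minimizes the weighted within-cluster objective
#' `J = sum_i sum_j w_ij^m ||x_i - mu_j||^2` by the standard alternating
#' updates: centers as membership-weighted means, memberships from inverse
#' squared distances raised to `1 / (m - 1)`. Memberships are
#' row-normalized (each observation's memberships sum to 1) and the
#' objective is non-increasing across iterations; the per-iteration trace
#' is returned so that can be inspected. Centers are returned sorted
#' ascending with membership columns reordered to match.
#'
#' @param values numeric vector to cluster.
#' @param n_clusters number of clusters (at most the number of distinct
#'   values).
#' @param m fuzzifier exponent (> 1; default 2).
#' @param tol convergence tolerance on the relative objective decrease.
#' @param max_iter iteration cap; non-convergence warns and returns the
#'   best iterate.
#' @param seed integer seed for the membership initialization.
#' @return A list with `centers` (ascending), `memberships`
#'   (`length(values)` x `n_clusters`, rows summing to 1), `objective`
#'   (per-iteration trace), and `converged`.
#' @export
#' @examples
#' x <- c(rnorm(40, 0, 0.1), rnorm(40, 5, 0.1))
#' fcm_cluster(x, 2, seed = 1)$centers
fcm_cluster <- function(values, n_clusters, m = 2, tol = 1e-8,
                        max_iter = 200, seed = 1L) {
  values <- as.numeric(values)
  n_clusters <- check_count(n_clusters, "n_clusters")
  if (n_clusters > length(unique(values))) {
    stop_input("`n_clusters` exceeds the number of distinct values")
  }
  if (m <= 1) stop_config("fuzzifier `m` must be > 1")
  n <- length(values)
  if (n_clusters == 1L) {
    return(list(centers = mean(values),
                memberships = matrix(1, n, 1),
                objective = sum((values - mean(values))^2),
                converged = TRUE))
  }
  local_rng(seed, {
    w <- matrix(runif(n * n_clusters), n, n_clusters)
    w <- w / rowSums(w)
    obj <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      wm <- w^m
      centers <- colSums(wm * values) / colSums(wm)
      d2 <- outer(values, centers, function(x, c) (x - c)^2)
      obj[it] <- sum(wm * d2)
      # membership update; observations sitting on a center get weight 1
      zero <- d2 < .Machine$double.eps
      inv <- d2^(-1 / (m - 1))
      w_new <- inv / rowSums(inv)
      hit <- rowSums(zero) > 0
      if (any(hit)) {
        w_new[hit, ] <- 0
        w_new[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
      }
      if (it > 1 && abs(obj[it - 1] - obj[it]) <= tol * max(obj[it - 1], 1e-300)) {
        w <- w_new
        converged <- TRUE
        break
      }
      w <- w_new
    }
    if (!converged) {
      warn(sprintf("fuzzy c-means did not converge in %d iterations; returning best iterate",
                   max_iter))
    }
    ord <- order(centers)
    list(centers = centers[ord],
         memberships = w[, ord, drop = FALSE],
         objective = obj,
         converged = converged)
  })
}
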