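#' Fuzzy partitions
#'
#' A fuzzy partition discretizes one numeric variable into an ordered bank
#' of membership functions ("levels"), ordered by increasing center, whose
#' supports jointly cover the variable's observed domain.
#'
#' @param variable_id name of the variable.
#' @param mfs list of [membership][mf_triangular] functions, center-ordered.
#' @param domain numeric length-2 `c(min, max)`.
#' @return A `fuzzy_partition` object.
#' @export
fuzzy_partition <- function(variable_id, mfs, domain) {
  centers <- vapply(mfs, mf_center, 0)
  if (is.unsorted(centers)) {
    ord <- order(centers)
    mfs <- mfs[ord]
  }
  structure(list(variable_id = variable_id, mfs = mfs,
                 domain = as.numeric(domain)),
            class = "fuzzy_partition")
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat(sprintf("<fuzzy_partition> `%s`: %d %s level(s) on [%.4g, %.4g]\n",
              x$variable_id, length(x$mfs),
              if (length(x$mfs)) x$mfs[[1]]$kind else "?",
              x$domain[1], x$domain[2]))
  invisible(x)
}

# n x L matrix of membership degrees of `values` in each level.
partition_memberships <- function(partition, values) {
  m <- vapply(partition$mfs, eval_mf, numeric(length(values)), x = values)
  matrix(m, nrow = length(values))
}

#' Build fuzzy partitions for the columns of a feature table
#'
#' Per variable, lays `n_levels` membership functions over the observed
#' `[min, max]` domain. With `placement = "uniform"` the centers form an
#' even grid and neighboring triangular levels cross at membership 0.5;
#' with `placement = "fcm"` the centers come from fuzzy c-means clustering
#' of the observed values ([fcm_cluster()]). Edge levels extend one
#' spacing beyond the domain so every domain point has positive
#' membership. A constant column yields a single degenerate level and a
#' warning.
#'
#' @param table tibble whose numeric columns (all but `label`, unless
#'   `columns` is given) are partitioned.
#' @param n_levels levels per variable (>= 2; default 9, giving level
#'   indices 0-8).
#' @param mf_kind `"triangular"` (default), `"trapezoidal"`,
#'   `"piecewise_linear"`, `"gaussian"`, or `"bell"`.
#' @param placement `"uniform"` or `"fcm"`.
#' @param columns optional character vector of columns to partition.
#' @param seed integer seed (used by fcm placement).
#' @return Named list of `fuzzy_partition` objects, one per column.
#' @export
#' @examples
#' tbl <- tibble::tibble(x = seq(0, 8, by = 0.5), label = 0L)
#' parts <- build_partitions(tbl, n_levels = 9)
#' vapply(parts$x$mfs, fuzzyhisto:::mf_center, 0)  # 0 1 ... 8
build_partitions <- function(table, n_levels = 9, mf_kind = "triangular",
                             placement = c("uniform", "fcm"),
                             columns = NULL, seed = 1L) {
  placement <- match.arg(placement)
  n_levels <- check_count(n_levels, "n_levels", min = 2L)
  cols <- columns %||% setdiff(names(table), "label")
  parts <- lapply(cols, function(cn) {
    v <- table[[cn]]
    lo <- min(v); hi <- max(v)
    if (hi <= lo) {
      warn(sprintf("column `%s` is constant; degenerate single-level partition", cn))
      return(fuzzy_partition(cn, list(mf_triangular(lo - 1, lo, lo + 1)),
                             c(lo, lo)))
    }
    centers <- if (placement == "uniform") {
      seq(lo, hi, length.out = n_levels)
    } else {
      fcm_cluster(v, n_clusters = n_levels, seed = seed)$centers
    }
    fuzzy_partition(cn, mfs_from_centers(centers, mf_kind, lo, hi), c(lo, hi))
  })
  names(parts) <- cols
  parts
}

# Lay one mf of `kind` per center; spacing-derived shape parameters.
mfs_from_centers <- function(centers, kind, lo, hi) {
  L <- length(centers)
  gaps <- diff(centers)
  # left/right neighbor distance per center (edge levels reuse the edge gap)
  left <- c(gaps[1], gaps)
  right <- c(gaps, gaps[L - 1])
  lapply(seq_len(L), function(k) {
    c0 <- centers[k]
    switch(
      kind,
      triangular = mf_triangular(c0 - left[k], c0, c0 + right[k]),
      piecewise_linear = mf_piecewise_linear(
        c(c0 - left[k], c0, c0 + right[k]), c(0, 1, 0)
      ),
      trapezoidal = mf_trapezoidal(c0 - left[k], c0 - left[k] / 4,
                                   c0 + right[k] / 4, c0 + right[k]),
      gaussian = mf_gaussian(c0, (left[k] + right[k]) / 4),
      bell = mf_bell(c0, (left[k] + right[k]) / 4, 2),
      stop_config(sprintf("unknown membership kind `%s`", kind))
    )
  })
}

#' Plot the membership functions of a partition
#'
#' @param object a `fuzzy_partition`.
#' @param n_grid resolution of the evaluation grid.
#' @param ... unused.
#' @return A ggplot with one curve per level.
#' @method autoplot fuzzy_partition
#' @export
autoplot.fuzzy_partition <- function(object, n_grid = 301, ...) {
  pad <- diff(object$domain) * 0.1 + 1e-9
  xs <- seq(object$domain[1] - pad, object$domain[2] + pad, length.out = n_grid)
  df <- purrr::imap(object$mfs, function(mf, k) {
    tibble(x = xs, membership = eval_mf(mf, xs), level = factor(k - 1))
  }) |> list_rbind()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$membership,
                                   colour = .data$level)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = sprintf("Partition of `%s`", object$variable_id),
                  x = object$variable_id, y = "membership") +
    ggplot2::theme_minimal()
}
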