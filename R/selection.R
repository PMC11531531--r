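#' Shannon entropy of a class distribution
#'
#' The impurity measure behind the decision-tree ranker:
#' `-sum(p * log2(p))` with the convention `0 * log2(0) = 0`. Returned in
#' bits.
#'
#' @param class_probs nonnegative probabilities summing to 1.
#' @param tol tolerance on the sum-to-one check.
#' @return Nonnegative entropy in bits.
#' @export
#' @examples
#' shannon_entropy(c(0.5, 0.5))          # 1
#' shannon_entropy(rep(0.25, 4))         # 2
shannon_entropy <- function(class_probs, tol = 1e-8) {
  if (any(class_probs < 0)) stop_input("probabilities must be nonnegative")
  if (abs(sum(class_probs) - 1) > tol) {
    stop_input("probabilities must sum to 1")
  }
  p <- class_probs[class_probs > 0]
  -sum(p * log2(p))
}

#' Recursive feature elimination with decision trees
#'
#' Iteratively ranks features with entropy-split decision trees scored over
#' stratified folds, drops the least important `step` fraction each round,
#' and stops when `target_n_features` remain. Per round, one tree is fit
#' per fold on the training folds; held-out fold accuracies are averaged
#' and recorded, and the trees' impurity-decrease importances (averaged
#' over folds; features unused by every tree score 0) drive the
#' elimination. Ties are broken by keeping the lower column index.
#'
#' @param table tibble of numeric feature columns plus a `label` column
#'   with two classes.
#' @param target_n_features number of features to retain (default 10000,
#'   capped by the available columns at the caller's risk).
#' @param n_folds number of stratified folds (>= 2, default 5).
#' @param step fraction of the surviving features dropped per round
#'   (0 < step < 1, default 0.1); at least one feature is dropped per
#'   round while above the target.
#' @param max_depth optional depth cap on the trees.
#' @param seed integer seed (fold assignment).
#' @return An object of class `rfe_result` with components
#'   `ranking` (tibble: `feature`, `rank`, most important first),
#'   `per_round` (tibble: `round`, `n_features`, `mean_accuracy`),
#'   `retained` (character vector in original column order), and
#'   `reduced` (the input table restricted to retained columns + label).
#' @export
#' @examples
#' tbl <- make_feature_table(fixture_spec(n_per_class = 30, n_features = 12,
#'                                        n_informative = 2,
#'                                        class_separation = 5, seed = 2))
#' fit <- rfe(tbl, target_n_features = 4, seed = 2)
#' glance(fit)
rfe <- function(table, target_n_features = 10000, n_folds = 5, step = 0.1,
                max_depth = NULL, seed = 1L) {
  feats <- setdiff(names(table), "label")
  if (!"label" %in% names(table)) stop_input("table must have a `label` column")
  y <- as.integer(table$label)
  if (length(unique(y)) < 2L) stop_input("labels contain a single class")
  target_n_features <- check_count(target_n_features, "target_n_features")
  if (target_n_features > length(feats)) {
    stop_input("`target_n_features` exceeds the number of available features")
  }
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  if (step <= 0 || step >= 1) stop_config("`step` must be in (0, 1)")

  folds <- local_rng(seed, stratified_folds(y, n_folds))
  current <- feats
  eliminated <- character(0)  # importance-descending among the dropped
  per_round <- list()
  round_i <- 0L
  repeat {
    round_i <- round_i + 1L
    sc <- score_features(table, current, y, folds, max_depth)
    per_round[[round_i]] <- tibble(
      round = round_i, n_features = length(current),
      mean_accuracy = sc$accuracy
    )
    if (length(current) == target_n_features) {
      final_importance <- sc$importance
      break
    }
    n_drop <- max(1L, floor(step * length(current)))
    n_drop <- min(n_drop, length(current) - target_n_features)
    # lowest importance dropped; among ties the higher column index goes
    idx <- match(current, feats)
    ord <- order(sc$importance, -idx)  # ascending importance, ties: higher idx first
    drop <- current[ord[seq_len(n_drop)]]  # weakest first
    # later rounds outrank earlier ones; within a round, stronger first
    eliminated <- c(rev(drop), eliminated)
    current <- setdiff(current, drop)
  }
  imp_ord <- order(-final_importance, match(current, feats))
  ranking <- tibble(
    feature = c(current[imp_ord], eliminated),
    rank = seq_len(length(feats))
  )
  structure(
    list(
      ranking = ranking,
      per_round = list_rbind(per_round),
      retained = feats[feats %in% current],
      reduced = table[, c(feats[feats %in% current], "label")]
    ),
    class = "rfe_result"
  )
}

# Stratified fold ids: within each class, shuffled samples dealt round-robin.
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# One RFE round: per fold, an entropy-split tree on the training folds;
# held-out accuracy and impurity-decrease importances averaged over folds.
score_features <- function(table, current, y, folds, max_depth) {
  n_folds <- max(folds)
  imp <- numeric(length(current))
  names(imp) <- current
  acc <- numeric(n_folds)
  df <- as.data.frame(table[, current, drop = FALSE])
  df$.y <- factor(y)
  ctrl <- rpart::rpart.control(
    xval = 0, cp = 0.001, minsplit = 10,
    maxdepth = if (is.null(max_depth)) 30 else max_depth
  )
  for (k in seq_len(n_folds)) {
    train <- df[folds != k, , drop = FALSE]
    test <- df[folds == k, , drop = FALSE]
    fit <- rpart::rpart(.y ~ ., data = train, method = "class",
                        parms = list(split = "information"), control = ctrl)
    pred <- predict(fit, test, type = "class")
    acc[k] <- mean(pred == test$.y)
    vi <- fit$variable.importance
    if (!is.null(vi)) {
      hit <- intersect(names(vi), current)
      imp[hit] <- imp[hit] + vi[hit] / n_folds
    }
  }
  list(importance = imp, accuracy = mean(acc))
}

#' @export
print.rfe_result <- function(x, ...) {
  cat(sprintf("<rfe_result> %d -> %d features over %d round(s); final mean fold accuracy %.3f\n",
              nrow(x$ranking), length(x$retained), nrow(x$per_round),
              x$per_round$mean_accuracy[nrow(x$per_round)]))
  invisible(x)
}

#' Tidy a feature-elimination result
#'
#' @param x an `rfe_result`.
#' @param ... unused.
#' @return The ranking tibble (`feature`, `rank`, `retained`).
#' @method tidy rfe_result
#' @export
tidy.rfe_result <- function(x, ...) {
  mutate(x$ranking, retained = .data$feature %in% x$retained)
}

#' @rdname tidy.rfe_result
#' @return `glance()`: one row with feature counts, rounds, and final mean
#'   fold accuracy.
#' @method glance rfe_result
#' @export
glance.rfe_result <- function(x, ...) {
  tibble(
    n_features_in = nrow(x$ranking),
    n_features_out = length(x$retained),
    n_rounds = nrow(x$per_round),
    final_accuracy = x$per_round$mean_accuracy[nrow(x$per_round)]
  )
}

#' Plot per-round fold accuracy of an RFE run
#'
#' @param object an `rfe_result`.
#' @param ... unused.
#' @return A ggplot of mean fold accuracy against surviving feature count.
#' @method autoplot rfe_result
#' @export
autoplot.rfe_result <- function(object, ...) {
  ggplot2::ggplot(object$per_round,
                  ggplot2::aes(x = .data$n_features, y = .data$mean_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "surviving features", y = "mean fold accuracy",
                  title = "Recursive feature elimination") +
    ggplot2::theme_minimal()
}
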