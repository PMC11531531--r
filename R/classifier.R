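#' Elementwise rectified linear unit
#'
#' `max(0, x)`, elementwise on vectors and matrices.
#'
#' @param x numeric vector or matrix.
#' @return Same shape as `x`.
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Row-wise softmax
#'
#' `exp(z_i) / sum_j exp(z_j)` per row, computed with the row-maximum
#' shifted out so arbitrarily large scores do not overflow. Shift
#' invariant: adding a constant to a row leaves its output unchanged.
#'
#' @param z numeric vector or matrix of scores (vectors are treated as a
#'   single row).
#' @return Matrix of probabilities with rows summing to 1.
#' @export
#' @examples
#' softmax(c(0, 0))        # 0.5 0.5
#' softmax(c(1000, 0))     # ~1, ~0 without overflow
softmax <- function(z) {
  if (is.vector(z)) z <- matrix(z, nrow = 1L)
  if (any(!is.finite(z))) stop_input("softmax requires finite scores")
  e <- exp(z - apply(z, 1L, max))
  e / rowSums(e)
}

#' Fuzzification: per-rule firing strengths of crisp samples
#'
#' For each sample s and rule i computes
#' `alpha_is = prod_j mu_{i j}(x_sj)`: the product, over the rule
#' variables, of the membership of the sample's value in the rule's
#' antecedent level. Activations lie in \[0, 1\]; a single zero factor
#' annihilates the rule.
#'
#' @param x data frame / tibble containing the rule-variable columns
#'   (extra columns are ignored).
#' @param rule_base a [wang_mendel()] rule base.
#' @return An `nrow(x)` x `n_rules` matrix of activations.
#' @export
fuzzify <- function(x, rule_base) {
  stopifnot(inherits(rule_base, "rule_base"))
  vars <- names(rule_base$partitions)
  missing_cols <- setdiff(vars, colnames(x))
  if (length(missing_cols)) {
    stop_input(paste("sample lacks rule-variable column(s):",
                     paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(x)
  M <- nrow(rule_base$rules)
  alpha <- matrix(1, n, M)
  for (j in seq_along(vars)) {
    mm <- partition_memberships(rule_base$partitions[[vars[j]]], x[[vars[j]]])
    lev <- rule_base$rules[[vars[j]]]  # 0-based level index per rule
    alpha <- alpha * mm[, lev + 1L, drop = FALSE]
  }
  alpha
}

#' Defuzzification: rule activations to class scores
#'
#' The weighted-sum defuzzification `beta_sk = sum_i alpha_is w_ik`, i.e.
#' a plain matrix product of the activation matrix with the rule-to-class
#' weight matrix; linear in both arguments.
#'
#' @param alpha `n` x `M` activation matrix (or length-`M` vector).
#' @param w `M` x `K` rule-to-class weight matrix.
#' @return `n` x `K` score matrix.
#' @export
defuzzify <- function(alpha, w) {
  if (is.vector(alpha)) alpha <- matrix(alpha, nrow = 1L)
  if (ncol(alpha) != nrow(w)) {
    stop_input(sprintf("shape mismatch: %d activations vs %d rule weights",
                       ncol(alpha), nrow(w)))
  }
  alpha %*% w
}

#' Training configuration for the fuzzy deep classifier
#'
#' Defaults follow the usual training recipe for this architecture: Adam,
#' learning rate 0.001, cross-entropy loss, batch size 32, 100 epochs, and
#' a stratified 80/20 train/validation split.
#'
#' @param optimizer `"adam"` (default) or `"sgd"` (plain gradient
#'   descent, useful for convexity diagnostics).
#' @param learning_rate step size (default 0.001).
#' @param batch_size minibatch size (default 32).
#' @param epochs training epochs (default 100).
#' @param train_fraction fraction of samples in the training split
#'   (default 0.8).
#' @param hidden_dim width of the dense hidden layers (default 128).
#' @param seed integer seed (split, initialization, batch order).
#' @return A `train_config` object.
#' @export
train_config <- function(optimizer = c("adam", "sgd"), learning_rate = 0.001,
                         batch_size = 32, epochs = 100, train_fraction = 0.8,
                         hidden_dim = 128, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_config("`train_fraction` must be in (0, 1)")
  }
  structure(
    list(
      optimizer = optimizer,
      learning_rate = check_positive(learning_rate, "learning_rate"),
      batch_size = check_count(batch_size, "batch_size"),
      epochs = check_count(epochs, "epochs"),
      train_fraction = as.numeric(train_fraction),
      hidden_dim = check_count(hidden_dim, "hidden_dim", min = 0L),
      seed = check_count(seed, "seed", min = 0L)
    ),
    class = "train_config"
  )
}

#' Train the fuzzy deep classifier
#'
#' Fits the neuro-fuzzy network: a dense pathway over all input features
#' (dense - ReLU - dense - ReLU, standardized inputs) runs alongside a
#' fuzzification layer that converts the raw values of the designated
#' rule features into per-rule firing strengths ([fuzzify()]); the hidden
#' activations and the rule activations are concatenated into the
#' defuzzification/output layer ([defuzzify()] plus a bias) and passed
#' through [softmax()]. The rule-to-class weights are initialized from
#' the rule consequents (one-hot times rule degree) and then trained with
#' everything else by minibatch Adam under cross-entropy loss.
#'
#' The data are split into stratified train/validation subsets under the
#' configured seed; per-epoch loss and accuracy on both subsets are
#' recorded. Training aborts with a diagnostic if the loss turns
#' non-finite.
#'
#' @param table tibble of numeric feature columns plus a two-class
#'   `label` column; must contain every rule variable of `rule_base`.
#' @param rule_base a [wang_mendel()] rule base over a subset of the
#'   feature columns.
#' @param cfg a [train_config()].
#' @param architecture `"full"` (default) or `"linear"` — the latter drops
#'   the hidden pathway's nonlinearity (single linear map plus the rule
#'   activations), giving a convex training problem used in diagnostics.
#' @param split optional logical vector (`TRUE` = training row) fixing the
#'   train/validation partition externally — use this when the rule base
#'   was induced on the training rows only, so no validation information
#'   reaches the model. `NULL` (default) draws a stratified split from the
#'   config seed.
#' @return A `fuzzy_deep_model` with the trained weights, input schema,
#'   standardization constants, the rule base, and a `history` tibble
#'   (`epoch`, `train_loss`, `train_accuracy`, `val_loss`,
#'   `val_accuracy`).
#' @export
fit_fuzzy_deep <- function(table, rule_base, cfg = train_config(),
                           architecture = c("full", "linear"), split = NULL) {
  architecture <- match.arg(architecture)
  stopifnot(inherits(rule_base, "rule_base"), inherits(cfg, "train_config"))
  feats <- setdiff(names(table), "label")
  if (!"label" %in% names(table)) stop_input("table must have a `label` column")
  y <- as.integer(table$label)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop_input("training labels contain a single class")
  K <- length(classes)
  n <- nrow(table)

  if (!is.null(split) && (!is.logical(split) || length(split) != n)) {
    stop_input("`split` must be a logical vector with one entry per row")
  }
  local_rng(cfg$seed, {
    idx_train <- split %||% stratified_split(y, cfg$train_fraction)
    split <- list(train = which(idx_train), val = which(!idx_train))
    if (length(unique(y[split$train])) < 2L) {
      stop_input("training split contains a single class; increase sample size")
    }

    X <- as.matrix(table[, feats, drop = FALSE])
    center <- colMeans(X[split$train, , drop = FALSE])
    scl <- apply(X[split$train, , drop = FALSE], 2L, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    Xs <- sweep(sweep(X, 2L, center), 2L, scl, "/")
    A <- fuzzify(table, rule_base)
    Yhot <- matrix(0, n, K)
    Yhot[cbind(seq_len(n), match(y, classes))] <- 1

    d <- length(feats); h <- cfg$hidden_dim; M <- nrow(rule_base$rules)
    Wr0 <- matrix(0, M, K)
    Wr0[cbind(seq_len(M), match(rule_base$rules$consequent, classes))] <-
      rule_base$rules$degree
    params <- if (architecture == "full") {
      list(
        W1 = matrix(rnorm(d * h, 0, sqrt(2 / d)), d, h), b1 = numeric(h),
        W2 = matrix(rnorm(h * h, 0, sqrt(2 / h)), h, h), b2 = numeric(h),
        # zero-init output weights of the dense pathway: at epoch 0 the
        # consequent-initialized rule weights alone drive the predictions
        V = matrix(0, h, K),
        Wr = Wr0, b3 = numeric(K)
      )
    } else {
      list(V = matrix(0, d, K), Wr = Wr0, b3 = numeric(K))
    }

    opt <- adam_state(params)
    history <- vector("list", cfg$epochs)
    tr <- split$train
    for (epoch in seq_len(cfg$epochs)) {
      ord <- tr[sample.int(length(tr))]
      starts <- seq(1L, length(ord), by = cfg$batch_size)
      for (s in starts) {
        b <- ord[s:min(s + cfg$batch_size - 1L, length(ord))]
        g <- ffd_gradients(params, Xs[b, , drop = FALSE], A[b, , drop = FALSE],
                           Yhot[b, , drop = FALSE], architecture)
        opt <- apply_update(params, g, opt, cfg)
        params <- opt$params
      }
      m_tr <- ffd_evaluate(params, Xs[tr, , drop = FALSE], A[tr, , drop = FALSE],
                           Yhot[tr, , drop = FALSE], architecture)
      m_va <- ffd_evaluate(params, Xs[split$val, , drop = FALSE],
                           A[split$val, , drop = FALSE],
                           Yhot[split$val, , drop = FALSE], architecture)
      if (!is.finite(m_tr$loss)) {
        abort(sprintf("non-finite training loss at epoch %d; lower the learning rate or rescale the features",
                      epoch), class = "fuzzyhisto_numeric_error")
      }
      history[[epoch]] <- tibble(
        epoch = epoch,
        train_loss = m_tr$loss, train_accuracy = m_tr$accuracy,
        val_loss = m_va$loss, val_accuracy = m_va$accuracy
      )
    }

    structure(
      list(
        params = params, architecture = architecture,
        feature_names = feats, classes = classes,
        center = center, scale = scl,
        rule_base = rule_base, config = cfg,
        split = split,
        history = list_rbind(history)
      ),
      class = "fuzzy_deep_model"
    )
  })
}

# TRUE for training rows; stratified by class.
stratified_split <- function(y, train_fraction) {
  take <- logical(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_tr <- max(1L, round(train_fraction * length(idx)))
    n_tr <- min(n_tr, length(idx) - 1L)
    take[sample(idx, n_tr)] <- TRUE
  }
  take
}

ffd_forward <- function(params, Xs, A, architecture) {
  if (architecture == "full") {
    H1 <- relu(sweep(Xs %*% params$W1, 2L, params$b1, "+"))
    H2 <- relu(sweep(H1 %*% params$W2, 2L, params$b2, "+"))
    B <- sweep(H2 %*% params$V + defuzzify(A, params$Wr), 2L, params$b3, "+")
    list(H1 = H1, H2 = H2, scores = B, probs = softmax(B))
  } else {
    B <- sweep(Xs %*% params$V + defuzzify(A, params$Wr), 2L, params$b3, "+")
    list(scores = B, probs = softmax(B))
  }
}

ffd_gradients <- function(params, Xs, A, Yhot, architecture) {
  fw <- ffd_forward(params, Xs, A, architecture)
  nb <- nrow(Xs)
  dB <- (fw$probs - Yhot) / nb
  if (architecture == "full") {
    g <- list(
      V = crossprod(fw$H2, dB), Wr = crossprod(A, dB), b3 = colSums(dB)
    )
    dH2 <- (dB %*% t(params$V)) * (fw$H2 > 0)
    g$W2 <- crossprod(fw$H1, dH2); g$b2 <- colSums(dH2)
    dH1 <- (dH2 %*% t(params$W2)) * (fw$H1 > 0)
    g$W1 <- crossprod(Xs, dH1); g$b1 <- colSums(dH1)
    g[names(params)]
  } else {
    list(V = crossprod(Xs, dB), Wr = crossprod(A, dB), b3 = colSums(dB))
  }
}

ffd_evaluate <- function(params, Xs, A, Yhot, architecture) {
  fw <- ffd_forward(params, Xs, A, architecture)
  eps <- 1e-12
  list(
    loss = -mean(log(rowSums(fw$probs * Yhot) + eps)),
    accuracy = mean(max.col(fw$probs) == max.col(Yhot))
  )
}

adam_state <- function(params) {
  list(
    params = params,
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

# One optimizer step; Adam uses the conventional moment defaults
# (beta1 = 0.9, beta2 = 0.999, eps = 1e-8).
apply_update <- function(params, grads, opt, cfg) {
  if (cfg$optimizer == "sgd") {
    opt$params <- purrr::map2(params, grads, function(p, g) p - cfg$learning_rate * g)
    return(opt)
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  opt$t <- opt$t + 1L
  for (nm in names(params)) {
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * grads[[nm]]
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- opt$m[[nm]] / (1 - b1^opt$t)
    vhat <- opt$v[[nm]] / (1 - b2^opt$t)
    opt$params[[nm]] <- params[[nm]] - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
  }
  opt
}

#' @export
print.fuzzy_deep_model <- function(x, ...) {
  hf <- x$history[nrow(x$history), ]
  cat(sprintf("<fuzzy_deep_model> %d features, %d rules, %s architecture; %d epoch(s), final val accuracy %.3f\n",
              length(x$feature_names), nrow(x$rule_base$rules),
              x$architecture, nrow(x$history), hf$val_accuracy))
  invisible(x)
}

#' Predict with a fuzzy deep classifier
#'
#' @param object a `fuzzy_deep_model`.
#' @param newdata tibble containing at least the training feature columns
#'   (a `label` column, if present, is ignored).
#' @param ... unused.
#' @return A tibble with `.pred_class` plus one `.pred_<class>`
#'   probability column per class; probability rows sum to 1.
#' @export
predict.fuzzy_deep_model <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$feature_names, names(newdata))
  if (length(missing_cols)) {
    stop_input(paste("newdata lacks feature column(s):",
                     paste(head(missing_cols, 5), collapse = ", ")))
  }
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  Xs <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  A <- fuzzify(newdata, object$rule_base)
  fw <- ffd_forward(object$params, Xs, A, object$architecture)
  probs <- fw$probs
  out <- tibble(.pred_class = object$classes[max.col(probs)])
  for (k in seq_along(object$classes)) {
    out[[paste0(".pred_", object$classes[k])]] <- probs[, k]
  }
  out
}

#' Tidy the training history of a fuzzy deep model
#'
#' @param x a `fuzzy_deep_model`.
#' @param ... unused.
#' @return The per-epoch history tibble.
#' @method tidy fuzzy_deep_model
#' @export
tidy.fuzzy_deep_model <- function(x, ...) x$history

#' @rdname tidy.fuzzy_deep_model
#' @return `glance()`: one row with the final epoch's metrics and model
#'   dimensions.
#' @method glance fuzzy_deep_model
#' @export
glance.fuzzy_deep_model <- function(x, ...) {
  hf <- x$history[nrow(x$history), ]
  tibble(
    n_features = length(x$feature_names),
    n_rules = nrow(x$rule_base$rules),
    epochs = nrow(x$history),
    train_accuracy = hf$train_accuracy,
    val_accuracy = hf$val_accuracy,
    train_loss = hf$train_loss,
    val_loss = hf$val_loss
  )
}

#' Plot training curves of a fuzzy deep model
#'
#' @param object a `fuzzy_deep_model`.
#' @param ... unused.
#' @return A ggplot of loss and accuracy per epoch for the train and
#'   validation splits.
#' @method autoplot fuzzy_deep_model
#' @export
autoplot.fuzzy_deep_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = c("split", "metric"), names_sep = "_")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Fuzzy deep classifier training") +
    ggplot2::theme_minimal()
}
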