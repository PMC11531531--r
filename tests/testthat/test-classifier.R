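rule_setup <- function(tbl, top_k = 4, n_levels = 9, seed = 1) {
  ruletab <- prefilter_and_rank(tbl, top_k = top_k, seed = seed)
  wang_mendel(ruletab, build_partitions(ruletab, n_levels = n_levels))
}

# Leakage-free protocol: split first, induce rules on training rows only,
# then train with the same partition.
fit_clean <- function(tbl, cfg, top_k = 3, rule_seed = 1) {
  split <- withr::with_seed(cfg$seed,
    fuzzyhisto:::stratified_split(tbl$label, cfg$train_fraction))
  rb <- rule_setup(tbl[split, ], top_k = top_k, seed = rule_seed)
  fit_fuzzy_deep(tbl, rb, cfg, split = split)
}

test_that("relu and softmax behave per definition", {
  expect_equal(relu(c(-3, 0, 5)), c(0, 0, 5))
  expect_equal(relu(matrix(c(-1, 2, -0.5, 3), 2)), matrix(c(0, 2, 0, 3), 2))
  expect_equal(as.numeric(softmax(c(0, 0))), c(0.5, 0.5))
  expect_equal(as.numeric(softmax(c(1, 1, 1))), rep(1 / 3, 3))
  big <- softmax(c(1000, 0))
  expect_true(all(is.finite(big)))
  expect_equal(as.numeric(big), c(1, 0), tolerance = 1e-12)
  # shift invariance and row normalization
  z <- matrix(rnorm(12), 3)
  expect_equal(softmax(z), softmax(z + 7), tolerance = 1e-12)
  expect_equal(rowSums(softmax(z)), rep(1, 3), tolerance = 1e-12)
})

test_that("fuzzification matches the brute-force product oracle", {
  tbl <- sep_table(n_per_class = 30, n_features = 6, n_informative = 2)
  rb <- rule_setup(tbl)
  x <- tbl[1:7, ]
  alpha <- fuzzify(x, rb)
  expect_true(all(alpha >= 0 & alpha <= 1))
  expect_equal(alpha, oracle_fuzzify(x, rb), tolerance = 1e-12)
})

test_that("a sample at every antecedent apex fires its rule fully", {
  vars <- c("x1", "x2")
  grid <- tibble::tibble(x1 = c(0, 1), x2 = c(0, 1), label = 0L)
  parts <- build_partitions(grid, n_levels = 3)
  tbl <- tibble::tibble(x1 = 0.5, x2 = 1, label = 1L)
  rb <- wang_mendel(tbl, parts)
  # apex values of the antecedent levels of the single rule
  apex <- vapply(vars, function(v) {
    fuzzyhisto:::mf_center(parts[[v]]$mfs[[rb$rules[[v]][1] + 1L]])
  }, 0)
  alpha <- fuzzify(tibble::tibble(x1 = apex[1], x2 = apex[2]), rb)
  expect_equal(as.numeric(alpha), 1)
  # one zero factor annihilates the activation
  far <- tibble::tibble(x1 = 99, x2 = apex[2])
  expect_equal(as.numeric(fuzzify(far, rb)), 0)
})

test_that("defuzzification is the matrix product, checked by double loop", {
  withr::with_seed(3, {
    alpha <- matrix(runif(5 * 7), 5, 7)
    w <- matrix(rnorm(7 * 2), 7, 2)
  })
  beta <- defuzzify(alpha, w)
  expect_equal(beta, oracle_defuzzify(alpha, w), tolerance = 1e-12)
  # one-hot activation selects the rule's weight row
  hot <- rep(0, 7); hot[4] <- 1
  expect_equal(as.numeric(defuzzify(hot, w)), w[4, ])
  expect_equal(as.numeric(defuzzify(rep(0, 7), w)), c(0, 0))
  expect_error(defuzzify(alpha, w[1:3, ]), class = "fuzzyhisto_input_error")
})

test_that("training recovers separable data across seeds", {
  for (s in 1:5) {
    tbl <- sep_table(n_per_class = 100, n_features = 20, n_informative = 3,
                     separation = 6, seed = 500 + s)
    m <- fit_clean(tbl, train_config(epochs = 5, hidden_dim = 16, seed = s),
                   top_k = 3, rule_seed = s)
    expect_gte(glance(m)$val_accuracy, 0.95)
  }
})

test_that("label-shuffled data trains to chance-level validation accuracy", {
  tbl <- sep_table(n_per_class = 100, n_features = 20, n_informative = 3,
                   separation = 6, seed = 900)
  tbl$label <- withr::with_seed(1, sample(tbl$label))
  m <- fit_clean(tbl, train_config(epochs = 5, hidden_dim = 16, seed = 2))
  acc <- glance(m)$val_accuracy
  expect_gte(acc, 0.35)
  expect_lte(acc, 0.65)
})

test_that("training is deterministic under a fixed seed", {
  tbl <- sep_table(n_per_class = 40, n_features = 8, n_informative = 2)
  rb <- rule_setup(tbl, top_k = 3)
  cfg <- train_config(epochs = 3, hidden_dim = 8, seed = 31)
  m1 <- fit_fuzzy_deep(tbl, rb, cfg)
  m2 <- fit_fuzzy_deep(tbl, rb, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("full-batch gradient descent on the linear architecture descends", {
  tbl <- sep_table(n_per_class = 50, n_features = 6, n_informative = 2)
  rb <- rule_setup(tbl, top_k = 3)
  cfg <- train_config(optimizer = "sgd", learning_rate = 0.05,
                      batch_size = 1000, epochs = 40, seed = 7)
  m <- fit_fuzzy_deep(tbl, rb, cfg, architecture = "linear")
  # convex problem, full-batch small steps: loss non-increasing
  expect_true(all(diff(m$history$train_loss) <= 1e-8))
})

test_that("predictions normalize, memorize, and reject schema mismatches", {
  tbl <- sep_table(n_per_class = 50, n_features = 10, n_informative = 3)
  rb <- rule_setup(tbl, top_k = 3)
  m <- fit_fuzzy_deep(tbl, rb, train_config(epochs = 20, hidden_dim = 32,
                                            seed = 13))
  preds <- predict(m, tbl)
  expect_equal(preds$.pred_0 + preds$.pred_1, rep(1, nrow(tbl)),
               tolerance = 1e-6)
  # over-capacity model memorizes its training split
  tr <- m$split$train
  expect_gte(mean(preds$.pred_class[tr] == tbl$label[tr]), 0.95)
  expect_identical(predict(m, tbl), preds)
  expect_error(predict(m, tbl[, 1:3]), class = "fuzzyhisto_input_error")
})

test_that("degenerate training tables are rejected", {
  tbl <- sep_table(n_per_class = 20, n_features = 5, n_informative = 2)
  rb <- rule_setup(tbl, top_k = 2)
  one <- tbl; one$label <- 1L
  expect_error(fit_fuzzy_deep(one, rb, train_config(epochs = 1)),
               class = "fuzzyhisto_input_error")
})
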