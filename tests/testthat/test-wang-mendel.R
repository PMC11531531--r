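two_var_partitions <- function() {
  grid <- tibble::tibble(x1 = c(0, 1), x2 = c(0, 1), label = 0L)
  build_partitions(grid, n_levels = 3)
}

test_that("one training sample yields one rule with a product degree", {
  parts <- two_var_partitions()
  tbl <- tibble::tibble(x1 = 0.2, x2 = 0.9, label = 1L)
  rb <- wang_mendel(tbl, parts)
  expect_equal(nrow(rb$rules), 1L)
  expect_equal(rb$provenance[["primitive"]], 1L)
  # degree = product of the maximal memberships per variable
  mu1 <- max(fuzzyhisto:::partition_memberships(parts$x1, 0.2))
  mu2 <- max(fuzzyhisto:::partition_memberships(parts$x2, 0.9))
  expect_equal(rb$rules$degree, mu1 * mu2)
  expect_equal(rb$rules$consequent, 1L)
})

test_that("duplicate samples collapse to one rule", {
  parts <- two_var_partitions()
  tbl <- tibble::tibble(x1 = c(0.2, 0.2), x2 = c(0.9, 0.9), label = c(1L, 1L))
  rb <- wang_mendel(tbl, parts)
  expect_equal(nrow(rb$rules), 1L)
  expect_equal(rb$provenance[["primitive"]], 2L)
})

test_that("conflicting antecedents keep the higher-degree consequent", {
  parts <- two_var_partitions()
  # same antecedent cell (levels 0 and 2), different labels; the first
  # sample sits closer to the apexes so its degree wins (0.81 vs 0.49)
  tbl <- tibble::tibble(x1 = c(0.05, 0.15), x2 = c(0.95, 0.85),
                        label = c(1L, 0L))
  # oracle: brute-force the two primitive degrees
  deg <- vapply(1:2, function(i) {
    prod(max(fuzzyhisto:::partition_memberships(parts$x1, tbl$x1[i])),
         max(fuzzyhisto:::partition_memberships(parts$x2, tbl$x2[i])))
  }, 0)
  expect_gt(deg[1], deg[2])
  rb <- wang_mendel(tbl, parts)
  expect_equal(nrow(rb$rules), 1L)
  expect_equal(rb$rules$consequent, 1L)
  expect_equal(rb$rules$degree, deg[1])
  expect_equal(rb$provenance[["conflict_resolved"]], 1L)
})

test_that("rule bases have unique antecedents and primitive count = n", {
  tbl <- sep_table(n_per_class = 60, n_features = 6, n_informative = 2)
  parts <- build_partitions(tbl, n_levels = 9)
  rb <- wang_mendel(tbl, parts)
  vars <- setdiff(names(tbl), "label")
  ants <- do.call(paste, rb$rules[vars])
  expect_equal(anyDuplicated(ants), 0L)
  expect_equal(rb$provenance[["primitive"]], nrow(tbl))
  expect_gte(rb$provenance[["primitive"]], rb$provenance[["final"]])
  expect_true(all(rb$rules$degree > 0 & rb$rules$degree <= 1))
  expect_true(all(as.matrix(rb$rules[vars]) %in% 0:8))
})

test_that("rule induction is invariant to sample order", {
  tbl <- sep_table(n_per_class = 40, n_features = 5, n_informative = 2)
  parts <- build_partitions(tbl, n_levels = 7)
  rb1 <- wang_mendel(tbl, parts)
  shuf <- withr::with_seed(4, tbl[sample.int(nrow(tbl)), ])
  rb2 <- wang_mendel(shuf, parts)
  vars <- setdiff(names(tbl), "label")
  expect_equal(dplyr::arrange(rb1$rules, dplyr::across(dplyr::all_of(vars))),
               dplyr::arrange(rb2$rules, dplyr::across(dplyr::all_of(vars))))
})

test_that("zero-heavy columns are dropped and correlation ranks the rest", {
  withr::with_seed(6, {
    n <- 100
    tbl <- tibble::tibble(
      dense = rnorm(n),
      sparse = ifelse(runif(n) < 0.3, 0, rnorm(n)),  # ~30% zeros
      label = rep(c(0L, 1L), each = n / 2)
    )
    tbl$proxy <- as.numeric(tbl$label) + 1  # shifted label copy: |r| = 1, no zeros
  })
  out <- prefilter_and_rank(tbl, zero_frac_threshold = 0.10, top_k = 2,
                            seed = 1)
  expect_false("sparse" %in% names(out))
  expect_identical(names(out)[1], "proxy")
  expect_equal(nrow(out), nrow(tbl))
})

test_that("top-k correlation ranking recovers planted informative dims", {
  tbl <- make_feature_table(fixture_spec(
    n_per_class = 150, n_features = 40, n_informative = 8,
    class_separation = 3, seed = 77
  ))
  out <- prefilter_and_rank(tbl, top_k = 8, seed = 2)
  expect_setequal(setdiff(names(out), "label"), informative_features(tbl))
})

test_that("prefilter error paths fire", {
  tbl <- tibble::tibble(a = c(0, 0, 0, 1), label = c(0L, 1L, 0L, 1L))
  expect_error(prefilter_and_rank(tbl, zero_frac_threshold = 0.10, top_k = 1),
               class = "fuzzyhisto_input_error")
  tbl2 <- tibble::tibble(a = rnorm(4), label = c(0L, 1L, 0L, 1L))
  expect_error(prefilter_and_rank(tbl2, top_k = 3),
               class = "fuzzyhisto_input_error")
})

test_that("rule bases round-trip through JSON", {
  tbl <- sep_table(n_per_class = 30, n_features = 4, n_informative = 2)
  rb <- wang_mendel(tbl, build_partitions(tbl, n_levels = 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_rule_base(rb, path)
  back <- read_rule_base(path)
  expect_equal(back$rules, rb$rules, tolerance = 1e-12)
  expect_equal(unname(back$provenance), unname(rb$provenance))
  # memberships of the reloaded partitions agree everywhere
  xs <- seq(min(tbl$f0001), max(tbl$f0001), length.out = 50)
  v <- names(rb$partitions)[1]
  expect_equal(fuzzyhisto:::partition_memberships(back$partitions[[v]], xs),
               fuzzyhisto:::partition_memberships(rb$partitions[[v]], xs),
               tolerance = 1e-12)
})
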