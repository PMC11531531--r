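# Shared tiny fixtures and independent oracle helpers.

tiny_images <- function(n_per_class = 2, seed = 11) {
  make_images(fixture_spec(n_per_class = n_per_class, image_size = 32,
                           seed = seed))
}

sep_table <- function(n_per_class = 100, n_features = 20, n_informative = 3,
                      separation = 6, seed = 42) {
  make_feature_table(fixture_spec(
    n_per_class = n_per_class, n_features = n_features,
    n_informative = n_informative, class_separation = separation,
    noise_sd = 1, seed = seed
  ))
}

# Independent oracle: brute-force per-rule activation, one loop per factor.
oracle_fuzzify <- function(x, rule_base) {
  vars <- names(rule_base$partitions)
  out <- matrix(NA_real_, nrow(x), nrow(rule_base$rules))
  for (s in seq_len(nrow(x))) {
    for (i in seq_len(nrow(rule_base$rules))) {
      a <- 1
      for (v in vars) {
        lev <- rule_base$rules[[v]][i] + 1L
        a <- a * eval_mf(rule_base$partitions[[v]]$mfs[[lev]], x[[v]][s])
      }
      out[s, i] <- a
    }
  }
  out
}

# Independent oracle: naive double-loop weighted-sum defuzzification.
oracle_defuzzify <- function(alpha, w) {
  out <- matrix(0, nrow(alpha), ncol(w))
  for (s in seq_len(nrow(alpha))) {
    for (k in seq_len(ncol(w))) {
      out[s, k] <- sum(alpha[s, ] * w[, k])
    }
  }
  out
}
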