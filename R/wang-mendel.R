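#' Wang-Mendel rule induction
#'
#' Generates one primitive fuzzy rule per training sample: the antecedent
#' takes, for each rule variable, the partition level where the sample's
#' value has maximal membership (ties to the lower level index); the rule
#' degree is the product of those maximal memberships; the consequent is
#' the sample's class label. Duplicate rules (same antecedent and
#' consequent) are collapsed keeping the maximum degree, and conflicting
#' rules (same antecedent, different consequent) are resolved by keeping
#' the higher-degree rule. Provenance counts of each stage are recorded.
#'
#' @param table tibble with the rule-variable columns plus `label`.
#' @param partitions named list of [fuzzy_partition()]s covering every
#'   rule-variable column (e.g. from [build_partitions()]).
#' @return A `rule_base`: list with `rules` (tibble with one level-index
#'   column per variable, plus `consequent` and `degree`), `partitions`,
#'   and `provenance` (counts: `primitive`, `deduplicated`,
#'   `conflict_resolved`, `final`).
#' @export
#' @examples
#' tbl <- tibble::tibble(x1 = c(0.1, 0.9), x2 = c(0.8, 0.2), label = c(0L, 1L))
#' rb <- wang_mendel(tbl, build_partitions(tbl, n_levels = 3))
#' tidy(rb)
wang_mendel <- function(table, partitions) {
  vars <- names(partitions)
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols)) {
    stop_input(paste("table lacks rule-variable column(s):",
                     paste(missing_cols, collapse = ", ")))
  }
  if (!"label" %in% names(table)) stop_input("table must have a `label` column")
  n <- nrow(table)
  if (n == 0L) stop_input("empty training table")

  # per variable: maximal-membership level (0-based) and its membership
  lev <- matrix(0L, n, length(vars), dimnames = list(NULL, vars))
  mu <- matrix(0, n, length(vars))
  for (j in seq_along(vars)) {
    mm <- partition_memberships(partitions[[vars[j]]], table[[vars[j]]])
    if (any(mm[cbind(seq_len(n), max.col(mm, ties.method = "first"))] <= 0)) {
      stop("sample outside all partition supports; coverage invariant violated")
    }
    lev[, j] <- max.col(mm, ties.method = "first") - 1L
    mu[, j] <- mm[cbind(seq_len(n), lev[, j] + 1L)]
  }
  primitive <- as_tibble(lev)
  primitive$consequent <- as.integer(table$label)
  primitive$degree <- apply(mu, 1L, prod)

  # dedup: same antecedent + consequent, keep max degree
  dedup <- primitive |>
    group_by(across(all_of(c(vars, "consequent")))) |>
    summarise(degree = max(.data$degree), .groups = "drop")
  # conflicts: same antecedent, different consequent -> max degree wins,
  # ties broken toward the lower class id for determinism
  final <- dedup |>
    group_by(across(all_of(vars))) |>
    arrange(desc(.data$degree), .data$consequent, .by_group = TRUE) |>
    slice_head(n = 1L) |>
    ungroup() |>
    arrange(across(all_of(vars)))

  structure(
    list(
      rules = final,
      partitions = partitions,
      provenance = c(
        primitive = n,
        deduplicated = nrow(dedup),
        conflict_resolved = nrow(dedup) - nrow(final),
        final = nrow(final)
      )
    ),
    class = "rule_base"
  )
}

#' @export
print.rule_base <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<rule_base> %d rule(s) over %d variable(s) (%d primitive, %d after dedup, %d conflicts resolved)\n",
              p[["final"]], length(x$partitions), p[["primitive"]],
              p[["deduplicated"]], p[["conflict_resolved"]]))
  invisible(x)
}

#' Tidy a rule base
#'
#' @param x a `rule_base`.
#' @param ... unused.
#' @return The rules tibble: one level-index column per variable plus
#'   `consequent` and `degree`.
#' @method tidy rule_base
#' @export
tidy.rule_base <- function(x, ...) x$rules

#' @rdname tidy.rule_base
#' @return `glance()`: one row of provenance counts.
#' @method glance rule_base
#' @export
glance.rule_base <- function(x, ...) {
  as_tibble(as.list(x$provenance))
}

#' Zero-fraction prefilter and correlation ranking of features
#'
#' The rule-variable selection step ahead of rule induction: drops feature
#' columns whose fraction of exact zeros exceeds `zero_frac_threshold`,
#' ranks the survivors by absolute Pearson correlation with the 0/1 label
#' (point-biserial), keeps the `top_k` strongest, and returns them
#' concatenated with the label, rows shuffled under the given seed.
#'
#' @param table tibble of numeric feature columns plus `label`.
#' @param zero_frac_threshold drop columns with a zero fraction strictly
#'   above this (default 0.10).
#' @param top_k number of top-correlated columns to keep (default 8).
#' @param seed integer seed for the row shuffle.
#' @return A tibble with `top_k` feature columns (correlation-ranked,
#'   strongest first) plus `label`.
#' @export
prefilter_and_rank <- function(table, zero_frac_threshold = 0.10, top_k = 8,
                               seed = 1L) {
  if (zero_frac_threshold <= 0 || zero_frac_threshold >= 1) {
    stop_config("`zero_frac_threshold` must be in (0, 1)")
  }
  top_k <- check_count(top_k, "top_k")
  feats <- setdiff(names(table), "label")
  y <- as.numeric(table$label)
  zero_frac <- vapply(feats, function(cn) mean(table[[cn]] == 0), 0)
  keep <- feats[zero_frac <= zero_frac_threshold]
  if (!length(keep)) stop_input("no feature column survives the zero-fraction filter")
  if (top_k > length(keep)) {
    stop_input(sprintf("`top_k` (%d) exceeds the %d surviving column(s)",
                       top_k, length(keep)))
  }
  r <- vapply(keep, function(cn) {
    v <- table[[cn]]
    if (sd(v) == 0) return(0)
    abs(cor(v, y))
  }, 0)
  ranked <- keep[order(-r, match(keep, feats))][seq_len(top_k)]
  out <- table[, c(ranked, "label")]
  local_rng(seed, out[sample.int(nrow(out)), ])
}

#' Serialize / load a rule base as JSON
#'
#' Partitions are written as (kind, params) per level, rules as antecedent
#' level-index lists with consequent and degree, plus the provenance
#' counts.
#'
#' @param rule_base a `rule_base`.
#' @param path JSON file path.
#' @return `write_rule_base()` returns `path` invisibly;
#'   `read_rule_base()` returns the `rule_base`.
#' @export
write_rule_base <- function(rule_base, path) {
  stopifnot(inherits(rule_base, "rule_base"))
  vars <- names(rule_base$partitions)
  obj <- list(
    variables = vars,
    partitions = lapply(rule_base$partitions, function(p) {
      list(variable_id = p$variable_id, domain = p$domain,
           levels = lapply(p$mfs, function(mf) list(kind = mf$kind, params = mf$params)))
    }),
    rules = lapply(seq_len(nrow(rule_base$rules)), function(i) {
      row <- rule_base$rules[i, ]
      list(antecedent = as.integer(unlist(row[vars])),
           consequent = row$consequent, degree = row$degree)
    }),
    provenance = as.list(rule_base$provenance)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rule_base
#' @export
read_rule_base <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  vars <- unlist(obj$variables)
  partitions <- lapply(obj$partitions, function(p) {
    mfs <- lapply(p$levels, function(lv) {
      pa <- lapply(lv$params, function(v) unlist(v))
      switch(lv$kind,
        triangular = mf_triangular(pa$a, pa$b, pa$c),
        trapezoidal = mf_trapezoidal(pa$a, pa$b, pa$c, pa$d),
        gaussian = mf_gaussian(pa$center, pa$sigma),
        bell = mf_bell(pa$center, pa$a, pa$b),
        piecewise_linear = mf_piecewise_linear(pa$x, pa$y)
      )
    })
    fuzzy_partition(p$variable_id, mfs, unlist(p$domain))
  })
  names(partitions) <- vars
  ants <- matrix(unlist(lapply(obj$rules, function(r) as.integer(unlist(r$antecedent)))),
                 ncol = length(vars), byrow = TRUE)
  rules <- as_tibble(ants, .name_repair = ~vars)
  rules$consequent <- vapply(obj$rules, function(r) as.integer(r$consequent), 0L)
  rules$degree <- vapply(obj$rules, function(r) as.numeric(r$degree), 0)
  structure(
    list(rules = rules, partitions = partitions,
         provenance = unlist(obj$provenance)),
    class = "rule_base"
  )
}
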