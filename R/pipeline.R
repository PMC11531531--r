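#' Pipeline configuration
#'
#' One serializable object describing a full run: synthetic-fixture
#' parameters, stage toggles, and the per-stage settings. Every stage
#' seed is derived from the single `seed`, so a config fully determines a
#' run.
#'
#' @param seed global integer seed.
#' @param route `"features"` (synthetic feature table straight into
#'   selection) or `"images"` (synthetic images through augmentation and
#'   stub feature extraction first).
#' @param fixtures named list of [fixture_spec()] arguments (without
#'   `seed`).
#' @param do_augment whether the image route runs augmentation.
#' @param augmentation named list of [augmentation_config()] arguments.
#' @param extractor named list of [feature_extractor_config()] arguments.
#' @param rfe named list: `target_n_features`, `n_folds`, `step`.
#' @param rules named list: `n_levels`, `mf_kind`, `placement`,
#'   `zero_frac_threshold`, `top_k`.
#' @param train named list of [train_config()] arguments (without
#'   `seed`).
#' @param shuffle_labels permute the labels before modelling (negative
#'   control runs).
#' @param out_dir optional directory; when given, every stage artifact
#'   plus a manifest is written there.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(seed = 1L,
                            route = c("features", "images"),
                            fixtures = list(),
                            do_augment = TRUE,
                            augmentation = list(),
                            extractor = list(),
                            rfe = list(),
                            rules = list(),
                            train = list(),
                            shuffle_labels = FALSE,
                            out_dir = NULL) {
  route <- match.arg(route)
  fixtures <- modifyList(list(n_per_class = 150, image_size = 48,
                              n_features = 60, n_informative = 8,
                              class_separation = 6, noise_sd = 1), fixtures)
  augmentation <- modifyList(list(scale_factor = 1.2, rotation_range_deg = 50,
                                  n_rotations = 3, include_original = TRUE),
                             augmentation)
  extractor <- modifyList(list(input_size = 48, backbone = "stub",
                               stub_width = 48), extractor)
  rfe <- modifyList(list(target_n_features = 20, n_folds = 5, step = 0.1),
                    rfe)
  rules <- modifyList(list(n_levels = 9, mf_kind = "triangular",
                           placement = "uniform", zero_frac_threshold = 0.10,
                           top_k = 8), rules)
  train <- modifyList(list(optimizer = "adam", learning_rate = 0.001,
                           batch_size = 32, epochs = 40, train_fraction = 0.8,
                           hidden_dim = 32), train)
  # canonical scalar types so configs compare equal after a YAML round-trip
  canon <- function(lst) {
    lapply(lst, function(x) {
      if (is.numeric(x) && length(x) == 1L && is.finite(x) &&
          x == floor(x) && abs(x) < .Machine$integer.max) as.integer(x) else x
    })
  }
  fixtures <- canon(fixtures); augmentation <- canon(augmentation)
  extractor <- canon(extractor); rfe <- canon(rfe)
  rules <- canon(rules); train <- canon(train)
  structure(
    list(seed = check_count(seed, "seed", min = 0L), route = route,
         fixtures = fixtures, do_augment = isTRUE(do_augment),
         augmentation = augmentation, extractor = extractor, rfe = rfe,
         rules = rules, train = train,
         shuffle_labels = isTRUE(shuffle_labels), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Serialize / load a pipeline configuration as YAML
#'
#' Configurations round-trip unchanged: `read_pipeline_config()` re-runs
#' the [pipeline_config()] constructor on the parsed fields.
#'
#' @param cfg a `pipeline_config`.
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns the `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full pipeline on synthetic fixtures
#'
#' Executes the stages in order — fixture generation, (image route only)
#' augmentation and stub feature extraction, recursive feature
#' elimination, zero-fraction prefilter + correlation ranking, fuzzy
#' partitioning and Wang-Mendel rule induction, classifier training, and
#' metric evaluation on the validation split. When `cfg$out_dir` is set,
#' each artifact is written there together with a manifest recording the
#' config, its hash, and the derived stage seeds.
#'
#' @param cfg a [pipeline_config()].
#' @return A `pipeline_run`: list with the `config`, the fitted
#'   `rfe` result, `rule_base`, `model`, validation `confusion` and
#'   `metrics`, and (if written) the artifact `paths`.
#' @export
#' @examples
#' \donttest{
#' run <- run_pipeline(pipeline_config(seed = 7,
#'   fixtures = list(n_per_class = 60, n_features = 30, n_informative = 5),
#'   rfe = list(target_n_features = 10), train = list(epochs = 10)))
#' run$metrics
#' }
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  seeds <- derive_seeds(cfg$seed)

  fspec <- do.call(fixture_spec, c(cfg$fixtures, list(seed = seeds["fixtures"])))
  table <- if (cfg$route == "images") {
    imgs <- make_images(fspec)
    if (cfg$do_augment) {
      imgs <- augment(imgs, do.call(augmentation_config,
                                    c(cfg$augmentation, list(seed = seeds["augment"]))))
    }
    ecfg <- do.call(feature_extractor_config, cfg$extractor)
    extract_features(preprocess_images(imgs, ecfg), ecfg)
  } else {
    make_feature_table(fspec)
  }
  if (cfg$shuffle_labels) {
    table$label <- local_rng(seeds["shuffle"], sample(table$label))
  }

  sel <- rfe(table,
             target_n_features = min(cfg$rfe$target_n_features,
                                     ncol(table) - 1L),
             n_folds = cfg$rfe$n_folds, step = cfg$rfe$step,
             seed = seeds["rfe"])

  # train/validation partition is drawn first so rule induction sees only
  # training rows; the same partition is handed to the classifier
  tcfg <- do.call(train_config, c(cfg$train, list(seed = seeds["train"])))
  split <- local_rng(seeds["train"],
                     stratified_split(sel$reduced$label, tcfg$train_fraction))
  ruletab <- prefilter_and_rank(sel$reduced[split, ],
                                zero_frac_threshold = cfg$rules$zero_frac_threshold,
                                top_k = min(cfg$rules$top_k,
                                            length(sel$retained)),
                                seed = seeds["rules"])
  partitions <- build_partitions(ruletab, n_levels = cfg$rules$n_levels,
                                 mf_kind = cfg$rules$mf_kind,
                                 placement = cfg$rules$placement,
                                 seed = seeds["rules"])
  rb <- wang_mendel(ruletab, partitions)

  model <- fit_fuzzy_deep(sel$reduced, rb, tcfg, split = split)

  val <- sel$reduced[model$split$val, , drop = FALSE]
  preds <- predict(model, val)
  cm <- confusion(val$label, preds$.pred_class)
  metrics <- classification_metrics(cm)

  run <- structure(
    list(config = cfg, rfe = sel, rule_base = rb, model = model,
         confusion = cm, metrics = metrics, paths = NULL),
    class = "pipeline_run"
  )
  if (!is.null(cfg$out_dir)) run$paths <- write_run_artifacts(run, cfg$out_dir)
  run
}

derive_seeds <- function(seed) {
  c(fixtures = seed + 101L, augment = seed + 211L, shuffle = seed + 307L,
    rfe = seed + 401L, rules = seed + 503L, train = seed + 601L) %% .Machine$integer.max
}

write_run_artifacts <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    features = file.path(dir, "selected_features.csv"),
    ranking = file.path(dir, "ranking.csv"),
    rules = file.path(dir, "rules.json"),
    history = file.path(dir, "history.csv"),
    report = file.path(dir, "report.json"),
    manifest = file.path(dir, "manifest.json")
  )
  write_feature_csv(run$rfe$reduced, paths$features)
  readr::write_csv(tidy(run$rfe), paths$ranking)
  write_rule_base(run$rule_base, paths$rules)
  readr::write_csv(run$model$history, paths$history)
  jsonlite::write_json(
    list(confusion = run$confusion[c("tp", "tn", "fp", "fn", "n")],
         metrics = as_tibble(run$metrics),
         final = as.list(glance(run$model))),
    paths$report, auto_unbox = TRUE, digits = NA
  )
  cfg_plain <- unclass(run$config)
  jsonlite::write_json(
    list(config = cfg_plain, config_hash = rlang::hash(cfg_plain),
         seeds = as.list(derive_seeds(run$config$seed))),
    paths$manifest, auto_unbox = TRUE, digits = NA
  )
  paths
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  print(glance(x$model))
  invisible(x)
}

#' Compare membership-function kinds under a shared seed and split
#'
#' Re-runs rule induction and classifier training once per membership
#' kind with everything else held fixed, so differences are attributable
#' to the membership shape alone. Rule-generation wall time is reported
#' but is hardware-dependent; the errors are data-dependent, not
#' contractual.
#'
#' @param cfg a [pipeline_config()].
#' @param kinds character vector of at least two membership kinds.
#' @return A tibble with one row per kind: `membership_function`,
#'   `rule_time_s`, `train_error`, `test_error`.
#' @export
compare_membership_functions <- function(cfg = pipeline_config(),
                                         kinds = c("trapezoidal",
                                                   "piecewise_linear",
                                                   "triangular")) {
  if (length(kinds) < 2L) stop_config("need at least two membership kinds")
  known <- c("triangular", "trapezoidal", "piecewise_linear", "gaussian", "bell")
  bad <- setdiff(kinds, known)
  if (length(bad)) {
    stop_config(paste("unknown membership kind(s):", paste(bad, collapse = ", ")))
  }
  rows <- map(kinds, function(kind) {
    k_cfg <- cfg
    k_cfg$rules$mf_kind <- kind
    k_cfg$out_dir <- NULL
    t0 <- proc.time()["elapsed"]
    run <- run_pipeline(k_cfg)
    g <- glance(run$model)
    tibble(
      membership_function = kind,
      rule_time_s = unname(proc.time()["elapsed"] - t0),
      train_error = 1 - g$train_accuracy,
      test_error = 1 - g$val_accuracy
    )
  })
  list_rbind(rows)
}
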