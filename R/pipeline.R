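#' Pipeline configuration
#'
#' Settings of the end-to-end tabular pipeline: synthetic generation (or a
#' CSV source), preprocessing, information-gain feature selection, the
#' PCSO-trained classifier and evaluation. Defaults are desk-scale: a
#' moderate optimizer budget that trains in seconds on a single CPU.
#'
#' @param n Samples to generate when no CSV is given.
#' @param imbalance_ratio Class-1 prevalence of the generator.
#' @param informative_names,effect_sizes Planted signal of the generator.
#' @param data_csv Optional path to a CSV with a MACCE label column; when
#'   given, the generator is skipped.
#' @param split_fraction Train fraction of the 80:20-style split.
#' @param use_smote Balance the training split with SMOTE.
#' @param smote_k,smote_target_ratio SMOTE parameters.
#' @param class_weight Positive-class loss weight (the alternative
#'   imbalance handle; independent of `use_smote`).
#' @param use_igfs Apply information-gain feature selection.
#' @param igfs_bins,igfs_rule,igfs_k Selection parameters (see
#'   [select_features()]).
#' @param hidden Classifier hidden sizes.
#' @param pop_size,max_iters,weight_bound PCSO budget and weight box.
#' @param refine_epochs Optional Adam refinement epochs (0 = off).
#' @param seed Integer master seed for every stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n = 1000L, imbalance_ratio = 0.3,
                            informative_names = c("LVEF", "Age", "TC"),
                            effect_sizes = c(-1.5, 1.0, 0.8),
                            data_csv = NULL, split_fraction = 0.8,
                            use_smote = FALSE, smote_k = 5L,
                            smote_target_ratio = 1.0, class_weight = 1,
                            use_igfs = TRUE, igfs_bins = 10L,
                            igfs_rule = "mean_ig", igfs_k = 5L,
                            hidden = c(128L, 64L, 32L), pop_size = 20L,
                            max_iters = 60L, weight_bound = 3,
                            refine_epochs = 0L, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

kfold_assign <- function(y, k, seed) {
  if (any(table(y) < k)) stop("every class needs at least k members")
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  start <- 0L
  # rotate the fold sequence between classes so overall sizes stay within 1
  for (cl in sort(unique(y))) {
    idx <- sample(which(y == cl))
    fold[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
    start <- start + length(idx)
  }
  fold
}

# Fit the preprocess -> IGFS -> PCSO-classifier pipeline on a training set
# and return the fitted transforms and model.
fit_pipeline_stage <- function(X, y, config, seed) {
  zs <- zscore_normalize(X)
  Xtr <- zs$matrix
  if (config$use_smote) {
    sm <- smote_oversample(Xtr, y, k = config$smote_k,
                           target_ratio = config$smote_target_ratio,
                           seed = seed)
    Xtr <- sm$X; y <- sm$y
  }
  keep <- colnames(X)
  score_table <- NULL
  if (config$use_igfs) {
    score_table <- select_features(Xtr, y, bins = config$igfs_bins,
                                   threshold_rule = config$igfs_rule,
                                   k = config$igfs_k)
    sel <- score_table$name[score_table$selected]
    if (length(sel) >= 2L) keep <- sel  # never feed fewer than 2 features
  }
  spec <- network_spec(length(keep), hidden = config$hidden,
                       class_weight = config$class_weight)
  model <- train_with_pcso(spec, Xtr[, keep, drop = FALSE], y,
                           pop_size = config$pop_size,
                           max_iters = config$max_iters,
                           weight_bound = config$weight_bound,
                           seed = seed,
                           refine_epochs = config$refine_epochs)
  list(zscore = zs, keep = keep, score_table = score_table, model = model)
}

predict_pipeline_stage <- function(fit, X) {
  Xz <- zscore_apply(fit$zscore, X)
  predict(fit$model, Xz[, fit$keep, drop = FALSE])
}

#' Stratified k-fold cross-validated evaluation
#'
#' Assigns stratified folds (each sample validated exactly once, fold sizes
#' within one), fits the full preprocess -> IGFS -> PCSO-classifier pipeline
#' on the training folds only (no leakage: z-score statistics, SMOTE and
#' feature selection are re-fitted per fold) and evaluates on the held-out
#' fold.
#'
#' @param X Feature matrix with column names.
#' @param y Binary 0/1 labels.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @param config A [pipeline_config()].
#' @return A `cv_report`: `folds` (per-fold metric data.frame), `mean` and
#'   `sd` of each metric, and the fold assignment vector.
#' @export
kfold_evaluate <- function(X, y, k = 5L, seed = 1L,
                           config = pipeline_config()) {
  stopifnot(k >= 2L)
  fold <- kfold_assign(y, k, seed)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold != f); va <- which(fold == f)
    fit <- fit_pipeline_stage(X[tr, , drop = FALSE], y[tr], config,
                              seed = seed + f)
    p <- predict_pipeline_stage(fit, X[va, , drop = FALSE])
    m <- metric_report(y[va], p)
    rows[[f]] <- data.frame(fold = f, n_val = length(va),
                            accuracy = m$accuracy, precision = m$precision,
                            recall = m$recall, f1 = m$f1, auc = m$auc)
  }
  folds <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "precision", "recall", "f1", "auc")
  structure(list(folds = folds,
                 mean = colMeans(folds[metric_cols]),
                 sd = vapply(folds[metric_cols], stats::sd, numeric(1)),
                 assignment = fold, k = k, seed = as.integer(seed)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV: accuracy %.3f +/- %.3f, auc %.3f +/- %.3f\n",
              x$k, x$mean["accuracy"], x$sd["accuracy"],
              x$mean["auc"], x$sd["auc"]))
  invisible(x)
}

#' Run the full tabular pipeline
#'
#' Generates (or loads) the data, imputes missing values, splits 80:20 with
#' stratification, fits z-scoring, optional SMOTE, information-gain feature
#' selection and the PCSO-trained classifier on the training part only, then
#' reports confusion-matrix metrics, ROC/AUC and the explanation layer on
#' the held-out part. A reproducibility manifest (config echo plus R and
#' package versions) is attached; re-running from the manifest reproduces
#' the report exactly.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log per-stage shapes and class counts (default `FALSE`).
#' @return A `pipeline_result`: `report` (a `metric_report`), `explanation`,
#'   `score_table`, `model`, `split`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(config$data_csv)) {
    ds <- read_tabular_csv(config$data_csv)
    say("stage load: %d x %d from %s", nrow(ds$X), ncol(ds$X),
        config$data_csv)
  } else {
    ds <- gen_tabular(n = config$n, seed = config$seed,
                      imbalance_ratio = config$imbalance_ratio,
                      informative_names = config$informative_names,
                      effect_sizes = config$effect_sizes)
    say("stage simulate: %d x %d, prevalence %.3f", nrow(ds$X), ncol(ds$X),
        mean(ds$y))
  }
  X <- ds$X; y <- ds$y
  if (anyNA(X)) {
    X <- impute_missing(X, ds$schema)
    say("stage impute: filled %d missing entries", sum(is.na(ds$X)))
  }
  split <- stratified_split(y, fraction = config$split_fraction,
                            seed = config$seed)
  say("stage split: %d train / %d test", length(split$train),
      length(split$test))
  fit <- fit_pipeline_stage(X[split$train, , drop = FALSE], y[split$train],
                            config, seed = config$seed)
  say("stage train: %d features kept, final fitness %.4f",
      length(fit$keep), fit$model$result$best_fitness)
  p <- predict_pipeline_stage(fit, X[split$test, , drop = FALSE])
  report <- metric_report(y[split$test], p)
  Xz_test <- zscore_apply(fit$zscore, X[split$test, , drop = FALSE])
  expl <- explain(fit$model, Xz_test[, fit$keep, drop = FALSE],
                  y[split$test], n_repeats = 5L, seed = config$seed)
  say("stage evaluate: accuracy %.3f, auc %.3f", report$accuracy,
      report$auc)
  manifest <- list(config = unclass(config),
                   r_version = as.character(getRversion()),
                   package_version =
                     as.character(utils::packageVersion("cardiopcso")))
  structure(list(report = report, explanation = expl,
                 score_table = fit$score_table, model = fit$model,
                 split = split, manifest = manifest),
            class = "pipeline_result")
}

#' Re-run a pipeline from a saved manifest
#'
#' @param manifest The `manifest` element of a `pipeline_result` (or a path
#'   to its JSON serialization).
#' @param verbose Passed to [run_pipeline()].
#' @return A new `pipeline_result` computed from the manifest's config.
#' @export
run_from_manifest <- function(manifest, verbose = FALSE) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest,
                                                              simplifyVector = TRUE)
  cfg <- manifest$config
  cfg$hidden <- as.integer(cfg$hidden)
  if (length(cfg$data_csv) == 0) cfg$data_csv <- NULL
  config <- do.call(pipeline_config, cfg)
  run_pipeline(config, verbose = verbose)
}

#' Write a pipeline manifest to JSON
#'
#' @param result A `pipeline_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(result, path) {
  jsonlite::write_json(result$manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
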