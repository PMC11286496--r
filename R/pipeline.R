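#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: cohort simulation,
#' marker extraction, classifier tuning and the experiment seeds.
#'
#' @param cohort a [cohort_config()].
#' @param r2_min fit-quality retention threshold.
#' @param short_window,long_window exponent-regression windows, s.
#' @param grid hyperparameter grid for tuning.
#' @param seeds integer vector of experiment seeds (splits, folds, noise).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), r2_min = 0.9,
                            short_window = NULL, long_window = c(3, 10),
                            grid = default_grid(), seeds = 1:5) {
  stopifnot(inherits(cohort, "cohort_config"))
  if (length(seeds) < 1) stop("at least one experiment seed is required")
  structure(list(cohort = cohort, r2_min = r2_min,
                 short_window = short_window, long_window = long_window,
                 grid = grid, seeds = as.integer(seeds)),
            class = "pipeline_config")
}

# one classification task: stratified split, CV-tuned hyperparameters,
# final fit, held-out evaluation
tuned_task <- function(table, features, seed, grid = default_grid(),
                       train_frac = 0.7) {
  sp <- split_train_test(table, train_frac, seed)
  cv <- cross_validate(sp$train, features, k = 10, grid = grid, seed = seed)
  clf <- train_classifier(sp$train, features, C = cv$best_C,
                          sigma = cv$best_sigma)
  ev <- evaluate_classifier(clf, sp$test)
  list(accuracy = ev$accuracy, auc = ev$auc, C = cv$best_C,
       sigma = cv$best_sigma, classifier = clf, metrics = ev, split = sp)
}

#' Headline classification experiments on one simulated cohort
#'
#' Simulates the default three-group cohort for one seed, extracts the nine
#' markers, and runs the standard battery of CV-tuned classification tasks:
#' healthy-vs-diseased (all markers, `Esum` only, `fT` only),
#' healthy-vs-treated, treated-vs-diseased, and the three-state task (all
#' markers, top-5 RFE-ranked markers, `Esum` only, `alphaR` only).
#'
#' @param seed cohort and experiment seed.
#' @param config a [pipeline_config()]; its cohort seed is replaced by
#'   `seed`.
#' @return List with `accuracies` (named numeric vector), `feature_table`,
#'   `fit_report`, `ranking`, and `esum_group_means`.
#' @export
run_headline_experiments <- function(seed = 1L,
                                     config = pipeline_config()) {
  cc <- config$cohort
  cc$seed <- as.integer(seed)
  cohort <- generate_cohort(cc)
  ft <- extract_features(cohort, r2_min = config$r2_min,
                         short_window = config$short_window,
                         long_window = config$long_window)
  report <- attr(ft, "fit_report")

  hd <- ft[ft$status %in% c(0, 2), , drop = FALSE]
  ht <- ft[ft$status %in% c(0, 1), , drop = FALSE]
  td <- ft[ft$status %in% c(1, 2), , drop = FALSE]

  acc <- c(
    hd_all9   = tuned_task(hd, MARKER_NAMES, seed, config$grid)$accuracy,
    hd_esum   = tuned_task(hd, "Esum", seed, config$grid)$accuracy,
    hd_ft     = tuned_task(hd, "fT", seed, config$grid)$accuracy,
    ht_all9   = tuned_task(ht, MARKER_NAMES, seed, config$grid)$accuracy,
    td_all9   = tuned_task(td, MARKER_NAMES, seed, config$grid)$accuracy,
    multi_all9 = NA_real_, multi_top5 = NA_real_,
    multi_esum = NA_real_, multi_alphaR = NA_real_)

  multi_task <- tuned_task(ft, MARKER_NAMES, seed, config$grid)
  acc["multi_all9"] <- multi_task$accuracy
  ranking <- rfe_rank(multi_task$split$train, MARKER_NAMES,
                      C = multi_task$C, sigma = multi_task$sigma)$ranking
  acc["multi_top5"] <- tuned_task(ft, ranking[1:5], seed, config$grid)$accuracy
  acc["multi_esum"] <- tuned_task(ft, "Esum", seed, config$grid)$accuracy
  acc["multi_alphaR"] <- tuned_task(ft, "alphaR", seed, config$grid)$accuracy

  gt <- cohort$ground_truth
  list(accuracies = acc, feature_table = ft, fit_report = report,
       ranking = ranking,
       esum_group_means = tapply(gt$Esum, gt$status, mean))
}

#' Run the full analysis pipeline and write its artifacts
#'
#' Executes simulate, extract, classify, select and assess for one
#' configuration and writes plain-text artifacts to `out_dir`:
#' `ground_truth.csv`, `feature_table.csv`, `metrics.json`,
#' `ablation_report.json`, `recovery_report.json` and `run_manifest.json`.
#' Rerunning with the same configuration reproduces identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return Invisibly, the list of result objects.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seeds[1]

  cohort <- generate_cohort(config$cohort)
  utils::write.csv(cohort$ground_truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)

  ft <- extract_features(cohort, r2_min = config$r2_min,
                         short_window = config$short_window,
                         long_window = config$long_window)
  utils::write.csv(ft, file.path(out_dir, "feature_table.csv"),
                   row.names = FALSE)

  state_task <- tuned_task(ft, MARKER_NAMES, seed, config$grid)
  metrics <- list(
    seed = seed,
    three_state = list(accuracy = state_task$accuracy, macro_auc = state_task$auc,
                       C = state_task$C, sigma = state_task$sigma,
                       confusion = as.data.frame(state_task$metrics$confusion)),
    fit_report = attr(ft, "fit_report"))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "columns")

  abl <- ablation_report(ft, MARKER_NAMES, C = state_task$C, sigma = state_task$sigma,
                         seed = seed)
  jsonlite::write_json(unclass(abl), file.path(out_dir, "ablation_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  rec <- recovery_report(ft, MARKER_NAMES, grid = config$grid, seed = seed)
  jsonlite::write_json(unclass(rec), file.path(out_dir, "recovery_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("viscomarker")),
    cohort_seed = config$cohort$seed, experiment_seed = seed,
    noise_sd = config$cohort$noise_sd,
    n_measurements = nrow(cohort$ground_truth),
    n_retained = nrow(ft),
    config_hash = config_hash(config))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(cohort = cohort, feature_table = ft, metrics = metrics,
                 ablation = abl, recovery = rec, manifest = manifest))
}

# deterministic short hash of a configuration (no digest dependency)
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", h)
}
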