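# End-to-end orchestration: cohort -> features -> selection -> kernel ->
# classifier -> evaluation, with a manifest capturing every configuration
# value so a run is reproducible from the returned object alone.

#' Run the full screening pipeline
#'
#' Orchestrates one complete experiment: obtain a cohort (a supplied
#' `cohort_table` or a synthetic one generated from `seed`), extract the
#' multimodal feature table, standardize with training-set parameters,
#' rank features with a random forest, keep the top importance
#' percentile, build the quantum-inspired kernel specification, compute
#' train/test Gram matrices, fit the support-vector classifier and
#' evaluate it on the held-out rows.
#'
#' @param cohort optional `cohort_table`; when NULL a synthetic cohort is
#'   generated with [synth_cohort()].
#' @param seed integer master seed; all stochastic stages draw child
#'   seeds from it.
#' @param n cohort size when simulating (default 194).
#' @param profiles effect profiles for simulation
#'   (default [class_effect_profiles()]).
#' @param percentile importance-selection percentile (default 80).
#' @param scale kernel angle scale factor (default 10).
#' @param cost soft-margin cost for the classifier (default 1).
#' @param n_trees random-forest size (default 500).
#' @param n_mfcc_components retained MFCC principal components (default 10).
#' @param run_benchmarks also run [benchmark_suite()] over the classical
#'   baselines (default FALSE; adds several minutes).
#' @param benchmark_quantum_subset optional row indices (within the test
#'   rows) for the circuit-simulated feature-map baselines.
#' @param progress print progress dots during feature extraction.
#' @return object of class `pipeline_result`: `evaluation` (an
#'   `eval_report`), `kernel_spec`, `importance`, `features`
#'   (standardized `feature_table`), `model`, `gram_train`, `gram_test`,
#'   `predictions`, `benchmarks` (NULL unless requested), `manifest`.
#' @export
run_pipeline <- function(cohort = NULL, seed = 1L, n = 194L,
                         profiles = class_effect_profiles(),
                         percentile = 80, scale = 10, cost = 1,
                         n_trees = 500L, n_mfcc_components = 10L,
                         run_benchmarks = FALSE,
                         benchmark_quantum_subset = NULL,
                         progress = FALSE) {
  simulated <- is.null(cohort)
  if (simulated) {
    cohort <- synth_cohort(n = n, profiles = profiles,
                           seed = child_seed(seed, "cohort"))
  }
  feats <- extract_features(cohort, n_mfcc_components = n_mfcc_components,
                            progress = progress)
  feats <- standardize(feats)
  imp <- rf_importances(feats, n_trees = n_trees, seed = seed)
  imp <- select_top_percentile(imp, q = percentile)
  ks <- build_kernel_spec(feats, imp, scale = scale)

  train <- feats$split == "train"
  a_tr <- ks$matrix[train, , drop = FALSE]
  a_te <- ks$matrix[!train, , drop = FALSE]
  gram_tr <- gram_matrix(a_tr, spec = ks$spec)
  gram_te <- gram_matrix(a_te, a_tr, spec = ks$spec)
  y_tr <- feats$labels[train]
  y_te <- feats$labels[!train]

  model <- svm_fit(gram_tr, y_tr, C = cost)
  pred <- svm_predict(model, gram_te)
  evaluation <- confusion_and_metrics(y_te, pred,
                                      scores = svm_decision(model, gram_te))

  benchmarks <- NULL
  if (run_benchmarks) {
    benchmarks <- benchmark_suite(
      kernel_matrix = ks$matrix, features = feats$matrix,
      labels = feats$labels, split = feats$split,
      spec = ks$spec, C = cost, seed = seed,
      quantum_subset = benchmark_quantum_subset)
  }

  manifest <- list(
    seed = seed, simulated = simulated,
    n_participants = length(feats$labels),
    n_train = sum(train), n_test = sum(!train),
    n_features_extracted = length(feats$feature_names) +
      length(feats$dropped_columns),
    n_features_standardized = length(feats$feature_names),
    n_features_selected = length(ks$spec$selected_feature_names),
    percentile = percentile, scale = scale, cost = cost,
    n_trees = n_trees, n_mfcc_components = n_mfcc_components,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  structure(list(
    evaluation = evaluation, kernel_spec = ks$spec, importance = imp,
    features = feats, model = model, gram_train = gram_tr,
    gram_test = gram_te, predictions = pred, truth = y_te,
    benchmarks = benchmarks, manifest = manifest,
    cohort = cohort), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("Screening pipeline result\n")
  cat(sprintf("  cohort: %d participants (%d train / %d test)%s\n",
              m$n_participants, m$n_train, m$n_test,
              if (m$simulated) ", simulated" else ""))
  cat(sprintf("  features: %d extracted -> %d standardized -> %d selected (p%d)\n",
              m$n_features_extracted, m$n_features_standardized,
              m$n_features_selected, as.integer(m$percentile)))
  cat(sprintf("  kernel: %d weighted angle features, scale %.3g; SVC cost %.3g\n",
              m$n_features_selected, m$scale, m$cost))
  print(x$evaluation)
  if (!is.null(x$benchmarks)) {
    cat("\nBenchmarks:\n")
    print(report_table(x$benchmarks))
  }
  invisible(x)
}
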