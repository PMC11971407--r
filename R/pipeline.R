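# Feature-table assembly and the selection/weighting pipeline:
# z-score standardization with training-set parameters, random-forest
# importance ranking, 80th-percentile selection, importance-multiplied and
# rescaled columns, and the softmax measurement weights of the kernel.

#' Extract the full multimodal feature table for a cohort
#'
#' Runs the gait, tapping, voice and demographic feature extractors over
#' every participant and merges the blocks into one participants-by-features
#' table.  MFCC summaries are reduced to 10 principal components with the
#' projection fitted on training rows only.  Demographics are encoded as
#' `demo_age` (years), `demo_gender` (female = 1), `demo_smoker` (0/1).
#'
#' @param cohort a `cohort_table` whose records carry in-memory trial
#'   objects (as produced by [synth_cohort()]) or file paths readable by
#'   the modality readers.
#' @param n_mfcc_components retained MFCC principal components.
#' @param progress print a dot per participant.
#' @return object of class `feature_table`: list with `matrix`
#'   (numeric, rownames = participant ids), `labels`, `split`,
#'   `feature_names`.
#' @export
extract_features <- function(cohort, n_mfcc_components = 10L,
                             progress = FALSE) {
  recs <- cohort$records
  n <- length(recs)
  resolve <- function(ref, reader) {
    # unwrap a plain container list (e.g. a single-trial list) but not a
    # classed trial object, which is itself a list
    obj <- if (is.list(ref) && is.null(attr(ref, "class"))) ref[[1L]] else ref
    if (is.character(obj)) reader(obj) else obj
  }
  rows <- vector("list", n)
  mfccs <- matrix(NA_real_, n, 26L)
  for (i in seq_len(n)) {
    r <- recs[[i]]
    gait <- resolve(r$trial_refs$gait, function(p)
      read_accel_trace(p, source_activity = "gait"))
    tapping <- r$trial_refs$tapping
    if (is.list(tapping) && length(tapping) == 1L && is.null(names(tapping))) {
      tapping <- tapping[[1L]]
    }
    pick <- function(field) {
      if (!is.null(names(tapping)) && field %in% names(tapping)) {
        tapping[[field]]
      } else {
        tapping
      }
    }
    tap_ev <- resolve(pick("events"), read_tap_events)
    tap_tr <- resolve(pick("trace"),
                      function(p) read_accel_trace(p, source_activity = "tapping"))
    clip <- resolve(r$trial_refs$voice, read_audio)

    vb <- voice_feature_block(clip)
    demo <- c(demo_age = as.numeric(r$age),
              demo_gender = as.numeric(identical(r$gender, "female")),
              demo_smoker = as.numeric(isTRUE(r$smoker)))
    rows[[i]] <- c(gait_feature_block(gait),
                   tapping_feature_block(tap_ev, tap_tr),
                   vb$features, demo)
    mfccs[i, ] <- vb$mfcc
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  mat <- do.call(rbind, rows)
  rownames(mat) <- vapply(recs, `[[`, character(1), "participant_id")
  train_mask <- cohort$split$split == "train"
  pca <- mfcc_pca(mfccs, train_mask, n_mfcc_components)
  pcs <- pca$scores
  colnames(pcs) <- paste0("voice_", colnames(pcs))
  mat <- cbind(mat, pcs)
  structure(list(
    matrix = mat, labels = cohort$split$label, split = cohort$split$split,
    feature_names = colnames(mat), mfcc_pca = pca
  ), class = "feature_table")
}

#' Standardize a feature table with training-set parameters
#'
#' Missing values are imputed with the training-column median, then every
#' column is z-scored using the training rows' mean and population
#' standard deviation; columns that are constant (or all-missing) on the
#' training rows are dropped with a warning.
#'
#' @param table a `feature_table`.
#' @return the table with a standardized `matrix`, plus
#'   `standardization` (per-column mean/std/median) and `dropped_columns`.
#' @export
standardize <- function(table) {
  mat <- table$matrix
  train <- table$split == "train"
  meds <- apply(mat[train, , drop = FALSE], 2L, median, na.rm = TRUE)
  imputed <- which(is.na(mat), arr.ind = TRUE)
  if (nrow(imputed)) mat[imputed] <- meds[imputed[, 2L]]
  mu <- colMeans(mat[train, , drop = FALSE])
  sdv <- apply(mat[train, , drop = FALSE], 2L, pop_sd)
  drop <- !is.finite(sdv) | sdv < 1e-12 | !is.finite(mu)
  if (any(drop)) {
    warning(sprintf("dropping %d degenerate column(s): %s", sum(drop),
                    paste(colnames(mat)[drop], collapse = ", ")))
  }
  dropped <- colnames(mat)[drop]
  keep <- which(!drop)
  mat <- sweep(sweep(mat[, keep, drop = FALSE], 2L, mu[keep]), 2L,
               sdv[keep], `/`)
  table$matrix <- mat
  table$feature_names <- colnames(mat)
  table$standardization <- list(mean = mu[keep], std = sdv[keep],
                                median = meds[keep])
  table$dropped_columns <- dropped
  table$n_imputed <- nrow(imputed)
  table
}

#' Random-forest feature importances
#'
#' Impurity-based (mean decrease in Gini) importances from a forest fit on
#' the training rows only, normalized to sum to 1.
#'
#' @param table a standardized `feature_table`.
#' @param n_trees forest size (default 500).
#' @param seed integer seed (forest growth is randomized).
#' @return object of class `importance_profile`: `importances` (named,
#'   sums to 1), `selected` (filled by [select_top_percentile()]),
#'   `percentile_cut`.
#' @export
rf_importances <- function(table, n_trees = 500L, seed = 1L) {
  train <- table$split == "train"
  y <- factor(table$labels[train], levels = c("control", "PD"))
  if (nlevels(droplevels(y)) < 2L) {
    stop("training rows must contain both classes", call. = FALSE)
  }
  set.seed(child_seed(seed, "rf-importance"))
  fit <- randomForest::randomForest(
    x = as.data.frame(table$matrix[train, , drop = FALSE]), y = y,
    ntree = n_trees, importance = FALSE)
  imp <- fit$importance[, "MeanDecreaseGini"]
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  names(imp) <- table$feature_names
  structure(list(importances = imp, selected = NULL, percentile_cut = NA_real_),
            class = "importance_profile")
}

#' Select features at or above an importance percentile
#'
#' The threshold is the linear-interpolation percentile of the importance
#' vector; features with importance greater than or equal to the threshold
#' are kept (so full ties with the threshold survive).
#'
#' @param profile an `importance_profile`.
#' @param q percentile in \[0, 100\] (default 80).
#' @return the profile with `selected` (named logical) and
#'   `percentile_cut` filled in.
#' @export
select_top_percentile <- function(profile, q = 80) {
  imp <- profile$importances
  if (length(imp) < 5L) stop("need at least 5 features", call. = FALSE)
  thr <- as.numeric(quantile(imp, q / 100, type = 7, names = FALSE))
  profile$selected <- imp >= thr
  profile$percentile_cut <- q
  profile$threshold <- thr
  profile
}

#' Build the kernel specification and transformed matrix
#'
#' Selected standardized columns are multiplied by their importances,
#' reordered by importance (descending, ties broken by name), then scaled
#' by a common factor (default 10) so typical magnitudes approach 1 for
#' the angle embedding.  The kernel measurement weights are the softmax of
#' the selected features' raw importances (temperature 1).  Angles beyond
#' +/- pi after scaling are counted and reported as a data-quality note.
#'
#' @param table a standardized `feature_table`.
#' @param profile a selected `importance_profile` for this table.
#' @param scale common post-multiplication factor (default 10).
#' @return list: `spec` (class `kernel_spec`: `selected_feature_names`,
#'   `column_scalers`, `softmax_weights`, `scale`,
#'   `standardization_params`) and `matrix` (transformed, columns in
#'   kernel order).
#' @export
build_kernel_spec <- function(table, profile, scale = 10) {
  if (is.null(profile$selected)) {
    profile <- select_top_percentile(profile)
  }
  sel <- names(profile$selected)[profile$selected]
  if (!length(sel)) stop("empty feature selection", call. = FALSE)
  imp <- profile$importances[sel]
  ord <- order(-imp, sel)
  sel <- sel[ord]; imp <- imp[ord]
  w <- exp(imp - max(imp))
  w <- w / sum(w)
  transformed <- sweep(table$matrix[, sel, drop = FALSE], 2L, imp, `*`) * scale
  n_wrap <- sum(abs(transformed) > pi)
  if (n_wrap > 0) {
    message(sprintf("note: %d angle(s) exceed +/- pi after scaling (%.1f%%)",
                    n_wrap, 100 * n_wrap / length(transformed)))
  }
  spec <- structure(list(
    selected_feature_names = sel,
    column_scalers = imp * scale,
    softmax_weights = w,
    scale = scale,
    standardization_params = table$standardization
  ), class = "kernel_spec")
  list(spec = spec, matrix = transformed)
}

#' Serialize / deserialize a kernel spec as YAML
#' @param spec a `kernel_spec`.
#' @param path file path.
#' @return `read_kernel_spec` returns the `kernel_spec`.
#' @export
write_kernel_spec <- function(spec, path) {
  to_y <- function(x) {
    if (is.list(x)) lapply(x, to_y)
    else if (is.numeric(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(to_y(unclass(spec)), path, precision = 17L)
  invisible(path)
}

#' @rdname write_kernel_spec
#' @export
read_kernel_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  to_num <- function(x) unlist(x)
  structure(list(
    selected_feature_names = unlist(raw$selected_feature_names),
    column_scalers = to_num(raw$column_scalers),
    softmax_weights = to_num(raw$softmax_weights),
    scale = raw$scale,
    standardization_params = lapply(raw$standardization_params, to_num)
  ), class = "kernel_spec")
}
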