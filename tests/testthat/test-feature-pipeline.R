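# Build a small deterministic feature table without running extractors.
toy_table <- function(mat, labels, split) {
  structure(list(matrix = mat, labels = labels, split = split,
                 feature_names = colnames(mat)), class = "feature_table")
}

test_that("standardization z-scores with train parameters and population std", {
  mat <- cbind(a = c(1, 2, 3, 10), b = c(4, 4, 4, 4), c = c(0, 1, 2, 2))
  rownames(mat) <- paste0("P", 1:4)
  tab <- toy_table(mat, c("PD", "control", "PD", "control"),
                   c("train", "train", "train", "test"))
  expect_warning(st <- standardize(tab), "constant|degenerate")
  expect_false("b" %in% colnames(st$matrix))
  expect_equal(unname(st$matrix[1:3, "a"]),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  # test value equal to the train mean -> 0
  mat2 <- cbind(a = c(1, 3, 2), b = c(5, 7, 9))
  tab2 <- toy_table(mat2, c("PD", "control", "PD"),
                    c("train", "train", "test"))
  st2 <- standardize(tab2)
  expect_equal(unname(st2$matrix[3, "a"]), 0)
})

test_that("missing values are imputed with the train median before scaling", {
  mat <- cbind(a = c(1, 2, 3, NA), b = c(1, 5, 9, 5))
  tab <- toy_table(mat, c("PD", "control", "PD", "control"),
                   c("train", "train", "train", "test"))
  st <- standardize(tab)
  expect_equal(st$n_imputed, 1)
  # imputed with train median 2, standardized -> (2 - 2) / sd = 0
  expect_equal(unname(st$matrix[4, "a"]), 0)
  expect_false(anyNA(st$matrix))
})

test_that("fit/transform separability: stored params reproduce the transform", {
  set.seed(2)
  mat <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, paste0("f", 1:5)))
  tab <- toy_table(mat, rep(c("PD", "control"), 4),
                   rep(c("train", "test"), c(6, 2)))
  st <- standardize(tab)
  manual <- sweep(sweep(mat, 2L, st$standardization$mean), 2L,
                  st$standardization$std, `/`)
  expect_identical(unname(st$matrix), unname(manual))
})

test_that("random-forest importances normalize, rank separability, and repeat", {
  set.seed(4)
  n <- 60
  y <- rep(c("PD", "control"), n / 2)
  sep <- ifelse(y == "PD", 1, -1) + rnorm(n, 0, 0.05)
  mat <- cbind(signal = sep,
               matrix(rnorm(n * 9), n, 9,
                      dimnames = list(NULL, paste0("noise", 1:9))))
  tab <- toy_table(mat, y, rep("train", n))
  imp <- rf_importances(tab, n_trees = 200, seed = 5)
  expect_equal(sum(imp$importances), 1, tolerance = 1e-9)
  expect_equal(names(which.max(imp$importances)), "signal")
  imp2 <- rf_importances(tab, n_trees = 200, seed = 5)
  expect_identical(imp$importances, imp2$importances)
})

test_that("single-class training labels error", {
  mat <- matrix(rnorm(30), 6, 5, dimnames = list(NULL, paste0("f", 1:5)))
  tab <- toy_table(mat, rep("PD", 6), rep("train", 6))
  expect_error(rf_importances(tab), "class")
})

test_that("percentile selection follows the linear-interpolation threshold", {
  mk <- function(v) structure(list(importances = setNames(v / sum(v),
                                                          paste0("f", seq_along(v))),
                                   selected = NULL, percentile_cut = NA_real_),
                              class = "importance_profile")
  # importances 1..10, q=80: threshold 8.2 -> features 9 and 10 kept
  p <- select_top_percentile(mk(1:10), 80)
  expect_identical(names(which(p$selected)), c("f9", "f10"))
  # all equal -> all kept (ties at the threshold survive)
  p2 <- select_top_percentile(mk(rep(1, 10)), 80)
  expect_true(all(p2$selected))
  # q = 0 -> all kept
  p3 <- select_top_percentile(mk(1:10), 0)
  expect_true(all(p3$selected))
})

test_that("kernel spec applies x importance, reorder, x scale, softmax", {
  mat <- cbind(a = c(0.8, 0), b = c(0.5, 1), c = c(0.1, 0.2))
  tab <- toy_table(mat, c("PD", "control"), c("train", "train"))
  prof <- structure(list(
    importances = c(a = 0.1, b = 0.6, c = 0.3),
    selected = c(a = TRUE, b = TRUE, c = FALSE),
    percentile_cut = 80), class = "importance_profile")
  ks <- build_kernel_spec(tab, prof, scale = 10)
  # ordered by importance descending
  expect_identical(ks$spec$selected_feature_names, c("b", "a"))
  # transformed value = standardized x importance x 10
  expect_equal(unname(ks$matrix[1, "a"]), 0.8 * 0.1 * 10)
  expect_equal(sum(ks$spec$softmax_weights), 1)
  # softmax over raw importances 0.6, 0.1
  w <- exp(c(0.6, 0.1)); w <- w / sum(w)
  expect_equal(unname(ks$spec$softmax_weights), w)
})

test_that("softmax weights: equal importances and shift invariance", {
  mat <- matrix(rnorm(8), 2, 4, dimnames = list(NULL, letters[1:4]))
  tab <- toy_table(mat, c("PD", "control"), c("train", "train"))
  prof_eq <- structure(list(
    importances = setNames(rep(0.25, 4), letters[1:4]),
    selected = setNames(c(TRUE, TRUE, FALSE, FALSE), letters[1:4]),
    percentile_cut = 80), class = "importance_profile")
  ks <- build_kernel_spec(tab, prof_eq)
  expect_equal(unname(ks$spec$softmax_weights), c(0.5, 0.5))

  # importances (ln 2 + c, c) -> weights (2/3, 1/3) for any c
  for (cc in c(0, 0.1)) {
    imp <- c(x = log(2) + cc, y = cc)
    w <- exp(imp - max(imp)); w <- w / sum(w)
    expect_equal(unname(w), c(2 / 3, 1 / 3))
  }
})

test_that("column order of the input table does not change the result", {
  set.seed(11)
  mat <- matrix(rnorm(20), 4, 5, dimnames = list(NULL, paste0("f", 1:5)))
  tab <- toy_table(mat, c("PD", "control", "PD", "control"),
                   rep("train", 4))
  prof <- structure(list(
    importances = setNames(c(0.3, 0.25, 0.2, 0.15, 0.1), paste0("f", 1:5)),
    selected = setNames(c(TRUE, TRUE, TRUE, FALSE, FALSE), paste0("f", 1:5)),
    percentile_cut = 80), class = "importance_profile")
  k1 <- build_kernel_spec(tab, prof)
  perm <- c(4, 2, 5, 1, 3)
  tab2 <- toy_table(mat[, perm], tab$labels, tab$split)
  prof2 <- prof
  prof2$importances <- prof$importances[perm]
  prof2$selected <- prof$selected[perm]
  k2 <- build_kernel_spec(tab2, prof2)
  expect_identical(k1$spec$selected_feature_names,
                   k2$spec$selected_feature_names)
  expect_equal(k1$matrix, k2$matrix)
})

test_that("kernel spec YAML round-trips", {
  spec <- toy_kernel_spec(3)
  spec$standardization_params <- list(mean = c(f1 = 0.1, f2 = -0.2, f3 = 1),
                                      std = c(f1 = 1, f2 = 2, f3 = 0.5))
  p <- withr::local_tempfile(fileext = ".yaml")
  write_kernel_spec(spec, p)
  spec2 <- read_kernel_spec(p)
  expect_identical(spec2$selected_feature_names, spec$selected_feature_names)
  expect_equal(spec2$softmax_weights, spec$softmax_weights,
               ignore_attr = TRUE)
  expect_equal(spec2$standardization_params$mean,
               spec$standardization_params$mean)
})

test_that("extract_features merges blocks for a tiny in-memory cohort", {
  recs <- c(lapply(1:3, function(i) make_participant(paste0("PD", i), "PD",
                                                     seed = i)),
            lapply(1:3, function(i) make_participant(paste0("CT", i), "control",
                                                     seed = i + 50)))
  co <- assemble_cohort(recs, train_n = 4, test_n = 2, seed = 2)
  ft <- extract_features(co, n_mfcc_components = 2)
  expect_equal(nrow(ft$matrix), 6)
  expect_true(all(c("gait_rms_z", "tap_taps_total", "voice_hnr_db",
                    "demo_age", "voice_mfcc_pc1") %in% colnames(ft$matrix)))
  expect_identical(rownames(ft$matrix), co$split$participant_id)
})
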