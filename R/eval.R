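# Maximum-margin classification on precomputed Gram matrices, the
# confusion-matrix metric set, exact McNemar comparisons, and the
# benchmark suite of classical and feature-map models.

#' Fit a soft-margin SVM on a precomputed Gram matrix
#'
#' Solves the C-SVC dual on the kernel matrix (via kernlab's SMO) and
#' stores the support set, signed dual coefficients and bias so the
#' decision function is reproducible without the solver.  PD is the
#' positive class.
#'
#' @param train_gram square `gram_matrix` (or plain matrix) over the
#'   training rows.
#' @param labels character/factor labels ("PD" / "control").
#' @param C soft-margin cost (default 1; the kernel itself has no
#'   hyperparameters).
#' @return object of class `qsvm_model`: `support_indices`,
#'   `dual_coefficients` (alpha_i y_i for the support set), `bias`,
#'   `positive_label`, `C`, `n_train`.
#' @export
svm_fit <- function(train_gram, labels, C = 1.0) {
  K <- if (inherits(train_gram, "gram_matrix")) train_gram$values else train_gram
  if (nrow(K) != ncol(K)) stop("training Gram must be square", call. = FALSE)
  if (max(abs(K - t(K))) > 1e-8) stop("training Gram must be symmetric", call. = FALSE)
  y <- factor(as.character(labels), levels = c("control", "PD"))
  if (nlevels(droplevels(y)) < 2L) stop("need two classes", call. = FALSE)
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "C-svc", C = C)
  sv <- kernlab::SVindex(fit)
  co <- unlist(kernlab::coef(fit))
  b <- kernlab::b(fit)
  model <- structure(list(
    support_indices = sv, dual_coefficients = co, bias = -b,
    positive_label = "PD", negative_label = "control",
    C = C, n_train = nrow(K)
  ), class = "qsvm_model")
  # kernlab's internal +1 class can be either level; orient the decision
  # function so positive scores mean PD
  scores <- drop(K[, sv, drop = FALSE] %*% co) - b
  pred <- kernlab::predict(fit, kernlab::as.kernelMatrix(K[, sv, drop = FALSE]))
  agree_pd <- mean((scores > 0) == (pred == "PD"))
  if (agree_pd < 0.5) {
    model$dual_coefficients <- -co
    model$bias <- b
  }
  model
}

#' Decision scores and label predictions from a fitted model
#'
#' `scores = sum_i alpha_i y_i K(x, x_i) + b`; labels by sign, with a
#' zero score mapped to the positive (PD) class.
#'
#' @param model a `qsvm_model`.
#' @param cross_gram test-by-train `gram_matrix` (or matrix) whose columns
#'   align with the training rows the model was fitted on.
#' @return `svm_decision`: numeric scores; `svm_predict`: character labels.
#' @export
svm_decision <- function(model, cross_gram) {
  K <- if (inherits(cross_gram, "gram_matrix")) cross_gram$values else cross_gram
  if (ncol(K) != model$n_train) {
    stop("cross-Gram columns do not align with the training rows", call. = FALSE)
  }
  drop(K[, model$support_indices, drop = FALSE] %*% model$dual_coefficients) +
    model$bias
}

#' @rdname svm_decision
#' @export
svm_predict <- function(model, cross_gram) {
  s <- svm_decision(model, cross_gram)
  ifelse(s >= 0, model$positive_label, model$negative_label)
}

#' Rank-statistic ROC AUC
#'
#' Probability that a random positive scores above a random negative,
#' ties counted half (the Mann-Whitney statistic).
#'
#' @param y_true labels; `positive` names the positive class.
#' @param scores continuous decision scores.
#' @param positive positive class label (default "PD").
#' @return AUC in \[0, 1\]; NA if a class is absent.
#' @export
roc_auc <- function(y_true, scores, positive = "PD") {
  pos <- y_true == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion matrix and derived metrics
#'
#' @param y_true,y_pred labels ("PD" positive, "control" negative).
#' @param scores optional continuous scores for the AUC.
#' @return object of class `eval_report`: `confusion` (TP, FN, FP, TN),
#'   `accuracy`, `precision`, `recall_sensitivity`, `specificity`, `f1`,
#'   `roc_auc`, `n_test`.  A metric with a zero denominator is NA.
#' @export
confusion_and_metrics <- function(y_true, y_pred, scores = NULL) {
  stopifnot(length(y_true) == length(y_pred))
  pos <- "PD"
  tp <- sum(y_true == pos & y_pred == pos)
  fn <- sum(y_true == pos & y_pred != pos)
  fp <- sum(y_true != pos & y_pred == pos)
  tn <- sum(y_true != pos & y_pred != pos)
  n <- tp + fn + fp + tn
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  structure(list(
    confusion = c(TP = tp, FN = fn, FP = fp, TN = tn),
    accuracy = safe_div(tp + tn, n),
    precision = prec,
    recall_sensitivity = rec,
    specificity = safe_div(tn, tn + fp),
    f1 = if (is.na(prec) || is.na(rec) || (prec + rec) == 0) NA_real_
         else 2 * prec * rec / (prec + rec),
    roc_auc = if (is.null(scores)) NA_real_ else roc_auc(y_true, scores),
    n_test = n
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cm <- x$confusion
  cat("            Predicted positive  Predicted negative  Total\n")
  cat(sprintf("Actual positive %12d %19d %6d\n", cm["TP"], cm["FN"],
              cm["TP"] + cm["FN"]))
  cat(sprintf("Actual negative %12d %19d %6d\n", cm["FP"], cm["TN"],
              cm["FP"] + cm["TN"]))
  cat(sprintf("accuracy %.3f  precision %.3f  recall %.3f  specificity %.3f  f1 %.3f  auc %s\n",
              x$accuracy, x$precision, x$recall_sensitivity, x$specificity,
              x$f1, ifelse(is.na(x$roc_auc), "NA", sprintf("%.3f", x$roc_auc))))
  invisible(x)
}

#' Exact two-sided McNemar test
#'
#' For discordant-pair counts b and c, the exact binomial p-value
#' `2 * P(Binomial(b + c, 1/2) <= min(b, c))`, capped at 1; p = 1 when
#' b = c = 0.
#'
#' @param b,c non-negative discordant-pair counts.
#' @return two-sided p-value.
#' @export
mcnemar_exact <- function(b, c) {
  stopifnot(b >= 0, c >= 0)
  n <- b + c
  if (n == 0) return(1)
  k <- min(b, c)
  p <- 2 * pbinom(k, n, 0.5)
  if (b == c) p <- p - dbinom(k, n, 0.5)   # central term counted once
  min(1, p)
}

# discordant counts of two prediction vectors against the truth
discordant_counts <- function(y_true, pred1, pred2) {
  ok1 <- pred1 == y_true; ok2 <- pred2 == y_true
  c(b = sum(ok1 & !ok2), c = sum(!ok1 & ok2))
}

#' Benchmark suite over the proposed kernel and baseline models
#'
#' Trains and evaluates, on identical train/test rows: the proposed
#' quantum-inspired kernel SVM; linear, polynomial and RBF SVMs; logistic
#' regression; random forest; gradient boosting; naive Bayes; k-NN; and
#' the Z and ZZ feature-map fidelity kernels (optionally on a reduced
#' sample subset, since the entangling ZZ map needs full statevector
#' simulation).  A failing model is recorded as failed and the suite
#' continues.
#'
#' @param kernel_matrix angle-scaled feature matrix in kernel-spec column
#'   order (output of [build_kernel_spec()]).
#' @param features standardized (unweighted) feature matrix for the
#'   classical baselines.
#' @param labels,split per-row labels and "train"/"test" assignment.
#' @param spec the `kernel_spec`.
#' @param C SVM cost.
#' @param seed integer seed for the randomized baselines.
#' @param quantum_subset optional `c(n_train, n_test)` row counts for the
#'   Z/ZZ feature-map baselines (e.g. `c(30, 15)`); the ZZ map is
#'   additionally restricted to the first `min(15, ncol)` kernel features.
#' @param mcnemar compute pairwise exact McNemar p-values against the
#'   proposed model.
#' @return data.frame with one row per model: metrics, `n_test`,
#'   `mcnemar_p` (vs the proposed model), `failed`.
#' @export
benchmark_suite <- function(kernel_matrix, features, labels, split, spec,
                            C = 1.0, seed = 1L, quantum_subset = NULL,
                            mcnemar = TRUE) {
  tr <- split == "train"; te <- split == "test"
  y_tr <- labels[tr]; y_te <- labels[te]
  Xtr <- features[tr, , drop = FALSE]; Xte <- features[te, , drop = FALSE]
  Atr <- kernel_matrix[tr, , drop = FALSE]; Ate <- kernel_matrix[te, , drop = FALSE]

  results <- list(); preds <- list()
  truths <- list()
  add <- function(name, fit_fn) {
    out <- tryCatch(fit_fn(), error = function(e) e)
    if (inherits(out, "error")) {
      results[[name]] <<- list(report = NULL, failed = conditionMessage(out))
    } else {
      y_use <- out$y %||% y_te
      rep <- confusion_and_metrics(y_use, out$pred, out$scores)
      results[[name]] <<- list(report = rep, failed = NA_character_)
      preds[[name]] <<- out$pred
      truths[[name]] <<- y_use
    }
  }

  add("Proposed", function() {
    Ktr <- gram_matrix(Atr, Atr, spec)
    m <- svm_fit(Ktr, y_tr, C = C)
    Kte <- gram_matrix(Ate, Atr, spec)
    list(pred = svm_predict(m, Kte), scores = svm_decision(m, Kte))
  })

  svm_e1071 <- function(kern, ...) function() {
    yf <- factor(y_tr, levels = c("control", "PD"))
    m <- e1071::svm(Xtr, yf, kernel = kern, cost = C, probability = FALSE,
                    scale = FALSE, ...)
    dv <- attr(predict(m, Xte, decision.values = TRUE), "decision.values")
    s <- drop(dv)
    # e1071 names the pair by training-order, e.g. "PD/control"; a positive
    # decision value favors the first-named class
    if (grepl("^control", colnames(dv)[1L])) s <- -s  # orient PD-positive
    list(pred = as.character(predict(m, Xte)), scores = s)
  }
  add("Linear SVM", svm_e1071("linear"))
  add("Polynomial SVM", svm_e1071("polynomial"))
  add("RBF SVM", svm_e1071("radial"))

  add("Logistic Regression", function() {
    df <- data.frame(y = as.integer(y_tr == "PD"), Xtr)
    m <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    p <- suppressWarnings(predict(m, newdata = data.frame(Xte), type = "response"))
    list(pred = ifelse(p >= 0.5, "PD", "control"), scores = p)
  })

  add("Random Forest", function() {
    set.seed(child_seed(seed, "bench-rf"))
    m <- randomForest::randomForest(Xtr, factor(y_tr, levels = c("control", "PD")))
    p <- predict(m, Xte, type = "prob")[, "PD"]
    list(pred = ifelse(p >= 0.5, "PD", "control"), scores = p)
  })

  add("Gradient Boost", function() {
    set.seed(child_seed(seed, "bench-gb"))
    dtr <- xgboost::xgb.DMatrix(Xtr, label = as.integer(y_tr == "PD"))
    m <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                          max_depth = 3, eta = 0.1,
                                          nthread = 1),
                            data = dtr, nrounds = 100, verbose = 0)
    p <- predict(m, xgboost::xgb.DMatrix(Xte))
    list(pred = ifelse(p >= 0.5, "PD", "control"), scores = p)
  })

  add("Naive Bayes", function() {
    m <- e1071::naiveBayes(Xtr, factor(y_tr, levels = c("control", "PD")))
    p <- predict(m, Xte, type = "raw")[, "PD"]
    list(pred = ifelse(p >= 0.5, "PD", "control"), scores = p)
  })

  add("KNN", function() {
    pr <- class::knn(Xtr, Xte, factor(y_tr, levels = c("control", "PD")),
                     k = 5, prob = TRUE)
    conf <- attr(pr, "prob")
    s <- ifelse(pr == "PD", conf, 1 - conf)
    list(pred = as.character(pr), scores = s)
  })

  # feature-map baselines, optionally on a reduced subset
  sub_tr <- seq_len(if (!is.null(quantum_subset))
    min(quantum_subset[1L], nrow(Atr)) else nrow(Atr))
  sub_te <- seq_len(if (!is.null(quantum_subset))
    min(quantum_subset[2L], nrow(Ate)) else nrow(Ate))

  add("Z Feature Map", function() {
    A1 <- Atr[sub_tr, , drop = FALSE]; A2 <- Ate[sub_te, , drop = FALSE]
    K <- pairwise_gram(A1, A1, function(u, v) z_featuremap_kernel(u, v))
    m <- svm_fit(K, y_tr[sub_tr], C = C)
    Kte <- pairwise_gram(A2, A1, function(u, v) z_featuremap_kernel(u, v))
    list(pred = svm_predict(m, Kte), scores = svm_decision(m, Kte),
         y = y_te[sub_te])
  })
  add("ZZ Feature Map", function() {
    nf <- min(15L, ncol(Atr))
    A1 <- Atr[sub_tr, seq_len(nf), drop = FALSE]
    A2 <- Ate[sub_te, seq_len(nf), drop = FALSE]
    K <- pairwise_gram(A1, A1, function(u, v) zz_featuremap_kernel(u, v))
    m <- svm_fit(K, y_tr[sub_tr], C = C)
    Kte <- pairwise_gram(A2, A1, function(u, v) zz_featuremap_kernel(u, v))
    list(pred = svm_predict(m, Kte), scores = svm_decision(m, Kte),
         y = y_te[sub_te])
  })

  rows <- lapply(names(results), function(nm) {
    res <- results[[nm]]
    if (!is.na(res$failed)) {
      return(data.frame(model = nm, accuracy = NA, roc_auc = NA, f1 = NA,
                        precision = NA, recall_sensitivity = NA,
                        specificity = NA, n_test = NA, mcnemar_p = NA,
                        failed = res$failed, stringsAsFactors = FALSE))
    }
    r <- res$report
    p_mcn <- NA_real_
    if (mcnemar && nm != "Proposed" && !is.null(preds[["Proposed"]])) {
      y_ref <- truths[[nm]]
      n_ref <- length(y_ref)
      ref_pred <- preds[["Proposed"]][seq_len(n_ref)]
      dc <- discordant_counts(y_ref, ref_pred, preds[[nm]])
      p_mcn <- mcnemar_exact(dc["b"], dc["c"])
    }
    data.frame(model = nm, accuracy = r$accuracy, roc_auc = r$roc_auc,
               f1 = r$f1, precision = r$precision,
               recall_sensitivity = r$recall_sensitivity,
               specificity = r$specificity, n_test = r$n_test,
               mcnemar_p = p_mcn, failed = NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Comparison table in the standard column order
#'
#' One row per model with columns Accuracy, ROC/AUC, F1 Score, Precision,
#' Recall/Sensitivity, Specificity; missing metrics render as NA.
#'
#' @param reports data.frame from [benchmark_suite()] or a list of
#'   `eval_report`s named by model.
#' @return data.frame ready for printing / CSV export.
#' @export
report_table <- function(reports) {
  if (is.data.frame(reports)) {
    out <- reports[, c("model", "accuracy", "roc_auc", "f1", "precision",
                       "recall_sensitivity", "specificity")]
  } else {
    out <- do.call(rbind, lapply(names(reports), function(nm) {
      r <- reports[[nm]]
      data.frame(model = nm, accuracy = r$accuracy, roc_auc = r$roc_auc,
                 f1 = r$f1, precision = r$precision,
                 recall_sensitivity = r$recall_sensitivity,
                 specificity = r$specificity, stringsAsFactors = FALSE)
    }))
  }
  names(out) <- c("Model", "Accuracy", "ROC/AUC", "F1 Score", "Precision",
                  "Recall/Sensitivity", "Specificity")
  out
}
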