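#' Stratified k-fold partition
#'
#' Splits indices into `k` disjoint test folds preserving the class
#' proportions: within each class, indices are shuffled (deterministic
#' given `seed`) and dealt to folds whose per-class sizes differ by at
#' most one, so each fold's class proportion is within one observation
#' of the global proportion.
#'
#' @param labels Binary outcome vector (0/1).
#' @param k Number of folds (default 10).
#' @param seed Integer seed (default 42).
#' @return A list of `k` integer index vectors (the test sets).
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 42L) {
  labels <- as.integer(labels)
  k <- as.integer(k)
  cls <- sort(unique(labels))
  for (cl in cls)
    if (sum(labels == cl) < k)
      stop("class ", cl, " has fewer than k = ", k, " members")
  folds <- vector("list", k)
  offset <- 0L   # rotate the +1 folds across classes to even fold sizes
  with_local_seed(seed, function() {
    for (cl in cls) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      m <- length(idx)
      base <- m %/% k; extra <- m %% k
      sizes <- rep(base, k)
      if (extra > 0L)
        sizes[((offset + seq_len(extra) - 1L) %% k) + 1L] <- base + 1L
      offset <<- (offset + extra) %% k
      stops <- cumsum(sizes)
      starts <- c(1L, utils::head(stops, -1L) + 1L)
      for (f in seq_len(k))
        if (sizes[f] > 0L)
          folds[[f]] <<- c(folds[[f]], idx[starts[f]:stops[f]])
    }
  })
  lapply(folds, sort)
}

#' Area under the ROC curve (probability-of-correct-ranking form)
#'
#' Mann–Whitney statistic: the probability that a randomly chosen
#' positive outscores a randomly chosen negative, with ties counted 1/2.
#'
#' @param scores Numeric score vector (higher = more positive).
#' @param labels Binary outcome vector (0/1); both classes must occur.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metric panel
#'
#' Accuracy, sensitivity (recall), specificity, precision and AUC from
#' binary predictions, continuous scores and true outcomes.  A ratio
#' with zero denominator is reported as 0 and flagged in `undefined`.
#'
#' @param predictions Binary 0/1 predictions.
#' @param scores Continuous scores (for AUC).
#' @param labels Binary 0/1 outcomes.
#' @return Named list of the five metrics plus `undefined` (character
#'   vector of metrics whose denominator was zero).
#' @export
metric_panel <- function(predictions, scores, labels) {
  p <- as.integer(predictions); y <- as.integer(labels)
  tp <- sum(p == 1L & y == 1L); tn <- sum(p == 0L & y == 0L)
  fp <- sum(p == 1L & y == 0L); fn <- sum(p == 0L & y == 1L)
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); 0 } else num / den
  }
  list(auc = auc_score(scores, y),
       accuracy = (tp + tn) / length(y),
       sensitivity = ratio(tp, tp + fn, "sensitivity"),
       specificity = ratio(tn, tn + fp, "specificity"),
       precision = ratio(tp, tp + fp, "precision"),
       undefined = undefined)
}

#' Hyper-parameter grids for the classifiers
#'
#' `knn_grid()` enumerates `k` in \{1, 3, 5, 7, 9\} crossed with
#' Euclidean, Manhattan and Chebyshev distances (15 configs).
#' `svm_grid()` enumerates `C` in \{0.1, 1, 5, 10, 50, 100\} with linear,
#' RBF and polynomial kernels, `gamma` in \{1e-5, 1e-4, 1e-3, 1e-2, 0.1,
#' 1\} for rbf/poly and degree `d` in \{2..9\} for poly (330 configs).
#' Both accept restricted value sets for scaled-down runs.
#'
#' @param k,distances,C,kernels,gamma,degree Value sets to enumerate.
#' @return List of classifier config lists (each with a `$type`).
#' @export
knn_grid <- function(k = c(1, 3, 5, 7, 9),
                     distances = c("euclidean", "manhattan", "chebyshev")) {
  out <- list()
  for (d in distances) for (kk in k)
    out[[length(out) + 1L]] <- list(type = "knn", k = as.integer(kk),
                                    distance = d)
  out
}

#' @rdname knn_grid
#' @export
svm_grid <- function(C = c(0.1, 1, 5, 10, 50, 100),
                     kernels = c("linear", "rbf", "poly"),
                     gamma = c(1e-5, 1e-4, 1e-3, 1e-2, 0.1, 1),
                     degree = 2:9) {
  out <- list()
  for (cc in C) {
    if ("linear" %in% kernels)
      out[[length(out) + 1L]] <- list(type = "svm", C = cc,
                                      kernel = "linear", gamma = 1)
    if ("rbf" %in% kernels)
      for (g in gamma)
        out[[length(out) + 1L]] <- list(type = "svm", C = cc,
                                        kernel = "rbf", gamma = g)
    if ("poly" %in% kernels)
      for (g in gamma) for (d in degree)
        out[[length(out) + 1L]] <- list(type = "svm", C = cc,
                                        kernel = "poly", gamma = g,
                                        degree = as.integer(d))
  }
  out
}

#' Cross-validated evaluation of one classifier configuration
#'
#' Runs stratified k-fold cross-validation for a single classifier
#' config on a feature matrix.  In `mode = "reduced"` each training fold
#' is standardized and PCA-reduced (retaining `threshold`% of variance)
#' and the held-out fold is projected with that fold's fitted transforms
#' — test rows never influence the transforms.  In `mode = "whole"` the
#' features are used as-is.
#'
#' @param D Numeric `N x F` feature matrix.
#' @param y Binary outcome vector (0/1).
#' @param config Classifier config list (see [knn_grid()] / [svm_grid()]).
#' @param folds List of test-index vectors from [stratified_kfold()], or
#'   `NULL` to build them from `k` and `seed`.
#' @param mode `"whole"` or `"reduced"`.
#' @param threshold PCA retained-variance percentage (reduced mode).
#' @param k,seed Fold count and seed when `folds` is `NULL`.
#' @return List with per-metric `mean` and `sd` across folds and the
#'   per-fold metric table (`per_fold`) for audit.
#' @export
evaluate_config <- function(D, y, config, folds = NULL,
                            mode = c("whole", "reduced"), threshold = 95,
                            k = 10L, seed = 42L) {
  mode <- match.arg(mode)
  D <- as.matrix(D)
  y <- as.integer(y)
  if (is.null(folds)) folds <- stratified_kfold(y, k = k, seed = seed)
  metrics <- c("auc", "accuracy", "sensitivity", "specificity", "precision")
  per_fold <- matrix(NA_real_, length(folds), length(metrics),
                     dimnames = list(NULL, metrics))
  for (f in seq_along(folds)) {
    te <- folds[[f]]; tr <- setdiff(seq_len(nrow(D)), te)
    Xtr <- D[tr, , drop = FALSE]; Xte <- D[te, , drop = FALSE]
    if (mode == "reduced") {
      red <- reduce_features(Xtr, Xte, threshold)
      Xtr <- red$train; Xte <- red$test
    }
    model <- train_classifier(config, Xtr, y[tr])
    sc <- score_classifier(model, Xte)
    pr <- predict_classifier(model, Xte)
    m <- metric_panel(pr, sc, y[te])
    per_fold[f, ] <- unlist(m[metrics])
  }
  list(mean = colMeans(per_fold), sd = apply(per_fold, 2L, stats::sd),
       per_fold = per_fold, config = config, mode = mode)
}

#' Cross-validated grid search
#'
#' Evaluates every classifier configuration on the same stratified folds
#' and reports mean and standard deviation of AUC (and the companion
#' metric panel) per configuration.  The best configuration maximizes
#' mean AUC; ties are broken by smaller AUC standard deviation, then by
#' grid order.  This mirrors the common (optimistic) practice of
#' selecting hyper-parameters with the same cross-validation used for
#' reporting; see the methods vignette for the caveat.
#'
#' @inheritParams evaluate_config
#' @param configs List of classifier configs; default: the full KNN grid
#'   plus the full SVM grid.
#' @return An `evaluation_report`: `results` data frame (one row per
#'   config, columns `classifier`, `mean_auc`, `sd_auc`, further metric
#'   means/sds), `best` (row index), `folds`, and the per-config details.
#' @export
run_grid <- function(D, y, configs = c(knn_grid(), svm_grid()),
                     folds = NULL, mode = c("whole", "reduced"),
                     threshold = 95, k = 10L, seed = 42L) {
  mode <- match.arg(mode)
  y <- as.integer(y)
  if (is.null(folds)) folds <- stratified_kfold(y, k = k, seed = seed)
  details <- vector("list", length(configs))
  rows <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    ev <- evaluate_config(D, y, configs[[i]], folds = folds, mode = mode,
                          threshold = threshold)
    details[[i]] <- ev
    rows[[i]] <- data.frame(
      classifier = classifier_label(configs[[i]]),
      mean_auc = ev$mean[["auc"]], sd_auc = ev$sd[["auc"]],
      mean_accuracy = ev$mean[["accuracy"]],
      sd_accuracy = ev$sd[["accuracy"]],
      mean_sensitivity = ev$mean[["sensitivity"]],
      mean_specificity = ev$mean[["specificity"]],
      mean_precision = ev$mean[["precision"]],
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  ord <- order(-results$mean_auc, results$sd_auc, seq_len(nrow(results)))
  best <- ord[1L]
  structure(list(results = results, best = best, configs = configs,
                 details = details, folds = folds, mode = mode,
                 threshold = threshold),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  b <- x$results[x$best, ]
  cat(sprintf("grid search over %d configs (%s features): best %s, mean AUC %.2f +/- %.2f\n",
              nrow(x$results), x$mode, b$classifier, b$mean_auc, b$sd_auc))
  invisible(x)
}

#' End-to-end evaluation of one task on a manifest
#'
#' Extracts features for the requested descriptor and layer set, maps
#' labels through the task, and runs the classifier grid with stratified
#' k-fold cross-validation.
#'
#' @inheritParams extract_features
#' @inheritParams run_grid
#' @param task One of [octa_tasks()].
#' @return An `evaluation_report` (with the feature matrix attached as
#'   `$features`).
#' @export
evaluate_dataset <- function(manifest, task, descriptor = "lbp_riu2",
                             params = list(), layers = octa_layers(),
                             mode = c("whole", "reduced"),
                             configs = c(knn_grid(), svm_grid()),
                             threshold = 95, k = 10L, seed = 42L,
                             cache = NULL) {
  mode <- match.arg(mode)
  fm <- extract_features(manifest, descriptor, params, layers,
                         task = task, cache = cache)
  rep <- run_grid(fm$D, fm$outcome, configs = configs, mode = mode,
                  threshold = threshold, k = k, seed = seed)
  rep$features <- fm
  rep$task <- task
  rep
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output JSON path.
#' @export
report_to_json <- function(report, path) {
  b <- report$results[report$best, ]
  obj <- list(mode = report$mode,
              task = report$task %||% NA,
              best = list(classifier = b$classifier,
                          mean_auc = b$mean_auc, sd_auc = b$sd_auc),
              results = report$results)
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
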