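# Classifiers used by the evaluation grid.  Both return continuous
# scores for AUC: KNN the fraction of the k neighbours voting positive,
# SVM the signed decision value.

#' K-nearest-neighbour classifier
#'
#' Deterministic KNN with Euclidean, Manhattan or Chebyshev distance.
#' Neighbour ties at rank `k` are broken by smallest training-row index;
#' a 50/50 vote predicts the negative class.
#'
#' @param X Numeric `N x F` training matrix.
#' @param y Binary outcome vector (0/1) of length `N`.
#' @param k Number of neighbours.
#' @param distance One of `"euclidean"`, `"manhattan"`, `"chebyshev"`.
#' @return A `knn_model`.
#' @export
knn_fit <- function(X, y, k = 3L,
                    distance = c("euclidean", "manhattan", "chebyshev")) {
  distance <- match.arg(distance)
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  if (k < 1L || k > nrow(X)) stop("k must be in [1, N]")
  structure(list(X = X, y = as.integer(y), k = as.integer(k),
                 distance = distance),
            class = "knn_model")
}

knn_distances <- function(model, newx) {
  tr <- model$X
  switch(model$distance,
    euclidean = {
      d2 <- outer(rowSums(newx^2), rowSums(tr^2), "+") -
        2 * tcrossprod(newx, tr)
      sqrt(pmax(d2, 0))
    },
    manhattan = t(apply(newx, 1L, function(v)
      colSums(abs(t(tr) - v)))),
    chebyshev = t(apply(newx, 1L, function(v)
      apply(abs(sweep(tr, 2L, v)), 1L, max)))
  )
}

#' @rdname knn_fit
#' @param model A fitted `knn_model`.
#' @param newx Matrix of rows to score.
#' @return `knn_score` returns the fraction of the `k` nearest training
#'   rows labelled positive, per row of `newx`.
#' @export
knn_score <- function(model, newx) {
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1L)
  d <- knn_distances(model, as.matrix(newx))
  if (is.null(dim(d))) d <- matrix(d, nrow = nrow(newx))
  apply(d, 1L, function(di) {
    nb <- order(di, seq_along(di))[seq_len(model$k)]  # index tie-break
    mean(model$y[nb] == 1L)
  })
}

# --- Support vector machine (C-SVM) trained with a deterministic -------
# --- simplified SMO; small-N setting so the O(N^2) kernel matrix is fine.

kernel_matrix <- function(kernel, gamma, degree, A, B = A) {
  G <- tcrossprod(A, B)
  switch(kernel,
    linear = G,
    poly = (gamma * G)^degree,
    rbf = {
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * G
      exp(-gamma * pmax(d2, 0))
    },
    stop("unknown kernel: ", kernel))
}

#' Support vector machine classifier
#'
#' Binary C-SVM solved in the dual by a deterministic simplified SMO
#' (sequential minimal optimization) loop.  Kernels follow the common
#' scikit-learn parameterization: linear `x.y`, polynomial
#' `(gamma x.y)^d` and RBF `exp(-gamma ||x - y||^2)`.  Scores are signed
#' decision values; prediction thresholds at 0.
#'
#' @param X Numeric `N x F` training matrix.
#' @param y Binary outcome vector (0/1).
#' @param C Penalty parameter.
#' @param kernel `"linear"`, `"rbf"` or `"poly"`.
#' @param gamma Kernel coefficient for rbf/poly; default `1 / F`.
#' @param degree Polynomial degree (poly kernel only).
#' @param tol KKT violation tolerance.
#' @param max_sweeps Hard cap on full passes over the training set.
#' @return An `svm_model`.
#' @export
svm_fit <- function(X, y, C = 1, kernel = c("linear", "rbf", "poly"),
                    gamma = NULL, degree = 3L, tol = 1e-3,
                    max_sweeps = 200L) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n != length(y)) stop("X rows and y length differ")
  ys <- ifelse(as.integer(y) == 1L, 1, -1)
  if (length(unique(ys)) < 2L) stop("SVM needs both classes in training data")
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  K <- kernel_matrix(kernel, gamma, degree, X)

  alpha <- numeric(n)
  b <- 0
  errors <- function() as.vector(K %*% (alpha * ys)) + b - ys
  # jointly optimize the pair (i, j); returns TRUE on progress
  take_step <- function(i, j, Ei, Ej) {
    ai_old <- alpha[i]; aj_old <- alpha[j]
    if (ys[i] != ys[j]) {
      L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
    } else {
      L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
    }
    if (H - L < 1e-12) return(FALSE)
    eta <- 2 * K[i, j] - K[i, i] - K[j, j]
    if (eta >= -1e-12) return(FALSE)
    aj <- aj_old - ys[j] * (Ei - Ej) / eta
    aj <- min(max(aj, L), H)
    if (abs(aj - aj_old) < 1e-8 * (aj + aj_old + 1e-8)) return(FALSE)
    ai <- ai_old + ys[i] * ys[j] * (aj_old - aj)
    alpha[i] <<- ai; alpha[j] <<- aj
    b1 <- b - Ei - ys[i] * (ai - ai_old) * K[i, i] -
      ys[j] * (aj - aj_old) * K[i, j]
    b2 <- b - Ej - ys[i] * (ai - ai_old) * K[i, j] -
      ys[j] * (aj - aj_old) * K[j, j]
    b <<- if (ai > 0 && ai < C) b1
    else if (aj > 0 && aj < C) b2
    else (b1 + b2) / 2
    TRUE
  }
  for (sweep in seq_len(max_sweeps)) {
    changed <- 0L
    for (i in seq_len(n)) {
      E <- errors()
      Ei <- E[i]
      if (!((ys[i] * Ei < -tol && alpha[i] < C) ||
            (ys[i] * Ei > tol && alpha[i] > 0))) next
      # deterministic partner search: best |Ei - Ej| first, then the
      # remaining candidates in that order until one makes progress
      js <- setdiff(order(-abs(Ei - E), seq_len(n)), i)
      for (j in js)
        if (take_step(i, j, Ei, E[j])) { changed <- changed + 1L; break }
    }
    if (changed == 0L) break
  }
  sv <- alpha > 1e-8
  structure(list(X = X[sv, , drop = FALSE], coef = (alpha * ys)[sv],
                 b = b, kernel = kernel, gamma = gamma,
                 degree = as.integer(degree), C = C,
                 n_sv = sum(sv)),
            class = "svm_model")
}

#' @rdname svm_fit
#' @param model A fitted `svm_model`.
#' @param newx Matrix of rows to score.
#' @return `svm_score` returns signed decision values.
#' @export
svm_score <- function(model, newx) {
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1L)
  if (model$n_sv == 0L) return(rep(model$b, nrow(newx)))
  K <- kernel_matrix(model$kernel, model$gamma, model$degree,
                     as.matrix(newx), model$X)
  as.vector(K %*% model$coef) + model$b
}

# Uniform interface used by the evaluation grid: a classifier config is a
# list with $type ("knn"/"svm") and its hyper-parameters.
train_classifier <- function(config, X, y) {
  if (config$type == "knn")
    knn_fit(X, y, k = config$k, distance = config$distance)
  else
    svm_fit(X, y, C = config$C, kernel = config$kernel,
            gamma = config$gamma %||% (1 / ncol(as.matrix(X))),
            degree = config$degree %||% 3L)
}

score_classifier <- function(model, newx) {
  if (inherits(model, "knn_model")) knn_score(model, newx)
  else svm_score(model, newx)
}

predict_classifier <- function(model, newx) {
  s <- score_classifier(model, newx)
  if (inherits(model, "knn_model")) as.integer(s > 0.5)  # vote tie -> 0
  else as.integer(s > 0)
}

classifier_label <- function(config) {
  if (config$type == "knn")
    sprintf("KNN(k=%d,%s)", config$k, config$distance)
  else if (config$kernel == "linear")
    sprintf("SVM(linear,C=%g)", config$C)
  else if (config$kernel == "rbf")
    sprintf("SVM(rbf,C=%g,gamma=%g)", config$C, config$gamma)
  else
    sprintf("SVM(poly,C=%g,gamma=%g,d=%d)", config$C, config$gamma,
            config$degree)
}
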