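#' Column standardization (centring and scaling)
#'
#' Fits per-column means and standard deviations of a feature matrix and
#' applies the transform `(x - mu) / sigma`.  The standard deviation uses
#' the population form (divisor `N`).  Columns with zero variance are
#' mapped to all-zeros rather than dropped, so the feature count stays
#' stable across cross-validation folds; their indices are flagged.
#'
#' @param D Numeric `N x F` matrix, `N >= 2`.
#' @return An object of class `standardizer` with `mu`, `sigma` and
#'   `constant` (logical flag per column).
#' @export
fit_standardizer <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 2L) stop("standardization needs N >= 2 rows")
  if (!all(is.finite(D))) stop("non-finite entries in feature matrix")
  mu <- colMeans(D)
  sigma <- sqrt(colMeans(sweep(D, 2L, mu)^2))   # population divisor N
  structure(list(mu = mu, sigma = sigma, constant = sigma == 0),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param std A fitted `standardizer`.
#' @param X Matrix (or vector treated as one row) with `F` columns.
#' @export
apply_standardizer <- function(std, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != length(std$mu)) stop("column count mismatch")
  s <- ifelse(std$constant, 1, std$sigma)   # constant columns -> zeros
  out <- sweep(sweep(X, 2L, std$mu), 2L, s, "/")
  out[, std$constant] <- 0
  out
}

#' Principal component analysis of standardized features
#'
#' Eigendecomposition of the covariance matrix `t(SD) %*% SD / (N - 1)`
#' of the standardized data.  The retained dimension `K` is the smallest
#' number of leading components whose cumulative explained-variance
#' percentage reaches the retention threshold (default 95).  For
#' `F > N` the eigenpairs are obtained through the SVD of `SD`
#' (`lambda_j = s_j^2 / (N - 1)`), which is algebraically identical and
#' avoids forming a large `F x F` matrix.  Each eigenvector's sign is
#' fixed so its largest-magnitude entry is positive.
#'
#' @param SD Standardized `N x F` matrix (see [fit_standardizer()]).
#' @param threshold Retained-variance percentage in (0, 100\], default 95.
#' @return An object of class `pca_model`: `eigenvalues` (descending,
#'   length `min(N, F)`; trailing structural zeros of the rank-deficient
#'   case are included up to that length), `rotation` (`F x K` matrix of
#'   retained eigenvectors), `K`, `total_variance`, `pv` (percent
#'   explained per component) and `threshold`.
#' @export
fit_pca <- function(SD, threshold = 95) {
  SD <- as.matrix(SD)
  if (!all(is.finite(SD))) stop("non-finite entries in standardized data")
  n <- nrow(SD); f <- ncol(SD)
  if (n < 2L) stop("PCA needs N >= 2 rows")
  if (threshold <= 0 || threshold > 100) stop("threshold must be in (0, 100]")
  k_max <- min(n, f)
  sv <- svd(SD, nu = 0L, nv = k_max)
  lambda <- sv$d[seq_len(k_max)]^2 / (n - 1)
  tv <- sum(lambda)      # equals trace of the F x F covariance matrix
  if (tv <= 0) stop("total variance is zero; PCA undefined")
  pv <- 100 * lambda / tv
  K <- pca_select_k(pv, threshold)
  phi <- sv$v[, seq_len(K), drop = FALSE]
  # sign convention: largest-magnitude entry of each eigenvector positive
  for (j in seq_len(K)) {
    i <- which.max(abs(phi[, j]))
    if (phi[i, j] < 0) phi[, j] <- -phi[, j]
  }
  structure(list(eigenvalues = lambda, rotation = phi, K = K,
                 total_variance = tv, pv = pv, threshold = threshold),
            class = "pca_model")
}

# Smallest K whose cumulative explained-variance percentage reaches the
# threshold (pv assumed sorted by descending eigenvalue).
pca_select_k <- function(pv, threshold = 95) {
  cs <- cumsum(pv)
  K <- which(cs >= threshold - 1e-9)[1L]
  if (is.na(K)) length(pv) else K
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf(
    "PCA: K = %d of %d components retained (%.2f%% of variance, threshold %g%%)\n",
    x$K, length(x$eigenvalues), sum(x$pv[seq_len(x$K)]), x$threshold))
  invisible(x)
}

#' Project standardized rows onto the retained principal components
#'
#' @param SD_rows Matrix (or single row vector) with `F` columns, already
#'   standardized with the training-fold parameters.
#' @param model A fitted [fit_pca()] model.
#' @return `N x K` matrix of reduced feature vectors.
#' @export
project_pca <- function(SD_rows, model) {
  if (is.null(dim(SD_rows))) SD_rows <- matrix(SD_rows, nrow = 1L)
  if (ncol(SD_rows) != nrow(model$rotation))
    stop("feature length mismatch with PCA model")
  SD_rows %*% model$rotation
}

#' One-call train/test feature reduction
#'
#' Fits the standardizer and PCA on the training rows only and applies
#' both to the training and test rows — the leakage-free contract used
#' inside each cross-validation fold.
#'
#' @param train,test Numeric matrices with identical column counts.
#' @param threshold Retained-variance percentage (default 95).
#' @return List with reduced `train`, `test`, and the fitted
#'   `standardizer` and `pca` objects.
#' @export
reduce_features <- function(train, test = NULL, threshold = 95) {
  std <- fit_standardizer(train)
  sd_tr <- apply_standardizer(std, train)
  pca <- fit_pca(sd_tr, threshold)
  out <- list(train = project_pca(sd_tr, pca), standardizer = std,
              pca = pca)
  if (!is.null(test))
    out$test <- project_pca(apply_standardizer(std, test), pca)
  out
}

#' Serialize a PCA model (with its standardizer) to JSON
#'
#' @param model A `pca_model`.
#' @param std Optional `standardizer` fitted on the same data.
#' @param path Output JSON path.
#' @export
pca_to_json <- function(model, path, std = NULL) {
  obj <- list(eigenvalues = model$eigenvalues, K = model$K,
              total_variance = model$total_variance, pv = model$pv,
              threshold = model$threshold, rotation = model$rotation)
  if (!is.null(std)) obj$standardizer <- list(mu = std$mu, sigma = std$sigma)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
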