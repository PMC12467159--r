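#' BRIEF sampling pattern
#'
#' Draws the `n` random pixel-pair test locations used by the BRIEF
#' descriptor inside an `S x S` patch.  Coordinates are sampled i.i.d.
#' uniformly over the patch grid (so tests reach the patch border with
#' equal probability everywhere); a pair whose two locations coincide is
#' redrawn.  One pattern is created per run and shared across every image
#' and patch, which keeps the histogram bins commensurable across images.
#'
#' @param S Patch side length in pixels (>= 2); the descriptor grid uses
#'   `S` in \{4, 5, 6, 7\}.
#' @param n Number of pixel pairs (>= 1); grid values \{4, 8, 12, 16\}.
#' @param seed Integer seed making the pattern reproducible.
#' @return An object of class `brief_config` with zero-based coordinate
#'   matrices `X` and `Y` (`n x 2`, columns row/col within the patch).
#' @export
brief_config <- function(S = 5L, n = 8L, seed = 42L) {
  S <- as.integer(S); n <- as.integer(n)
  if (is.na(S) || S < 2L) stop("S must be an integer >= 2")
  if (is.na(n) || n < 1L) stop("n must be an integer >= 1")
  if (n > 24L) stop("n > 24 unsupported (2^n histogram too large)")
  pts <- with_local_seed(seed, function() {
    X <- matrix(0L, n, 2L); Y <- matrix(0L, n, 2L)
    for (i in seq_len(n)) {
      repeat {
        xi <- sample.int(S, 2L, replace = TRUE) - 1L
        yi <- sample.int(S, 2L, replace = TRUE) - 1L
        if (!identical(xi, yi)) break
      }
      X[i, ] <- xi; Y[i, ] <- yi
    }
    list(X = X, Y = Y)
  })
  structure(list(S = S, n = n, seed = as.integer(seed),
                 X = pts$X, Y = pts$Y),
            class = "brief_config")
}

#' @export
print.brief_config <- function(x, ...) {
  cat(sprintf("BRIEF pattern: S = %d, n = %d, seed = %d\n", x$S, x$n,
              x$seed))
  invisible(x)
}

#' Serialize / restore a BRIEF sampling pattern as JSON
#'
#' @param config A [brief_config()].
#' @param path JSON file path.
#' @return `brief_config_from_json` returns the restored `brief_config`.
#' @export
brief_config_to_json <- function(config, path) {
  jsonlite::write_json(list(S = config$S, n = config$n, seed = config$seed,
                            X = config$X, Y = config$Y),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname brief_config_to_json
#' @export
brief_config_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- brief_config(j$S, j$n, j$seed)
  cfg$X <- matrix(as.integer(j$X), ncol = 2L)
  cfg$Y <- matrix(as.integer(j$Y), ncol = 2L)
  cfg
}

# Separable Gaussian blur with edge replication; kernel truncated at
# `radius` = 4 * sigma by default.
gaussian_blur <- function(img, sigma = 1, radius = ceiling(4 * sigma)) {
  k <- stats::dnorm(seq(-radius, radius), sd = sigma)
  k <- k / sum(k)
  blur1d <- function(m) {
    # pad rows by replication, convolve columns of the padded matrix
    top <- m[rep(1L, radius), , drop = FALSE]
    bot <- m[rep(nrow(m), radius), , drop = FALSE]
    pm <- rbind(top, m, bot)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k))
      out <- out + k[i] * pm[i:(i + nrow(m) - 1L), , drop = FALSE]
    out
  }
  t(blur1d(t(blur1d(img))))
}

#' Noise-adaptive BRIEF threshold from the image itself
#'
#' Estimates the image noise standard deviation sigma as the standard
#' deviation of the residual between the image and a Gaussian-blurred
#' copy of it (the residual contains mostly the noise signal), and sets
#' the binary-test threshold to `3 * sigma`.  On 8-bit OCTA-like speckle
#' this lands in the mid-single-digit grey range.
#'
#' @param image Numeric grey matrix.
#' @param blur_sigma Standard deviation of the Gaussian blur (grey-level
#'   smoothing scale, default 1 pixel; kernel truncated at 4 sigma).
#' @return A list with `sigma` and `threshold = 3 * sigma`.
#' @export
estimate_noise_sigma <- function(image, blur_sigma = 1) {
  validate_pixels(image)
  res <- image - gaussian_blur(image, sigma = blur_sigma)
  s <- stats::sd(as.vector(res))
  list(sigma = s, threshold = 3 * s)
}

#' BRIEF code of one patch
#'
#' Bit `i - 1` is set iff `P(X_i) - P(Y_i) > threshold` (strict), and the
#' bits are summed with weights `2^(i-1)`.
#'
#' @param patch `S x S` numeric matrix.
#' @param config A [brief_config()].
#' @param threshold Binary-test threshold (grey levels).
#' @return Integer code in `[0, 2^n - 1]`.
#' @export
brief_code <- function(patch, config, threshold) {
  if (!all(dim(patch) == config$S)) stop("patch must be S x S")
  px <- patch[config$X + 1L]   # zero-based (row, col) -> matrix index
  py <- patch[config$Y + 1L]
  sum(as.integer(px - py > threshold) * 2^(seq_len(config$n) - 1L))
}

#' Dense BRIEF code map and histogram of an image
#'
#' Extracts an `S x S` patch at every pixel whose patch fits entirely in
#' the image.  The patch is anchored so that the coded pixel sits at the
#' zero-based offset `floor((S - 1) / 2)` from the patch top-left corner.
#' Unless supplied, the threshold is estimated per image via
#' [estimate_noise_sigma()].
#'
#' @param image Numeric grey matrix (each side > `S`).
#' @param config A [brief_config()].
#' @param threshold Optional fixed threshold; default: 3 sigma estimated
#'   from the image.
#' @return An object of class `brief_code_image` with the integer code
#'   matrix, config, threshold and sigma used.
#' @export
dense_brief_map <- function(image, config, threshold = NULL) {
  validate_pixels(image)
  S <- config$S
  if (nrow(image) < S || ncol(image) < S)
    stop("image smaller than patch size S = ", S)
  sigma <- NA_real_
  if (is.null(threshold)) {
    ns <- estimate_noise_sigma(image)
    sigma <- ns$sigma
    threshold <- ns$threshold
  }
  a <- (S - 1L) %/% 2L           # anchor offset inside the patch
  ri <- (a + 1L):(nrow(image) - (S - 1L - a))  # valid anchor rows
  ci <- (a + 1L):(ncol(image) - (S - 1L - a))
  codes <- matrix(0, length(ri), length(ci))
  for (i in seq_len(config$n)) {
    dxr <- config$X[i, 1L] - a; dxc <- config$X[i, 2L] - a
    dyr <- config$Y[i, 1L] - a; dyc <- config$Y[i, 2L] - a
    d <- image[ri + dxr, ci + dxc, drop = FALSE] -
      image[ri + dyr, ci + dyc, drop = FALSE]
    codes <- codes + (d > threshold) * 2^(i - 1L)
  }
  structure(list(codes = matrix(as.integer(round(codes)),
                                length(ri), length(ci)),
                 config = config, threshold = threshold, sigma = sigma),
            class = c("brief_code_image"))
}

#' @export
print.brief_code_image <- function(x, ...) {
  cat(sprintf("BRIEF code map %d x %d (S = %d, n = %d, threshold = %.3g)\n",
              nrow(x$codes), ncol(x$codes), x$config$S, x$config$n,
              x$threshold))
  invisible(x)
}
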