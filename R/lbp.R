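#' Circular neighbourhood configuration for LBP coding
#'
#' Defines the evenly spaced circularly symmetric neighbourhood used by
#' the LBP family: `p` sampling pixels on a circle of radius `r` around
#' each centre pixel.  The first sample `g0` sits exactly one radius to
#' the right of the centre and subsequent samples follow the offsets
#' `(-r sin(2 pi n / p), r cos(2 pi n / p))` (row, column) for
#' `n = 0 .. p - 1`.  Off-grid samples are bilinearly interpolated.
#'
#' @param p Number of sampling pixels (> 1).  The descriptor grids use
#'   `p` in \{4, 8, 12, 16\}.
#' @param r Radius in pixels (> 0); grids use `r` in \{1, 2, 3, 4\}.
#' @return An object of class `lbp_config`.
#' @export
lbp_config <- function(p = 8L, r = 1) {
  p <- as.integer(p)
  if (is.na(p) || p <= 1L) stop("p must be an integer > 1")
  if (p > 24L) stop("p > 24 unsupported (2^p code space too large)")
  if (!is.finite(r) || r <= 0) stop("r must be > 0")
  structure(list(p = p, r = as.numeric(r)), class = "lbp_config")
}

#' @export
print.lbp_config <- function(x, ...) {
  cat(sprintf("LBP circular neighbourhood: p = %d, r = %g\n", x$p, x$r))
  invisible(x)
}

# Row/column offsets of the p samples relative to the centre.  Offsets
# within 1e-9 of an integer are snapped so that axis-aligned samples hit
# grid pixels exactly and bypass interpolation.
lbp_offsets <- function(config) {
  n <- seq_len(config$p) - 1L
  ang <- 2 * pi * n / config$p
  dr <- -config$r * sin(ang)
  dc <- config$r * cos(ang)
  snap <- function(x) ifelse(abs(x - round(x)) < 1e-9, round(x), x)
  cbind(drow = snap(dr), dcol = snap(dc))
}

# Bilinear interpolation of `img` at fractional (row, col) positions.
bilinear_at <- function(img, row, col) {
  h <- nrow(img); w <- ncol(img)
  if (any(row < 1 | row > h | col < 1 | col > w))
    stop("sample position outside image")
  r0 <- pmin(floor(row), h - 1L); c0 <- pmin(floor(col), w - 1L)
  fr <- row - r0; fc <- col - c0
  i00 <- cbind(r0, c0); i01 <- cbind(r0, c0 + 1)
  i10 <- cbind(r0 + 1, c0); i11 <- cbind(r0 + 1, c0 + 1)
  (1 - fr) * (1 - fc) * img[i00] + (1 - fr) * fc * img[i01] +
    fr * (1 - fc) * img[i10] + fr * fc * img[i11]
}

#' Sample the circular neighbourhood around one centre pixel
#'
#' @param image Numeric grey matrix.
#' @param centre Integer vector `c(row, col)` (1-based).
#' @param config An [lbp_config()].
#' @return Numeric vector of the `p` neighbour grey values `g0 .. g(p-1)`.
#' @export
sample_neighbourhood <- function(image, centre, config) {
  m <- ceiling(config$r)
  if (centre[1] <= m || centre[1] > nrow(image) - m ||
      centre[2] <= m || centre[2] > ncol(image) - m)
    stop("centre closer than ceiling(r) to the image border")
  off <- lbp_offsets(config)
  bilinear_at(image, centre[1] + off[, "drow"], centre[2] + off[, "dcol"])
}

#' Elementary LBP code of one neighbourhood
#'
#' Thresholds the neighbour-minus-centre differences at zero (a tie
#' `gn == gc` yields bit 1) and sums the bits weighted by `2^n`.
#'
#' @param gc Centre grey level (scalar).
#' @param g Numeric vector of `p` neighbour grey levels.
#' @return Integer code in `[0, 2^p - 1]`.
#' @export
lbp_code <- function(gc, g) {
  # ties count as >= 0; the tolerance keeps bilinearly interpolated
  # values that are mathematically equal to gc from flipping the bit
  # through float round-off
  sum(as.integer(g - gc >= -1e-9) * 2^(seq_along(g) - 1L))
}

#' Minimal circular right rotation of an LBP code
#'
#' Canonicalizes a `p`-bit code to the minimum decimal value over all `p`
#' circular bit-wise right rotations (the rotation-invariant mapping).
#'
#' @param code Integer (vector) in `[0, 2^p - 1]`.
#' @param p Number of bits.
#' @return A list with `min_code`, the minimal rotation(s), and `steps`,
#'   the smallest rotation count achieving it.
#' @export
ror_min <- function(code, p) {
  stopifnot(all(code >= 0), all(code < 2^p))
  code <- as.integer(code)
  mask <- as.integer(2^p - 1)
  best <- code
  steps <- integer(length(code))
  rot <- code
  for (n in seq_len(p - 1L)) {
    # one circular right shift
    rot <- bitwOr(bitwShiftR(rot, 1L), bitwShiftL(bitwAnd(rot, 1L), p - 1L))
    upd <- rot < best
    best[upd] <- rot[upd]
    steps[upd] <- n
  }
  list(min_code = best, steps = steps)
}

# Little-endian bit matrix of codes: column n+1 holds bit n (= s(gn - gc)).
code_bits <- function(code, p) {
  outer(as.integer(code), 2^(seq_len(p) - 1L),
        function(x, w) bitwAnd(x %/% w, 1L))
}

#' Uniformity measure of an LBP code
#'
#' Counts the circular 0/1 transitions in the `p`-bit pattern; the circle
#' is closed by comparing the last bit with the first.
#'
#' @inheritParams ror_min
#' @return Integer transition count(s).
#' @export
uniformity <- function(code, p) {
  b <- code_bits(code, p)
  abs(b[, p] - b[, 1L]) +
    rowSums(abs(b[, -1L, drop = FALSE] - b[, -p, drop = FALSE]))
}

#' Rotation-invariant uniform (riu2) label of an LBP code
#'
#' Codes with uniformity at most 2 are labelled by their number of 1 bits
#' (0 to `p`); all other codes share the single non-uniform label `p + 1`,
#' giving `p + 2` possible output labels.
#'
#' @inheritParams ror_min
#' @return Integer label(s) in `[0, p + 1]`.
#' @export
riu2_code <- function(code, p) {
  b <- code_bits(code, p)
  u <- abs(b[, p] - b[, 1L]) +
    rowSums(abs(b[, -1L, drop = FALSE] - b[, -p, drop = FALSE]))
  ifelse(u <= 2L, rowSums(b), p + 1L)
}

# riu2 lookup table over the full code space 0 .. 2^p - 1.
riu2_lut <- function(p) riu2_code(0:(2^p - 1), p)

#' Dense LBP / riu2 code map of an image
#'
#' Applies the descriptor to every interior pixel.  A margin of
#' `ceiling(r)` pixels is excluded on every side so that no neighbourhood
#' reaches outside the image (no padding is fabricated).
#'
#' @param pixels Numeric grey matrix.
#' @param config An [lbp_config()].
#' @param variant `"generic"` (codes `0 .. 2^p - 1`) or `"riu2"` (labels
#'   `0 .. p + 1`).
#' @return An object of class `lbp_code_image` holding the integer code
#'   matrix (`(H - 2m) x (W - 2m)`), the variant and the config.
#' @export
dense_code_map <- function(pixels, config, variant = c("riu2", "generic")) {
  variant <- match.arg(variant)
  validate_pixels(pixels)
  m <- as.integer(ceiling(config$r))
  h <- nrow(pixels); w <- ncol(pixels)
  if (h < 2L * m + 2L || w < 2L * m + 2L)
    stop("image too small for radius r = ", config$r)
  ri <- (m + 1L):(h - m)   # interior centre rows
  ci <- (m + 1L):(w - m)
  gc <- pixels[ri, ci, drop = FALSE]
  off <- lbp_offsets(config)
  codes <- matrix(0, length(ri), length(ci))
  for (n in seq_len(config$p)) {
    dr <- off[n, 1L]; dc <- off[n, 2L]
    r0 <- floor(dr); c0 <- floor(dc)
    fr <- dr - r0; fc <- dc - c0
    sub <- function(a, b) pixels[ri + a, ci + b, drop = FALSE]
    gn <- if (fr == 0 && fc == 0) sub(r0, c0)
    else (1 - fr) * (1 - fc) * sub(r0, c0) +
      (1 - fr) * fc * sub(r0, c0 + 1) +
      fr * (1 - fc) * sub(r0 + 1, c0) +
      fr * fc * sub(r0 + 1, c0 + 1)
    codes <- codes + (gn - gc >= -1e-9) * 2^(n - 1L)  # ties -> bit 1
  }
  codes <- matrix(as.integer(round(codes)), length(ri), length(ci))
  if (variant == "riu2") {
    lut <- riu2_lut(config$p)
    codes <- matrix(lut[codes + 1L], nrow(codes), ncol(codes))
  }
  structure(list(codes = codes, variant = variant, config = config),
            class = "lbp_code_image")
}

#' @export
print.lbp_code_image <- function(x, ...) {
  cat(sprintf("%s LBP code map %d x %d (p = %d, r = %g)\n", x$variant,
              nrow(x$codes), ncol(x$codes), x$config$p, x$config$r))
  invisible(x)
}

n_bins <- function(code_image) {
  if (inherits(code_image, "brief_code_image"))
    return(2L^code_image$config$n)
  switch(code_image$variant,
         generic = 2L^code_image$config$p,
         riu2 = code_image$config$p + 2L)
}

#' Histogram feature vector of a code map
#'
#' Bin `i` (zero-based) counts the occurrences of code `i` over the coded
#' pixels.  Normalized histograms hold relative frequencies summing to 1;
#' unnormalized ones sum to the number of coded pixels.
#'
#' @param code_image An `lbp_code_image` or `brief_code_image`.
#' @param normalize Return relative frequencies (default `TRUE`).
#' @return An object of class `texture_histogram`: numeric `bins` of
#'   length `2^p` (generic), `p + 2` (riu2) or `2^n` (BRIEF), with the
#'   descriptor tag and normalization flag.
#' @export
lbp_histogram <- function(code_image, normalize = TRUE) {
  nb <- n_bins(code_image)
  codes <- as.vector(code_image$codes)
  if (any(codes < 0L | codes >= nb)) stop("code out of range for variant")
  bins <- tabulate(codes + 1L, nbins = nb)
  bins <- if (normalize) bins / length(codes) else as.numeric(bins)
  tag <- if (inherits(code_image, "brief_code_image")) "brief"
  else if (code_image$variant == "riu2") "lbp_riu2" else "lbp"
  structure(list(bins = bins, descriptor = tag, normalized = normalize),
            class = "texture_histogram")
}

#' @export
print.texture_histogram <- function(x, ...) {
  cat(sprintf("%s histogram, %d bins (%s)\n", x$descriptor, length(x$bins),
              if (x$normalized) "relative frequencies" else "counts"))
  invisible(x)
}
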