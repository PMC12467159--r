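#' Read a greyscale image into a numeric matrix
#'
#' Reads a 2-D greyscale image on the 8-bit scale (0–255).  Native support
#' covers portable greymaps (PGM, both ASCII `P2` and binary `P5`) and
#' plain CSV matrices; PNG files are read when the optional \pkg{png}
#' package is installed.  Multi-channel (RGB) inputs are converted to
#' luminance with the ITU-R BT.601 weights (0.299, 0.587, 0.114).
#'
#' @param path Path to a `.pgm`, `.csv` or `.png` file.
#' @return A numeric matrix of grey levels (rows x columns), values on the
#'   0–255 scale.
#' @examples
#' f <- tempfile(fileext = ".pgm")
#' write_pgm(matrix(c(0, 255, 10, 20), 2, 2, byrow = TRUE), f)
#' read_image(f)
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    pgm = read_pgm(path),
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    png = read_png_grey(path),
    stop("unsupported image format '.", ext, "' (use pgm, csv or png)")
  )
  storage.mode(px) <- "double"
  dimnames(px) <- NULL
  validate_pixels(px)
  px
}

validate_pixels <- function(px) {
  if (!is.matrix(px) || nrow(px) < 2L || ncol(px) < 2L)
    stop("image must be a 2-D matrix with at least 2 rows and 2 columns")
  if (!all(is.finite(px)) || any(px < 0))
    stop("grey levels must be finite and non-negative")
  invisible(px)
}

read_png_grey <- function(path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("reading PNG requires the 'png' package; use PGM or CSV instead")
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    # drop alpha if present, then BT.601 luminance
    if (dim(a)[3] >= 3L)
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    else a <- a[, , 1]
  }
  round(a * 255)
}

#' Read and write portable greymap (PGM) images
#'
#' Minimal codecs for the plain-text `P2` and binary `P5` portable greymap
#' formats, the package's native on-disk image representation.  Only
#' 8-bit (maxval <= 255) images are supported.
#'
#' @param path File path.
#' @param pixels Numeric matrix of grey levels in \[0, 255\]; values are
#'   rounded to integers on write.
#' @param ascii Write the plain `P2` variant (default) rather than binary
#'   `P5`.
#' @return `read_pgm` returns a numeric matrix; `write_pgm` returns `path`
#'   invisibly.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) stop("not a PGM file (P2/P5): ", path)
  toks <- character(0)
  buf <- character(0)
  # token scanner that honours '#' comments and arbitrary whitespace
  next_token <- function() {
    tok <- ""
    repeat {
      ch <- rawToChar(readBin(con, "raw", 1L))
      if (length(ch) == 0L || ch == "") {
        if (nzchar(tok)) return(tok) else stop("truncated PGM header")
      }
      if (ch == "#") {
        repeat {
          ch <- rawToChar(readBin(con, "raw", 1L))
          if (ch %in% c("\n", "\r") || ch == "") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok)
      } else tok <- paste0(tok, ch)
    }
  }
  w <- as.integer(next_token())
  h <- as.integer(next_token())
  maxv <- as.integer(next_token())
  if (is.na(w) || is.na(h) || is.na(maxv)) stop("malformed PGM header")
  if (maxv > 255L) stop("only 8-bit PGM supported (maxval <= 255)")
  n <- w * h
  if (magic == "P5") {
    vals <- as.numeric(readBin(con, "raw", n))
    if (length(vals) < n) stop("truncated PGM pixel data")
  } else {
    txt <- readChar(con, file.size(path), useBytes = TRUE)
    txt <- gsub("#[^\n]*", " ", txt)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(txt),
                                                 "[[:space:]]+")[[1]]))
    if (length(vals) < n || anyNA(vals[seq_len(n)]))
      stop("truncated PGM pixel data")
    vals <- vals[seq_len(n)]
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname read_pgm
#' @export
write_pgm <- function(pixels, path, ascii = TRUE) {
  validate_pixels(pixels)
  v <- as.integer(round(pmin(pmax(pixels, 0), 255)))
  m <- matrix(v, nrow(pixels), ncol(pixels))
  if (ascii) {
    con <- file(path, "wb")  # binary mode: LF line endings on any platform
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(m), nrow(m)), "255"), con)
    writeLines(apply(m, 1L, paste, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(m), nrow(m)), con,
              eos = NULL)
    writeBin(as.raw(as.vector(t(m))), con)
  }
  invisible(path)
}
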