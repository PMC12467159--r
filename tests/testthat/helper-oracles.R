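# Independent brute-force oracles, kept deliberately naive and separate
# from the implementation paths they check.

# p-bit little-endian bit vector of a code (bit n = s(g_n - g_c)).
oracle_bits <- function(code, p) {
  vapply(0:(p - 1), function(n) (code %/% 2^n) %% 2, numeric(1))
}

# all p circular right rotations of a code, as decimal values
oracle_rotations <- function(code, p) {
  b <- oracle_bits(code, p)
  vapply(0:(p - 1), function(n) {
    rb <- b[((seq_len(p) - 1 + n) %% p) + 1]  # right-rotate by n
    sum(rb * 2^(0:(p - 1)))
  }, numeric(1))
}

# circular 0/1 transition count by explicit string walk
oracle_uniformity <- function(code, p) {
  b <- oracle_bits(code, p)
  sum(abs(diff(c(b, b[1]))))
}

# riu2 label from first principles
oracle_riu2 <- function(code, p) {
  if (oracle_uniformity(code, p) <= 2) sum(oracle_bits(code, p))
  else p + 1
}

# AUC by exhaustive positive/negative pair counting (ties = 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (sp in pos) for (sn in neg)
    tot <- tot + if (sp > sn) 1 else if (sp == sn) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# 4-point bilinear interpolation written out long-hand
oracle_bilinear <- function(img, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  dr <- r - r0; dc <- c - c0
  img[r0, c0] * (1 - dr) * (1 - dc) +
    img[r0, c0 + 1] * (1 - dr) * dc +
    img[r0 + 1, c0] * dr * (1 - dc) +
    img[r0 + 1, c0 + 1] * dr * dc
}

# two Gaussian clusters with a controllable gap (0/1 labelled)
sep_data <- function(n = 20, gap = 3, seed = 1, f = 5) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * f), n), matrix(rnorm(n * f, gap), n))
  list(X = X, y = rep(c(0L, 1L), each = n))
}

# deterministic seeded test image
toy_image <- function(n = 16, seed = 7, lo = 0, hi = 255) {
  set.seed(seed)
  matrix(round(runif(n * n, lo, hi)), n, n)
}

# tiny on-disk dataset: k eyes per class, PGM images + manifest
make_tiny_dataset <- function(dir, n_per_class = 3, layers = octa_layers(),
                              size = 16, seed = 1) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (lab in c("healthy", "wet_amd")) for (e in seq_len(n_per_class)) {
    id <- paste0(lab, "_", e)
    for (ly in layers) {
      fn <- sprintf("%s_%s.pgm", id, ly)
      write_pgm(matrix(round(runif(size^2, 0, 255)), size, size),
                file.path(dir, fn))
      rows[[length(rows) + 1]] <- data.frame(eye_id = id, layer = ly,
                                             label = lab, path = fn)
    }
  }
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), man_path, row.names = FALSE,
                   quote = FALSE)
  man_path
}
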