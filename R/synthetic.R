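# Seeded synthetic OCTA-like phantoms: class A ("healthy-like") renders
# filamentous curvilinear bright vessels on a dark background; class B
# ("CNV-like") adds bright irregular blob clusters and local dropout
# patches at a controllable density.  Multiplicative-character speckle is
# added on top.  The generator exists so every pipeline stage is testable
# without clinical data; it emulates vessel-vs-lesion micro-structure,
# not physically realistic OCTA decorrelation statistics.

#' Synthetic dataset specification
#'
#' @param n_eyes Integer vector `c(classA, classB)`: eyes per class
#'   (labels `healthy` and `wet_amd` in the emitted manifest).
#' @param image_size Side length in pixels (square images; default 320,
#'   the native en-face slab resolution).
#' @param layers Layers to emit per eye (default all four).
#' @param lesion_density In \[0, 1\]: rate of blob/dropout lesions in
#'   class B.  At 0 the two classes are identically distributed (a null
#'   construction); at 1 lesions are dense.
#' @param tortuosity Vessel waviness in \[0, 1\] (controls control-point
#'   jitter of the random spline curves).
#' @param speckle_sd Speckle noise standard deviation in grey levels at
#'   full brightness (signal-dependent: scaled by `sqrt(I / 255)`).
#' @param seed Integer master seed; every image derives its own stream
#'   from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_eyes = c(33L, 23L), image_size = 320L,
                           layers = octa_layers(), lesion_density = 0.8,
                           tortuosity = 0.5, speckle_sd = 10,
                           seed = 42L) {
  stopifnot(length(n_eyes) == 2L, all(n_eyes >= 1L), image_size >= 32L,
            lesion_density >= 0, lesion_density <= 1,
            tortuosity >= 0, tortuosity <= 1, speckle_sd >= 0)
  layers <- octa_layers()[octa_layers() %in% layers]
  structure(list(n_eyes = as.integer(n_eyes),
                 image_size = as.integer(image_size), layers = layers,
                 lesion_density = lesion_density, tortuosity = tortuosity,
                 speckle_sd = speckle_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Stamp a filled disc of given radius and value (additively, saturating
# later at render time).
stamp_disc <- function(img, row, col, radius, value) {
  n <- nrow(img)
  rr <- max(1L, floor(row - radius)):min(n, ceiling(row + radius))
  cc <- max(1L, floor(col - radius)):min(ncol(img), ceiling(col + radius))
  d2 <- outer((rr - row)^2, (cc - col)^2, "+")
  img[rr, cc] <- pmax(img[rr, cc], value * (d2 <= radius^2))
  img
}

# One random smooth curve through jittered control points, stroked with
# the given width onto the image.
draw_vessel <- function(img, tortuosity, width) {
  n <- nrow(img)
  ncp <- 5L
  # endpoints on opposite-ish borders, interior control points jittered
  t0 <- stats::runif(1, 0, 2 * pi)
  p0 <- c(n / 2 + n / 2 * sin(t0), n / 2 + n / 2 * cos(t0))
  p1 <- c(n / 2 - n / 2 * sin(t0), n / 2 - n / 2 * cos(t0))
  tt <- seq(0, 1, length.out = ncp)
  cr <- p0[1] + tt * (p1[1] - p0[1]) +
    c(0, stats::rnorm(ncp - 2L, 0, tortuosity * n / 4), 0)
  cc <- p0[2] + tt * (p1[2] - p0[2]) +
    c(0, stats::rnorm(ncp - 2L, 0, tortuosity * n / 4), 0)
  ts <- seq(0, 1, length.out = 6L * n)
  rows <- stats::spline(tt, cr, xout = ts)$y
  cols <- stats::spline(tt, cc, xout = ts)$y
  keep <- rows >= 1 & rows <= n & cols >= 1 & cols <= n
  rows <- rows[keep]; cols <- cols[keep]
  bright <- stats::runif(1, 150, 230)
  for (s in seq_along(rows))
    img <- stamp_disc(img, rows[s], cols[s], width / 2, bright)
  img
}

# Render one layer image for one eye of one class.
render_layer_image <- function(spec, class_b, layer) {
  n <- spec$image_size
  img <- matrix(0, n, n)
  n_vessels <- switch(layer, superficial = 14L, deep = 18L, outer = 6L,
                      choriocapillaris = 24L)
  n_vessels <- max(3L, round(n_vessels * n / 320))
  for (v in seq_len(n_vessels))
    img <- draw_vessel(img, spec$tortuosity,
                       width = stats::runif(1, 1, 3))
  img <- gaussian_blur(img, sigma = 0.8)
  if (class_b && spec$lesion_density > 0) {
    # neovascular-membrane-like lesions: irregular clusters of granular
    # bright texture (a chaotic microvascular tangle reads as pixel-scale
    # intensity disorder, unlike the smooth blurred vessel strokes).
    # Cluster stamping continues until the lesions cover a target
    # fraction of the image area proportional to the lesion density, so
    # separability does not depend on the rendered resolution.
    covered <- matrix(FALSE, n, n)
    target_blob <- 0.18 * spec$lesion_density
    while (mean(covered) < target_blob) {
      cr <- stats::runif(1, n * 0.1, n * 0.9)
      cc <- stats::runif(1, n * 0.1, n * 0.9)
      for (s in seq_len(stats::rpois(1, 6) + 2L)) {
        mask <- matrix(0, n, n)
        mask <- stamp_disc(mask, cr + stats::rnorm(1, 0, n / 30),
                           cc + stats::rnorm(1, 0, n / 30),
                           stats::runif(1, n / 60, n / 22), 1)
        inside <- mask > 0
        img[inside] <- stats::runif(sum(inside), 60, 255)
        covered <- covered | inside
      }
    }
    # local dropout patches (flow-void-like): erase texture to background
    dropped <- matrix(FALSE, n, n)
    target_drop <- 0.08 * spec$lesion_density
    while (mean(dropped) < target_drop) {
      mask <- matrix(0, n, n)
      mask <- stamp_disc(mask, stats::runif(1, 1, n), stats::runif(1, 1, n),
                         stats::runif(1, n / 40, n / 12), 1)
      img <- img * (1 - 0.9 * mask)
      dropped <- dropped | (mask > 0)
    }
  }
  if (spec$speckle_sd > 0) {
    noise <- stats::rnorm(n * n, 0, spec$speckle_sd) * sqrt(pmax(img, 0) / 255)
    img <- img + matrix(noise, n, n)
  }
  pmin(pmax(round(img), 0), 255)
}

#' Generate a synthetic OCTA-like dataset on disk
#'
#' Writes one PGM image per (eye, layer) plus a `manifest.csv` compatible
#' with [load_manifest()].  Class A eyes are labelled `healthy`, class B
#' eyes `wet_amd`.  Fully deterministic given `spec$seed`: each image
#' draws from its own seed derived from the master seed, so the dataset
#' is byte-identical across runs.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created if missing).
#' @return The loaded `octa_manifest` (invisibly usable immediately).
#' @export
generate_dataset <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  recs <- list()
  classes <- c("healthy", "wet_amd")
  img_index <- 0L
  for (ci in 1:2) {
    for (e in seq_len(spec$n_eyes[ci])) {
      eye_id <- sprintf("%s_%03d", c("A", "B")[ci], e)
      for (ly in spec$layers) {
        img_index <- img_index + 1L
        # per-image seed derived from the master seed; keep below 2^31
        img_seed <- (spec$seed * 1000003L + img_index * 7919L) %% 2147483647L
        px <- with_local_seed(img_seed, function()
          render_layer_image(spec, class_b = (ci == 2L), layer = ly))
        fn <- sprintf("%s_%s.pgm", eye_id, ly)
        write_pgm(px, file.path(out_dir, fn))
        recs[[length(recs) + 1L]] <- data.frame(
          eye_id = eye_id, layer = ly, label = classes[ci], path = fn,
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, recs)
  man <- new_manifest(df, base_dir = out_dir)
  write_manifest(man, file.path(out_dir, "manifest.csv"))
  man
}

#' Tiny deterministic fixture images with known code maps
#'
#' Hand-constructed small images used as ground truth for descriptor
#' tests: `"constant"` (all one grey level), `"step_edge"` (vertical
#' bright/dark halves), `"checkerboard"` (period-1 alternation) and
#' `"diagonal"` (one bright main diagonal).
#'
#' @param name Fixture name.
#' @param size Side length (default 8).
#' @return A list with `pixels` and, where a closed form exists,
#'   `expected_riu2` — the expected riu2 label(s) for `p = 8, r = 1`.
#' @export
tiny_fixture <- function(name = c("constant", "step_edge", "checkerboard",
                                  "diagonal"), size = 8L) {
  name <- match.arg(name)
  n <- as.integer(size)
  px <- switch(name,
    constant = matrix(100, n, n),
    step_edge = cbind(matrix(20, n, n %/% 2),
                      matrix(220, n, n - n %/% 2)),
    checkerboard = 100 + 100 * outer(seq_len(n), seq_len(n),
                                     function(i, j) (i + j) %% 2),
    diagonal = {
      m <- matrix(10, n, n); diag(m) <- 250; m
    })
  out <- list(name = name, pixels = px)
  if (name == "constant") out$expected_riu2 <- 8L  # all-ones pattern
  if (name == "checkerboard")
    # hand evaluation at p = 8, r = 1: a dark centre sees 4 brighter
    # axis neighbours and 4 interpolated diagonals above it -> 11111111,
    # label 8; a bright centre sees axis neighbours below it and
    # interpolated diagonals (0.414 dark + 0.586 bright mix) also below
    # it -> 00000000, label 0
    out$expected_riu2 <- c(dark = 8L, bright = 0L)
  out
}
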