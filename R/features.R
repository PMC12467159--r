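#' Enumerate the 15 vascular layer combinations
#'
#' All non-empty subsets of the four layers, in the standard reporting
#' order: the 4 single layers, the 6 pairs, the 4 triples, then all four
#' layers, with members of each subset in canonical layer order.
#'
#' @return A list of 15 character vectors.
#' @export
enumerate_layer_combinations <- function() {
  ly <- octa_layers()
  out <- list()
  for (k in 1:4) {
    cm <- utils::combn(4L, k)
    for (j in seq_len(ncol(cm))) out[[length(out) + 1L]] <- ly[cm[, j]]
  }
  out
}

# Histogram for one image under a descriptor spec.
descriptor_histogram <- function(pixels, descriptor, params,
                                 normalize = TRUE) {
  switch(descriptor,
    lbp_riu2 = lbp_histogram(dense_code_map(pixels, params, "riu2"),
                             normalize),
    lbp = lbp_histogram(dense_code_map(pixels, params, "generic"),
                        normalize),
    brief = lbp_histogram(dense_brief_map(pixels, params), normalize),
    stop("unknown descriptor: ", descriptor)
  )
}

descriptor_params <- function(descriptor, params) {
  if (descriptor %in% c("lbp_riu2", "lbp")) {
    if (inherits(params, "lbp_config")) params
    else lbp_config(params$p %||% 8L, params$r %||% 1)
  } else {
    if (inherits(params, "brief_config")) params
    else brief_config(params$S %||% 5L, params$n %||% 8L,
                      params$seed %||% 42L)
  }
}

#' Per-eye feature matrix from a manifest
#'
#' Builds one feature vector per eye by computing the descriptor
#' histogram of each requested layer image and concatenating the
#' histograms in canonical layer order (superficial, deep, outer,
#' choriocapillaris).  The unit of classification is the eye: all layers
#' of one eye occupy one row.
#'
#' @param manifest An [load_manifest()] result (or `new_manifest`).
#' @param descriptor One of `"lbp_riu2"`, `"lbp"`, `"brief"`.
#' @param params An [lbp_config()] / [brief_config()], or a list such as
#'   `list(p = 8, r = 1)` or `list(S = 5, n = 8, seed = 42)`.
#' @param layers Character subset of [octa_layers()] (default all four).
#' @param task Optional task from [octa_tasks()]; if given, only eyes
#'   whose condition participates in the task are kept and a binary
#'   outcome vector is attached.
#' @param normalize Use relative-frequency histograms (default `TRUE`),
#'   so concatenated layers with different valid areas are comparable.
#' @param cache Optional environment used to memoize per-image
#'   histograms across calls.
#' @return An object of class `feature_matrix`: list with `D` (numeric
#'   `N x F` matrix, rows named by eye), `eye_ids`, `labels` (condition
#'   strings), `outcome` (0/1 integer or `NULL`), `layers`, `descriptor`
#'   and `fingerprint`.
#' @export
extract_features <- function(manifest, descriptor = c("lbp_riu2", "lbp",
                                                      "brief"),
                             params = list(), layers = octa_layers(),
                             task = NULL, normalize = TRUE, cache = NULL) {
  descriptor <- match.arg(descriptor)
  layers <- octa_layers()[octa_layers() %in% layers]
  if (!length(layers)) stop("no valid layers requested")
  params <- descriptor_params(descriptor, params)
  df <- as.data.frame(manifest)

  eyes <- unique(df$eye_id)
  eye_label <- vapply(eyes, function(e) df$label[df$eye_id == e][1L],
                      character(1))
  outcome <- NULL
  if (!is.null(task)) {
    y <- task_outcome(eye_label, task)
    keep <- !is.na(y)
    eyes <- eyes[keep]; eye_label <- eye_label[keep]
    outcome <- y[keep]
  }
  if (!length(eyes)) stop("no eyes left after task filtering")

  fp <- feature_fingerprint(descriptor, params, normalize)
  rows <- vector("list", length(eyes))
  for (i in seq_along(eyes)) {
    vec <- numeric(0)
    for (ly in layers) {
      j <- which(df$eye_id == eyes[i] & df$layer == ly)
      if (!length(j))
        stop("eye '", eyes[i], "' is missing requested layer '", ly, "'")
      path <- manifest_path(manifest, j)
      key <- paste(fp, path, sep = "|")
      h <- if (!is.null(cache) && !is.null(cache[[key]])) cache[[key]]
      else {
        hh <- descriptor_histogram(read_image(path), descriptor, params,
                                   normalize)$bins
        if (!is.null(cache)) cache[[key]] <- hh
        hh
      }
      vec <- c(vec, h)
    }
    rows[[i]] <- vec
  }
  D <- do.call(rbind, rows)
  rownames(D) <- eyes
  structure(list(D = D, eye_ids = eyes, labels = eye_label,
                 outcome = outcome, layers = layers,
                 descriptor = descriptor, params = params,
                 fingerprint = fp),
            class = "feature_matrix")
}

feature_fingerprint <- function(descriptor, params, normalize) {
  ps <- if (inherits(params, "lbp_config"))
    sprintf("p%dr%g", params$p, params$r)
  else sprintf("S%dn%dseed%d", params$S, params$n, params$seed)
  sprintf("%s_%s_%s", descriptor, ps, if (normalize) "norm" else "count")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature matrix: %d eyes x %d features (%s; layers: %s)\n",
              nrow(x$D), ncol(x$D), x$fingerprint,
              paste(x$layers, collapse = ", ")))
  invisible(x)
}

#' Persist a feature matrix as CSV
#'
#' Columns: `eye_id`, `label`, then `f0 .. f(F-1)`.
#'
#' @param fm A `feature_matrix`.
#' @param path Output CSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  out <- data.frame(eye_id = fm$eye_ids, label = fm$labels,
                    fm$D, check.names = FALSE)
  names(out)[-(1:2)] <- paste0("f", seq_len(ncol(fm$D)) - 1L)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
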