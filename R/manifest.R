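#' Vascular layer and condition vocabularies
#'
#' `octa_layers()` returns the four en-face vascular layers in canonical
#' order (superficial inner retina, deep inner retina, outer retina,
#' choriocapillaris); this order fixes the concatenation order of per-layer
#' feature vectors.  `octa_labels()` returns the recognised eye-condition
#' labels and `octa_tasks()` the supported binary classification tasks.
#'
#' @return Character vectors.
#' @export
octa_layers <- function() c("superficial", "deep", "outer", "choriocapillaris")

#' @rdname octa_layers
#' @export
octa_labels <- function() c("healthy", "dry_amd", "wet_amd", "secondary_cnv")

#' @rdname octa_layers
#' @export
octa_tasks <- function() c("healthy_vs_wet", "dry_vs_wet", "cnv_vs_noncnv")

#' Load a dataset manifest from CSV
#'
#' The manifest lists one image file per (eye, layer) with columns exactly
#' `eye_id,layer,label,path`.  Layer tokens must come from [octa_layers()]
#' and labels from [octa_labels()]; an eye may appear with at most one
#' image per layer and must carry a single condition label.
#'
#' @param path CSV file path.
#' @return An object of class `octa_manifest`: a data frame of records
#'   plus a `base_dir` attribute used to resolve relative image paths.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  new_manifest(df, base_dir = dirname(path))
}

new_manifest <- function(df, base_dir = ".") {
  need <- c("eye_id", "layer", "label", "path")
  if (!identical(names(df)[seq_along(need)], need) ||
      ncol(df) != length(need))
    stop("manifest header must be exactly: ", paste(need, collapse = ","))
  bad_layer <- setdiff(unique(df$layer), octa_layers())
  if (length(bad_layer))
    stop("unknown layer token(s): ", paste(bad_layer, collapse = ", "))
  bad_label <- setdiff(unique(df$label), octa_labels())
  if (length(bad_label))
    stop("unknown label token(s): ", paste(bad_label, collapse = ", "))
  key <- paste(df$eye_id, df$layer)
  if (anyDuplicated(key))
    stop("duplicate (eye_id, layer) record(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  lab_per_eye <- tapply(df$label, df$eye_id, function(x) length(unique(x)))
  if (any(lab_per_eye > 1L))
    stop("conflicting labels for eye(s): ",
         paste(names(lab_per_eye)[lab_per_eye > 1L], collapse = ", "))
  structure(df, class = c("octa_manifest", "data.frame"),
            base_dir = base_dir)
}

#' @rdname load_manifest
#' @param manifest An `octa_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest)[, c("eye_id", "layer", "label",
                                               "path")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.octa_manifest <- function(x, ...) {
  cat("OCTA dataset manifest:", nrow(x), "images,",
      length(unique(x$eye_id)), "eyes\n")
  print(manifest_counts(x))
  invisible(x)
}

#' Per-(layer, label) image counts of a manifest
#'
#' @param manifest An `octa_manifest`.
#' @return A layer x label contingency table.
#' @export
manifest_counts <- function(manifest) {
  table(factor(manifest$layer, octa_layers()),
        factor(manifest$label, octa_labels()))
}

# Resolve a record's image path against the manifest base directory.
manifest_path <- function(manifest, i) {
  p <- manifest$path[i]
  if (file.exists(p)) p else file.path(attr(manifest, "base_dir"), p)
}

#' Map condition labels to the binary outcome of a task
#'
#' For `healthy_vs_wet` the positive class is `wet_amd` and the negative
#' class `healthy`; for `dry_vs_wet`, positive `wet_amd` vs negative
#' `dry_amd`; for `cnv_vs_noncnv` the positive class pools `wet_amd` with
#' `secondary_cnv` against negative `dry_amd`.  Labels outside the task
#' are returned as `NA` (those eyes are excluded from the task).
#'
#' @param labels Character vector of condition labels.
#' @param task One of [octa_tasks()].
#' @return Integer vector of 1 (positive), 0 (negative) or `NA`.
#' @export
task_outcome <- function(labels, task = octa_tasks()) {
  task <- match.arg(task)
  pos <- switch(task,
    healthy_vs_wet = "wet_amd",
    dry_vs_wet     = "wet_amd",
    cnv_vs_noncnv  = c("wet_amd", "secondary_cnv"))
  neg <- switch(task,
    healthy_vs_wet = "healthy",
    dry_vs_wet     = "dry_amd",
    cnv_vs_noncnv  = "dry_amd")
  out <- rep(NA_integer_, length(labels))
  out[labels %in% pos] <- 1L
  out[labels %in% neg] <- 0L
  out
}
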