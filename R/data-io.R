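#' Image sample
#'
#' The unit record of the pipeline: one RGB image with its class label(s),
#' a polyp (case) identifier, provenance, and an optional bounding box in
#' original-image pixel coordinates. Boxes use 0-based, half-open
#' conventions: the crop covers columns `[x_min, x_min + width)` and rows
#' `[y_min, y_min + height)`.
#'
#' @param pixels H x W x 3 numeric array in \[0, 1\].
#' @param label Character vector of class labels (length 1 for single-label
#'   data, longer for multilabel corpora, `NULL` for unlabeled images).
#' @param polyp_id Non-empty identifier of the polyp/case the image shows.
#' @param source Free-text provenance tag.
#' @param bbox Optional numeric vector `c(x_min, y_min, width, height)`.
#' @return An `image_sample` object.
#' @export
image_sample <- function(pixels, label = NULL, polyp_id, source = "unknown",
                         bbox = NULL) {
  assert_image(pixels, "pixels")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop_input("pixel values must lie in [0, 1]")
  if (missing(polyp_id) || !nzchar(polyp_id[1]))
    stop_input("polyp_id must be a non-empty string")
  if (!is.null(bbox)) validate_bbox(bbox, dim(pixels))
  structure(list(pixels = pixels,
                 label = if (is.null(label) || all(is.na(label))) NULL
                         else as.character(label),
                 polyp_id = as.character(polyp_id),
                 source = source, bbox = bbox),
            class = "image_sample")
}

validate_bbox <- function(bbox, img_dim) {
  if (length(bbox) != 4L || anyNA(bbox))
    stop_input("bbox must be c(x_min, y_min, width, height)")
  x <- bbox[1]; y <- bbox[2]; w <- bbox[3]; h <- bbox[4]
  if (w <= 0 || h <= 0) stop_input("bbox has zero or negative area")
  if (x < 0 || y < 0 || x + w > img_dim[2] || y + h > img_dim[1])
    stop_input("bbox [%g,%g,%g,%g] lies outside the %dx%d image",
               x, y, w, h, img_dim[2], img_dim[1])
  invisible(bbox)
}

#' Dataset of image samples
#'
#' @param samples List of [image_sample()] objects.
#' @param class_vocabulary Ordered character vector of class ids; defaults
#'   to the sorted union of all sample labels.
#' @param one_image_per_polyp Enforce unique polyp ids (the regime of
#'   few-shot polyp data, where each polyp contributes exactly one image
#'   and train/test splits are therefore structurally polyp-disjoint).
#' @return A `polyp_dataset` object.
#' @export
polyp_dataset <- function(samples, class_vocabulary = NULL,
                          one_image_per_polyp = TRUE) {
  if (!length(samples)) stop_input("dataset has no samples")
  labs <- unlist(lapply(samples, `[[`, "label"))
  if (is.null(class_vocabulary)) class_vocabulary <- sort(unique(labs))
  if (length(labs) && !all(labs %in% class_vocabulary))
    stop_input("labels outside the class vocabulary: %s",
               paste(setdiff(labs, class_vocabulary), collapse = ", "))
  ids <- vapply(samples, `[[`, "", "polyp_id")
  if (one_image_per_polyp && anyDuplicated(ids))
    stop_input("duplicate polyp ids with one_image_per_polyp enabled")
  structure(list(samples = samples,
                 class_vocabulary = as.character(class_vocabulary),
                 one_image_per_polyp = one_image_per_polyp),
            class = "polyp_dataset")
}

#' @export
print.polyp_dataset <- function(x, ...) {
  labs <- dataset_labels(x)
  cat(sprintf("<polyp_dataset> %d samples, %d classes (%s)\n",
              length(x$samples), length(x$class_vocabulary),
              paste(x$class_vocabulary, collapse = ", ")))
  if (length(labs)) print(table(labs, dnn = NULL))
  invisible(x)
}

# First label of each sample (NA for unlabeled); multilabel corpora use
# sample$label directly.
dataset_labels <- function(dataset) {
  vapply(dataset$samples, function(s)
    if (is.null(s$label)) NA_character_ else s$label[1], "")
}

dataset_polyp_ids <- function(dataset)
  vapply(dataset$samples, `[[`, "", "polyp_id")

#' Load a dataset from a CSV manifest
#'
#' The manifest must contain columns `path` and `polyp_id`; `label` and the
#' bbox columns `x_min`, `y_min`, `width`, `height` are optional. Rows with
#' a missing label are retained as unlabeled samples (usable by the
#' self-supervised stages; supervised operations will refuse them).
#'
#' @param manifest_path Path to the CSV manifest.
#' @param image_root Directory that `path` entries are relative to;
#'   defaults to the manifest's directory.
#' @return A [polyp_dataset()].
#' @export
load_manifest <- function(manifest_path, image_root = dirname(manifest_path)) {
  if (!file.exists(manifest_path))
    stop_input("manifest not found: %s", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("path", "polyp_id") %in% names(man)))
    stop_input("manifest must have 'path' and 'polyp_id' columns")
  has_bbox <- all(c("x_min", "y_min", "width", "height") %in% names(man))
  samples <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    f <- file.path(image_root, man$path[i])
    if (!file.exists(f))
      stop_input("manifest row %d: image file not found: %s", i, f)
    px <- read_image(f)
    bbox <- NULL
    if (has_bbox && !is.na(man$x_min[i]))
      bbox <- c(man$x_min[i], man$y_min[i], man$width[i], man$height[i])
    lab <- if ("label" %in% names(man) && !is.na(man$label[i]) &&
               nzchar(man$label[i]))
      strsplit(man$label[i], ";", fixed = TRUE)[[1]] else NULL
    samples[[i]] <- image_sample(px, label = lab,
                                 polyp_id = man$polyp_id[i],
                                 source = man$path[i], bbox = bbox)
  }
  polyp_dataset(samples,
                one_image_per_polyp = !anyDuplicated(man$polyp_id))
}

#' Read a PNG or JPEG file as an H x W x 3 array in \[0, 1\]
#' @param path Image file.
#' @return RGB array.
#' @export
read_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 3L))
  px[, , 1:3, drop = FALSE]
}

#' Crop to the polyp region and resample to a common shape
#'
#' Applies the standard preprocessing: if the sample carries a bounding
#' box the image is cropped to it, then bilinearly resampled to
#' `target_size` x `target_size` (both down- and up-sampling), and clipped
#' to \[0, 1\]. Applying `preprocess` twice at the same target size is a
#' no-op up to resampler round-off.
#'
#' @param sample An [image_sample()].
#' @param target_size Output side length in pixels (default 224).
#' @return The preprocessed `image_sample` (bbox consumed).
#' @export
preprocess <- function(sample, target_size = 224L) {
  stopifnot(inherits(sample, "image_sample"))
  px <- sample$pixels
  if (!is.null(sample$bbox)) {
    b <- validate_bbox(sample$bbox, dim(px))
    rows <- (b[2] + 1L):(b[2] + b[4])
    cols <- (b[1] + 1L):(b[1] + b[3])
    px <- px[rows, cols, , drop = FALSE]
  }
  px <- resize_image(px, target_size)
  image_sample(clip01(px), label = sample$label, polyp_id = sample$polyp_id,
               source = sample$source, bbox = NULL)
}

# Bilinear resize of an H x W x 3 array to size x size.
resize_image <- function(px, size) {
  d <- dim(px)
  if (d[1] == size && d[2] == size) return(px)
  out <- array(0, c(size, size, 3L))
  for (c in 1:3)
    out[, , c] <- EBImage::resize(px[, , c], w = size, h = size)
  out
}

#' Preprocess every sample of a dataset
#' @param dataset A [polyp_dataset()].
#' @param target_size Side length in pixels.
#' @return The preprocessed dataset.
#' @export
preprocess_dataset <- function(dataset, target_size = 224L) {
  dataset$samples <- lapply(dataset$samples, preprocess,
                            target_size = target_size)
  dataset
}

#' Write a dataset as PNG images plus a CSV manifest
#'
#' @param dataset A [polyp_dataset()] (or list of samples).
#' @param dir Output directory.
#' @param ground_truth Optional ground-truth list (as produced by the
#'   synthetic generators); written as a JSON sidecar, with any highlight
#'   masks stored as PNGs.
#' @return The manifest path, invisibly.
#' @export
write_image_dataset <- function(dataset, dir, ground_truth = NULL) {
  samples <- if (inherits(dataset, "polyp_dataset")) dataset$samples
             else dataset
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  n <- length(samples)
  man <- data.frame(path = character(n), label = character(n),
                    polyp_id = character(n),
                    x_min = NA_real_, y_min = NA_real_,
                    width = NA_real_, height = NA_real_)
  for (i in seq_len(n)) {
    s <- samples[[i]]
    rel <- file.path("images", sprintf("%s.png", s$polyp_id))
    png::writePNG(s$pixels, file.path(dir, rel))
    man$path[i] <- rel
    man$label[i] <- if (is.null(s$label)) NA_character_
                    else paste(s$label, collapse = ";")
    man$polyp_id[i] <- s$polyp_id
    if (!is.null(s$bbox)) man[i, 4:7] <- as.numeric(s$bbox)
  }
  if (all(is.na(man$x_min))) man <- man[, 1:3]
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mpath, row.names = FALSE)
  if (!is.null(ground_truth))
    write_ground_truth(ground_truth, dir, vapply(samples, `[[`, "", "polyp_id"))
  invisible(mpath)
}

write_ground_truth <- function(gt, dir, ids) {
  side <- gt
  if (!is.null(gt$highlight_masks)) {
    mdir <- file.path(dir, "highlight_masks")
    dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
    files <- character(length(gt$highlight_masks))
    for (i in seq_along(gt$highlight_masks)) {
      files[i] <- file.path("highlight_masks", sprintf("%s.png", ids[i]))
      png::writePNG(gt$highlight_masks[[i]] * 1, file.path(dir, files[i]))
    }
    side$highlight_masks <- files
  }
  jsonlite::write_json(side, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
}
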