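#' Augmentation settings
#'
#' Bundles the endoscopy-oriented augmentation set: random flips along both
#' image axes, photometric jitter of hue / contrast / brightness /
#' saturation, additive gaussian pixel noise, and grafting of specular
#' highlights drawn from a highlight bank. The fixed composition order is
#' flip, jitter, noise, graft; composed output always stays in \[0, 1\].
#'
#' Jitter semantics: brightness and saturation are multiplicative factors
#' (1 = identity), contrast scales deviation from the image mean, and hue
#' is a circular rotation of the chroma plane by `hue_delta` turns. All
#' ranges default to the package's "heavy jitter" setting of factors in
#' \[0.7, 1.3\] and hue shifts of up to 5% of the hue circle; every bound
#' is configurable.
#'
#' @param flip_axes Subset of `c("horizontal", "vertical")`.
#' @param hue_delta Maximum absolute hue rotation, in turns of the hue
#'   circle (0 disables).
#' @param contrast_range,brightness_range,saturation_range Two-element
#'   factor intervals; `c(1, 1)` disables the corresponding jitter.
#' @param noise_sigma Standard deviation of additive gaussian noise in
#'   intensity units (0 disables).
#' @param graft_highlights Logical; paste random specular highlights?
#' @param highlight_bank List of `highlight_mask` objects (required when
#'   `graft_highlights` is `TRUE`).
#' @param n_highlights Highlights grafted per image.
#' @return An `augmentation_spec` object.
#' @export
augmentation_spec <- function(flip_axes = c("horizontal", "vertical"),
                              hue_delta = 0.05,
                              contrast_range = c(0.7, 1.3),
                              brightness_range = c(0.7, 1.3),
                              saturation_range = c(0.7, 1.3),
                              noise_sigma = 0.02,
                              graft_highlights = FALSE,
                              highlight_bank = NULL,
                              n_highlights = 2L) {
  chk_range <- function(r, nm) {
    if (length(r) != 2L || r[1] > r[2])
      stop_input("%s must be an interval c(lo, hi) with lo <= hi", nm)
  }
  chk_range(contrast_range, "contrast_range")
  chk_range(brightness_range, "brightness_range")
  chk_range(saturation_range, "saturation_range")
  if (noise_sigma < 0) stop_input("noise_sigma must be >= 0")
  if (hue_delta < 0) stop_input("hue_delta must be >= 0")
  if (!all(flip_axes %in% c("horizontal", "vertical")))
    stop_input("flip_axes must be a subset of horizontal/vertical")
  if (isTRUE(graft_highlights) && length(highlight_bank) == 0L)
    stop_input("graft_highlights = TRUE requires a non-empty highlight_bank")
  structure(list(flip_axes = flip_axes, hue_delta = hue_delta,
                 contrast_range = contrast_range,
                 brightness_range = brightness_range,
                 saturation_range = saturation_range,
                 noise_sigma = noise_sigma,
                 graft_highlights = isTRUE(graft_highlights),
                 highlight_bank = highlight_bank,
                 n_highlights = as.integer(n_highlights)),
            class = "augmentation_spec")
}

#' Identity augmentation (no-op), handy for controls and validation sets.
#' @rdname augmentation_spec
#' @export
augmentation_identity <- function() {
  augmentation_spec(flip_axes = character(0), hue_delta = 0,
                    contrast_range = c(1, 1), brightness_range = c(1, 1),
                    saturation_range = c(1, 1), noise_sigma = 0,
                    graft_highlights = FALSE)
}

#' Deterministic image flips
#'
#' `flip_image` applies the requested flips exactly; `random_flip` flips
#' along each listed axis independently with probability 0.5 using the
#' current RNG stream. Horizontal flips mirror columns, vertical flips
#' mirror rows; applying the same flip twice restores the input.
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param horizontal,vertical Logical flags.
#' @param axes Axes eligible for random flipping.
#' @return The (possibly) flipped image.
#' @export
flip_image <- function(image, horizontal = FALSE, vertical = FALSE) {
  assert_image(image)
  if (vertical) image <- image[dim(image)[1]:1, , , drop = FALSE]
  if (horizontal) image <- image[, dim(image)[2]:1, , drop = FALSE]
  image
}

#' @rdname flip_image
#' @export
random_flip <- function(image, axes = c("horizontal", "vertical")) {
  flip_image(image,
             horizontal = "horizontal" %in% axes && stats::runif(1) < 0.5,
             vertical = "vertical" %in% axes && stats::runif(1) < 0.5)
}

# Hue rotation matrix about the gray axis (YIQ chroma plane), angle in turns.
hue_rotation_matrix <- function(turns) {
  rgb2yiq <- matrix(c(0.299, 0.587, 0.114,
                      0.596, -0.274, -0.322,
                      0.211, -0.523, 0.312), 3, 3, byrow = TRUE)
  th <- 2 * pi * turns
  rot <- matrix(c(1, 0, 0,
                  0, cos(th), -sin(th),
                  0, sin(th), cos(th)), 3, 3, byrow = TRUE)
  solve(rgb2yiq) %*% rot %*% rgb2yiq
}

#' Photometric jitter
#'
#' Randomly perturbs hue, contrast, brightness and saturation within the
#' bounds of `spec`. Degenerate bounds (`c(1, 1)` factors, `hue_delta = 0`)
#' are skipped entirely, so the identity spec returns the input unchanged,
#' bit for bit. Output is clipped to \[0, 1\].
#'
#' @param image H x W x 3 array.
#' @param spec An [augmentation_spec()].
#' @return Jittered image.
#' @export
photometric_jitter <- function(image, spec) {
  assert_image(image)
  stopifnot(inherits(spec, "augmentation_spec"))
  d <- dim(image)
  px <- matrix(image, ncol = 3L)
  changed <- FALSE
  runif1 <- function(r) stats::runif(1, r[1], r[2])

  if (spec$hue_delta > 0) {
    turns <- stats::runif(1, -spec$hue_delta, spec$hue_delta)
    px <- px %*% t(hue_rotation_matrix(turns))
    changed <- TRUE
  }
  if (any(spec$saturation_range != 1)) {
    s <- runif1(spec$saturation_range)
    gray <- px %*% c(0.299, 0.587, 0.114)
    px <- gray[, rep(1L, 3L)] + s * (px - gray[, rep(1L, 3L)])
    changed <- TRUE
  }
  if (any(spec$contrast_range != 1)) {
    cf <- runif1(spec$contrast_range)
    mu <- mean(px)
    px <- mu + cf * (px - mu)
    changed <- TRUE
  }
  if (any(spec$brightness_range != 1)) {
    px <- px * runif1(spec$brightness_range)
    changed <- TRUE
  }
  if (!changed) return(image)
  array(clip01(px), d)
}

#' Additive gaussian pixel noise
#'
#' @param image H x W x 3 array.
#' @param sigma Noise standard deviation in intensity units; 0 is the
#'   identity.
#' @return Noisy image clipped to \[0, 1\].
#' @export
add_gaussian_noise <- function(image, sigma) {
  assert_image(image)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop_input("sigma must be a single non-negative number")
  if (sigma == 0) return(image)
  clip01(image + array(stats::rnorm(length(image), sd = sigma), dim(image)))
}

#' Highlight mask/patch pair
#'
#' A specular highlight extracted from (or destined for) an image: a binary
#' mask plus the RGB patch of identical size.
#'
#' @param mask Logical H' x W' matrix; must contain at least one `TRUE`
#'   pixel unless `allow_empty`.
#' @param patch H' x W' x 3 array in \[0, 1\].
#' @param allow_empty Permit an empty mask (used by the detector to report
#'   "no highlight found").
#' @return A `highlight_mask` object.
#' @export
highlight_mask <- function(mask, patch, allow_empty = FALSE) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop_input("mask must be a logical matrix")
  assert_image(patch, "patch")
  if (!identical(dim(mask), dim(patch)[1:2]))
    stop_input("mask and patch sizes differ")
  if (!allow_empty && !any(mask)) stop_input("highlight mask is empty")
  structure(list(mask = mask, patch = patch, found = any(mask)),
            class = "highlight_mask")
}

#' Detect specular highlights
#'
#' Specular highlights on wet mucosa saturate the sensor: they are very
#' bright and nearly colorless. The detector marks pixels whose channel
#' maximum is at least `brightness_threshold` and whose saturation
#' (`(max - min) / max`) is at most `saturation_threshold`, then dilates
#' the mask with a disc of radius `dilation_radius` to capture the soft
#' rim of each blob.
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param brightness_threshold,saturation_threshold Thresholds in \[0, 1\].
#' @param dilation_radius Dilation radius in pixels (default 0 = the raw
#'   threshold mask; increase to capture the soft rim around each blob).
#' @return A [highlight_mask()] covering the whole image; its `found` field
#'   is `FALSE` when no pixel qualifies.
#' @export
detect_specular_highlights <- function(image, brightness_threshold = 0.95,
                                       saturation_threshold = 0.25,
                                       dilation_radius = 0L) {
  assert_image(image)
  for (v in c(brightness_threshold, saturation_threshold))
    if (v < 0 || v > 1) stop_input("thresholds must lie in [0, 1]")
  vmax <- pmax(image[, , 1], image[, , 2], image[, , 3])
  vmin <- pmin(image[, , 1], image[, , 2], image[, , 3])
  sat <- ifelse(vmax > 0, (vmax - vmin) / vmax, 0)
  mask <- vmax >= brightness_threshold & sat <= saturation_threshold
  if (dilation_radius > 0 && any(mask)) {
    brush <- EBImage::makeBrush(2L * as.integer(dilation_radius) + 1L, "disc")
    mask <- EBImage::dilate(mask * 1, brush) > 0
  }
  highlight_mask(mask, image, allow_empty = TRUE)
}

#' Graft specular highlights onto an image
#'
#' Pastes `n_highlights` entries drawn from the bank at uniform random
#' positions. Pixels under each entry's mask are replaced by the entry's
#' patch values (hard replacement: real specular highlights saturate the
#' sensor, so no alpha blending is applied); all pixels outside the
#' returned composite mask are bit-identical to the input.
#'
#' @param image H x W x 3 array.
#' @param bank Non-empty list of [highlight_mask()] objects.
#' @param n_highlights Number of highlights to place (0 = identity).
#' @return List with the modified `image` and the logical composite `mask`.
#' @export
graft_highlights <- function(image, bank, n_highlights = 2L) {
  assert_image(image)
  n_highlights <- as.integer(n_highlights)
  if (n_highlights < 0) stop_input("n_highlights must be >= 0")
  d <- dim(image)
  comp <- matrix(FALSE, d[1], d[2])
  if (n_highlights == 0L)
    return(list(image = image, mask = comp))
  if (length(bank) == 0L)
    stop_input("cannot graft highlights from an empty bank")
  picks <- sample.int(length(bank), n_highlights, replace = TRUE)
  for (k in picks) {
    hm <- bank[[k]]
    ph <- dim(hm$mask)[1]; pw <- dim(hm$mask)[2]
    if (ph > d[1] || pw > d[2]) stop_input("bank entry larger than image")
    i0 <- sample.int(d[1] - ph + 1L, 1L) - 1L
    j0 <- sample.int(d[2] - pw + 1L, 1L) - 1L
    sub <- image[i0 + seq_len(ph), j0 + seq_len(pw), , drop = FALSE]
    m3 <- array(hm$mask, dim(sub))
    sub[m3] <- hm$patch[m3]
    image[i0 + seq_len(ph), j0 + seq_len(pw), ] <- sub
    comp[i0 + seq_len(ph), j0 + seq_len(pw)] <-
      comp[i0 + seq_len(ph), j0 + seq_len(pw)] | hm$mask
  }
  list(image = image, mask = comp)
}

#' Apply the full augmentation pipeline to one image
#'
#' Fixed composition order: flip, photometric jitter, gaussian noise,
#' highlight grafting. Randomness is drawn from the current RNG stream, so
#' seeding the stream makes the augmentation reproducible.
#'
#' @param image H x W x 3 array.
#' @param spec An [augmentation_spec()].
#' @return Augmented image in \[0, 1\].
#' @export
augment_image <- function(image, spec) {
  stopifnot(inherits(spec, "augmentation_spec"))
  image <- random_flip(image, spec$flip_axes)
  image <- photometric_jitter(image, spec)
  if (spec$noise_sigma > 0) image <- add_gaussian_noise(image, spec$noise_sigma)
  if (spec$graft_highlights)
    image <- graft_highlights(image, spec$highlight_bank, spec$n_highlights)$image
  image
}

#' Serialize / load a highlight bank
#'
#' Each entry is written as a pair of PNGs (binary mask, RGB patch) plus a
#' JSON index listing the pairs.
#'
#' @param bank List of [highlight_mask()] objects.
#' @param dir Output directory (created if missing).
#' @return `write_highlight_bank` returns `dir` invisibly;
#'   `read_highlight_bank` returns the bank.
#' @export
write_highlight_bank <- function(bank, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- vector("list", length(bank))
  for (i in seq_along(bank)) {
    mfile <- sprintf("highlight_%03d_mask.png", i)
    pfile <- sprintf("highlight_%03d_patch.png", i)
    png::writePNG(bank[[i]]$mask * 1, file.path(dir, mfile))
    png::writePNG(bank[[i]]$patch, file.path(dir, pfile))
    idx[[i]] <- list(mask = mfile, patch = pfile)
  }
  jsonlite::write_json(idx, file.path(dir, "index.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_highlight_bank
#' @export
read_highlight_bank <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "index.json"))
  lapply(idx, function(e) {
    mask <- png::readPNG(file.path(dir, e$mask))
    if (length(dim(mask)) == 3L) mask <- mask[, , 1]
    patch <- png::readPNG(file.path(dir, e$patch))
    if (length(dim(patch)) == 2L) patch <- array(patch, c(dim(patch), 3L))
    highlight_mask(mask > 0.5, patch[, , 1:3, drop = FALSE])
  })
}
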