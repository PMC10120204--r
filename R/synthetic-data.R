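# Synthetic image generators.
#
# These emulate the structure of few-shot polyp data without any clinical
# content: two classes that differ only in surface texture (dark/white
# spots or homogeneous appearance versus oval/tubular/branched bright
# ridge structures), a multilabel texture corpus for pretraining, scene-
# structured videos with planted sharp frames, and banks of specular
# highlight patches. Everything is a pure function of its spec, seed
# included.

# Smooth random field: coarse gaussian grid, bilinearly upsampled.
smooth_field <- function(size, grid = 6L, amplitude = 1) {
  g <- matrix(stats::rnorm(grid * grid), grid, grid)
  amplitude * EBImage::resize(g, w = size, h = size)
}

# Randomly placed soft spots (dark or bright); near zero-mean by design.
render_spots <- function(size, density, contrast) {
  pat <- matrix(0, size, size)
  if (density <= 0 || contrast <= 0) return(pat)
  r0 <- max(2, 0.03 * size)
  n_spots <- max(1L, round(density * size^2 / (pi * r0^2)))
  for (k in seq_len(n_spots)) {
    cx <- stats::runif(1, 1, size)
    cy <- stats::runif(1, 1, size)
    r <- r0 * stats::runif(1, 0.6, 1.4)
    sgn <- sample(c(-1, 1), 1)
    win <- ceiling(3 * r)
    ii <- max(1, floor(cy - win)):min(size, ceiling(cy + win))
    jj <- max(1, floor(cx - win)):min(size, ceiling(cx + win))
    d2 <- outer((ii - cy)^2, (jj - cx)^2, "+")
    pat[ii, jj] <- pat[ii, jj] + sgn * exp(-d2 / (2 * (r / 1.6)^2))
  }
  contrast * 0.45 * (pat - mean(pat))
}

# Warped oriented sinusoidal ridges with a secondary branching component.
render_ridges <- function(size, freq, contrast) {
  if (freq <= 0 || contrast <= 0) return(matrix(0, size, size))
  xs <- matrix(rep(seq_len(size), each = size), size, size)   # column index
  ys <- matrix(rep(seq_len(size), times = size), size, size)  # row index
  wx <- smooth_field(size, grid = 5L, amplitude = 0.06 * size)
  wy <- smooth_field(size, grid = 5L, amplitude = 0.06 * size)
  theta <- stats::runif(1, 0, pi)
  phase <- stats::runif(1, 0, 2 * pi)
  u <- cos(theta) * (xs + wx) + sin(theta) * (ys + wy)
  s1 <- sin(2 * pi * freq * u / size + phase)
  theta2 <- theta + stats::runif(1, 0.6, 1.2)
  v <- cos(theta2) * (xs + wy) + sin(theta2) * (ys + wx)
  s2 <- sin(2 * pi * freq * 0.7 * v / size + phase / 2)
  ridge <- pmax(s1, 0)^2 + 0.5 * pmax(s2, 0)^2  # bright ridge structures
  contrast * 0.5 * (ridge - mean(ridge))
}

# Shared mucosa-like base: identical color statistics for every class, so
# only the superimposed texture is class-discriminative.
render_base <- function(size) {
  base_col <- c(0.72, 0.47, 0.42)
  shade <- smooth_field(size, grid = 5L, amplitude = 0.05)
  img <- array(0, c(size, size, 3L))
  for (c in 1:3)
    img[, , c] <- base_col[c] + shade + smooth_field(size, 8L, 0.02)
  img
}

# Paste one saturated near-white blob; returns image + core (saturated)
# mask. Core pixels are hard-set (a saturated sensor records no texture or
# noise); a narrow soft rim fades back into the scene.
render_highlight_blob <- function(img, cx, cy, r) {
  size_r <- dim(img)[1]; size_c <- dim(img)[2]
  win <- ceiling(r + 3)
  ii <- max(1, floor(cy - win)):min(size_r, ceiling(cy + win))
  jj <- max(1, floor(cx - win)):min(size_c, ceiling(cx + win))
  d <- sqrt(outer((ii - cy)^2, (jj - cx)^2, "+"))
  w <- pmin(1, pmax(0, 1 - (d - r) / 1.5))
  hl_col <- c(0.99, 0.99, 0.97)
  for (c in 1:3) {
    sub <- img[ii, jj, c]
    img[ii, jj, c] <- sub * (1 - w) + hl_col[c] * w
  }
  core <- matrix(FALSE, size_r, size_c)
  core[ii, jj] <- d <= r
  list(image = img, core = core)
}

#' Specification of a synthetic two-class polyp image set
#'
#' Each synthetic polyp contributes exactly one image (the few-shot regime
#' of curated polyp data), with class identity expressed purely through
#' surface texture: a "spotted" class with dark/white spots on an otherwise
#' homogeneous mucosa-like base, and a "tubular" class with bright, warped,
#' branched ridge structures. Both classes share base color statistics.
#' Saturated specular highlights are superimposed at a Poisson-distributed
#' rate and sensor noise is added before the (noise-free, saturated)
#' highlights.
#'
#' @param n_polyps_per_class Polyps (= images) per class, >= 1.
#' @param image_size Square image side in pixels, >= 32 (default 224).
#' @param class_texture_params Named list of per-class parameter lists,
#'   each with `spot_density` (fraction of area covered by spots),
#'   `tubule_frequency` (ridge cycles per image width) and
#'   `pattern_contrast` in \[0, 1\] (0 makes the classes statistically
#'   indistinguishable).
#' @param highlight_density Expected highlights per image (Poisson mean).
#' @param noise_sigma Gaussian sensor-noise standard deviation.
#' @param seed Integer seed; fully determines the generated set.
#' @return A `synthetic_polyp_spec` object.
#' @export
synthetic_polyp_spec <- function(n_polyps_per_class = 5L,
                                 image_size = 224L,
                                 class_texture_params = list(
                                   spotted = list(spot_density = 0.03,
                                                  tubule_frequency = 0,
                                                  pattern_contrast = 0.8),
                                   tubular = list(spot_density = 0,
                                                  tubule_frequency = 9,
                                                  pattern_contrast = 0.8)),
                                 highlight_density = 3,
                                 noise_sigma = 0.05,
                                 seed = 1L) {
  if (n_polyps_per_class < 1) stop_input("n_polyps_per_class must be >= 1")
  if (image_size < 32) stop_input("image_size must be >= 32")
  if (length(class_texture_params) < 2 ||
      is.null(names(class_texture_params)))
    stop_input("class_texture_params must be a named list of >= 2 classes")
  structure(list(n_polyps_per_class = as.integer(n_polyps_per_class),
                 image_size = as.integer(image_size),
                 class_texture_params = class_texture_params,
                 highlight_density = highlight_density,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synthetic_polyp_spec")
}

#' Generate a synthetic polyp image set with ground truth
#'
#' @param spec A [synthetic_polyp_spec()].
#' @return List with `dataset` (a [polyp_dataset()], one image per polyp)
#'   and `ground_truth` (class label and logical highlight mask per image).
#' @export
generate_polyp_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_polyp_spec"))
  classes <- names(spec$class_texture_params)
  n_total <- spec$n_polyps_per_class * length(classes)
  samples <- vector("list", n_total)
  masks <- vector("list", n_total)
  labels <- character(n_total)
  with_seed(spec$seed, {
    idx <- 0L
    for (cls in classes) {
      tp <- spec$class_texture_params[[cls]]
      for (i in seq_len(spec$n_polyps_per_class)) {
        idx <- idx + 1L
        img <- render_base(spec$image_size)
        pat <- render_spots(spec$image_size, tp$spot_density,
                            tp$pattern_contrast) +
               render_ridges(spec$image_size, tp$tubule_frequency,
                             tp$pattern_contrast)
        for (c in 1:3) img[, , c] <- img[, , c] + pat
        if (spec$noise_sigma > 0)
          img <- img + array(stats::rnorm(length(img),
                                          sd = spec$noise_sigma), dim(img))
        # mucosal texture never saturates the sensor: cap below the
        # specular range so only rendered highlights occupy it
        img <- pmin(clip01(img), 0.93)
        mask <- matrix(FALSE, spec$image_size, spec$image_size)
        n_hl <- stats::rpois(1, spec$highlight_density)
        for (h in seq_len(n_hl)) {
          r <- spec$image_size * stats::runif(1, 0.02, 0.045)
          blob <- render_highlight_blob(
            img, cx = stats::runif(1, r + 2, spec$image_size - r - 2),
            cy = stats::runif(1, r + 2, spec$image_size - r - 2), r = r)
          img <- blob$image
          mask <- mask | blob$core
        }
        pid <- sprintf("%s_%03d", cls, i)
        samples[[idx]] <- image_sample(clip01(img), label = cls,
                                       polyp_id = pid, source = "synthetic")
        masks[[idx]] <- mask
        labels[idx] <- cls
      }
    }
  })
  list(dataset = polyp_dataset(samples, class_vocabulary = classes),
       ground_truth = list(labels = labels, highlight_masks = masks))
}

#' Generate a multilabel texture pretraining corpus
#'
#' A stand-in for a describable-textures corpus: each class is a randomly
#' drawn texture signature (oriented ridges or spot fields at a
#' class-specific frequency/density), and a chosen fraction of images
#' blends a second class's texture and carries both labels.
#'
#' @param n_classes Number of texture classes, >= 2.
#' @param n_images_per_class Images generated per class.
#' @param multilabel_fraction Fraction of all images that carry >= 2
#'   labels.
#' @param seed Integer seed.
#' @param image_size Square image side (default 64; texture pretraining
#'   does not need polyp-scale resolution).
#' @return A [polyp_dataset()] whose samples carry label-sets.
#' @export
generate_texture_corpus <- function(n_classes, n_images_per_class,
                                    multilabel_fraction = 0, seed = 1L,
                                    image_size = 64L) {
  if (n_classes < 2) stop_input("n_classes must be >= 2")
  if (multilabel_fraction < 0 || multilabel_fraction > 1)
    stop_input("multilabel_fraction must lie in [0, 1]")
  with_seed(seed, {
    class_names <- sprintf("texture_%02d", seq_len(n_classes))
    protos <- lapply(seq_len(n_classes), function(k)
      list(style = if (k %% 2 == 1) "ridges" else "spots",
           freq = stats::runif(1, 4, 13),
           density = stats::runif(1, 0.02, 0.06),
           theta_bias = stats::runif(1, 0, pi)))
    render_class <- function(k, contrast) {
      p <- protos[[k]]
      if (p$style == "ridges") render_ridges(image_size, p$freq, contrast)
      else render_spots(image_size, p$density, contrast)
    }
    n_total <- n_classes * n_images_per_class
    n_multi <- round(multilabel_fraction * n_total)
    multi_ids <- if (n_multi > 0) sample.int(n_total, n_multi) else integer(0)
    samples <- vector("list", n_total)
    idx <- 0L
    for (k in seq_len(n_classes)) {
      for (i in seq_len(n_images_per_class)) {
        idx <- idx + 1L
        img <- render_base(image_size)
        pat <- render_class(k, contrast = 0.8)
        labs <- class_names[k]
        if (idx %in% multi_ids) {
          k2 <- sample(setdiff(seq_len(n_classes), k), 1)
          pat <- pat + render_class(k2, contrast = 0.6)
          labs <- c(labs, class_names[k2])
        }
        for (c in 1:3) img[, , c] <- img[, , c] + pat
        img <- clip01(img + array(stats::rnorm(length(img), sd = 0.03),
                                  dim(img)))
        samples[[idx]] <- image_sample(img, label = labs,
                                       polyp_id = sprintf("tex_%04d", idx),
                                       source = "synthetic_texture")
      }
    }
    polyp_dataset(samples, class_vocabulary = class_names)
  })
}

#' Specification of a synthetic scene-structured video
#'
#' Emulates endoscopic footage as a camera traversing a large textured
#' world: frames within a scene view (almost) the same window up to small
#' translational jitter and per-frame gaussian blur; between scenes the
#' window jumps by `inter_scene_translation` pixels, changing content
#' beyond any feature-matching threshold. Exactly one planted frame per
#' scene is rendered unblurred and is therefore the sharpest in its scene.
#'
#' @param n_scenes Number of scenes, >= 1.
#' @param frames_per_scene Frames per scene, >= 1.
#' @param sharp_frame_index_per_scene 1-based index of the sharp frame in
#'   each scene (defaults to a random draw per scene).
#' @param inter_scene_translation Camera jump between scenes in pixels
#'   (default: one full frame width).
#' @param blur_sigma_range Blur sigmas (pixels) for non-sharp frames; the
#'   lower bound must exceed 0 so planted frames are strictly sharpest.
#' @param image_size Square frame side (default 64).
#' @param seed Integer seed.
#' @return A `synthetic_video_spec` object.
#' @export
synthetic_video_spec <- function(n_scenes = 3L, frames_per_scene = 10L,
                                 sharp_frame_index_per_scene = NULL,
                                 inter_scene_translation = NULL,
                                 blur_sigma_range = c(0.8, 2.2),
                                 image_size = 64L, seed = 1L) {
  if (n_scenes < 1) stop_input("n_scenes must be >= 1")
  if (frames_per_scene < 1) stop_input("frames_per_scene must be >= 1")
  if (blur_sigma_range[1] <= 0 || blur_sigma_range[1] > blur_sigma_range[2])
    stop_input("blur_sigma_range must be an interval with positive lower bound")
  if (!is.null(sharp_frame_index_per_scene)) {
    if (length(sharp_frame_index_per_scene) != n_scenes)
      stop_input("need one sharp-frame index per scene")
    if (any(sharp_frame_index_per_scene < 1 |
            sharp_frame_index_per_scene > frames_per_scene))
      stop_input("sharp frame indices must lie in 1..frames_per_scene")
  }
  structure(list(n_scenes = as.integer(n_scenes),
                 frames_per_scene = as.integer(frames_per_scene),
                 sharp_frame_index_per_scene = sharp_frame_index_per_scene,
                 inter_scene_translation =
                   as.integer(inter_scene_translation %||% image_size),
                 blur_sigma_range = blur_sigma_range,
                 image_size = as.integer(image_size),
                 seed = as.integer(seed)),
            class = "synthetic_video_spec")
}

#' Generate a synthetic video with planted scene structure
#'
#' @param spec A [synthetic_video_spec()].
#' @return List with `frames` (list of H x W x 3 arrays, scene by scene)
#'   and `ground_truth` holding 1-based `scene_boundaries` (first frame
#'   index of every scene after the first), `planted_keyframe_indices`,
#'   and `scene_of_frame`.
#' @export
generate_video <- function(spec) {
  stopifnot(inherits(spec, "synthetic_video_spec"))
  s <- spec$image_size
  jit <- 2L
  with_seed(spec$seed, {
    world_w <- s + (spec$n_scenes - 1L) * spec$inter_scene_translation +
      2L * jit
    world_h <- s + 2L * jit
    world <- array(0, c(world_h, world_w, 3L))
    base_col <- c(0.6, 0.55, 0.5)
    # coarse structure plus fine-grained detail: the detail layer is what
    # gaussian blur destroys, making the planted unblurred frame strictly
    # sharpest regardless of the small window jitter
    detail <- EBImage::gblur(matrix(stats::rnorm(world_h * world_w),
                                    world_h, world_w), sigma = 0.6)
    tex <- render_spots_rect(world_h, world_w, density = 0.08,
                             contrast = 0.9) +
           render_ridges_rect(world_h, world_w, freq = 10, contrast = 0.7) +
           0.25 * detail
    for (c in 1:3) world[, , c] <- clip01(base_col[c] + tex)
    sharp <- spec$sharp_frame_index_per_scene %||%
      sample.int(spec$frames_per_scene, spec$n_scenes, replace = TRUE)
    frames <- vector("list", spec$n_scenes * spec$frames_per_scene)
    idx <- 0L
    for (sc in seq_len(spec$n_scenes)) {
      x0 <- (sc - 1L) * spec$inter_scene_translation + jit
      for (f in seq_len(spec$frames_per_scene)) {
        idx <- idx + 1L
        dx <- sample(-jit:jit, 1L)
        dy <- sample(-jit:jit, 1L)
        fr <- world[(jit + dy) + seq_len(s), (x0 + dx) + seq_len(s), ,
                    drop = FALSE]
        if (f != sharp[sc]) {
          sig <- stats::runif(1, spec$blur_sigma_range[1],
                              spec$blur_sigma_range[2])
          fr <- EBImage::gblur(fr, sigma = sig)
        }
        frames[[idx]] <- clip01(fr)
      }
    }
    fps <- spec$frames_per_scene
    list(frames = frames,
         ground_truth = list(
           scene_boundaries = if (spec$n_scenes > 1)
             fps * seq_len(spec$n_scenes - 1L) + 1L else integer(0),
           planted_keyframe_indices = (seq_len(spec$n_scenes) - 1L) * fps +
             sharp,
           scene_of_frame = rep(seq_len(spec$n_scenes), each = fps)))
  })
}

# Rectangular variants used for the video world texture.
render_spots_rect <- function(h, w, density, contrast) {
  size <- max(h, w)
  render_spots(size, density, contrast)[seq_len(h), seq_len(w)]
}

render_ridges_rect <- function(h, w, freq, contrast) {
  size <- max(h, w)
  render_ridges(size, freq, contrast)[seq_len(h), seq_len(w)]
}

#' Generate a bank of specular highlight patches
#'
#' Each entry is a saturated near-white blob with a soft rim: a binary core
#' mask plus the RGB patch, suitable for [graft_highlights()].
#'
#' @param n Number of entries, >= 1.
#' @param size_range Patch side lengths in pixels, `c(min, max)`.
#' @param seed Integer seed.
#' @return List of [highlight_mask()] objects.
#' @export
generate_highlight_bank <- function(n, size_range = c(10L, 24L), seed = 1L) {
  if (n < 1) stop_input("n must be >= 1")
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      s <- round(stats::runif(1, size_range[1], size_range[2]))
      s <- max(6L, s)
      base <- array(rep(c(0.55, 0.45, 0.4), each = s * s), c(s, s, 3L))
      r <- 0.3 * s
      blob <- render_highlight_blob(base, cx = (s + 1) / 2, cy = (s + 1) / 2,
                                    r = r)
      highlight_mask(blob$core, clip01(blob$image))
    })
  })
}
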