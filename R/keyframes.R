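# Keyframe selection by keypoint matching: decompose a video into scenes
# wherever consecutive frames stop matching, then keep the sharpest frame
# of each scene. The detector/descriptor is of the ORB family: corner
# detection on a smoothed grayscale frame plus a BRIEF-style binary
# descriptor of pixel-intensity comparisons, matched by Hamming distance.

#' Keypoint detection and matching parameters
#'
#' @param n_keypoints Maximum corners kept per frame (default 500).
#' @param patch_radius Descriptor patch radius in pixels.
#' @param n_bits Descriptor length in bits.
#' @param max_hamming Maximum Hamming distance for an accepted match.
#' @param smooth_sigma Gaussian smoothing before gradient computation.
#' @param response_fraction Corner-response threshold as a fraction of the
#'   strongest response in the frame.
#' @return An `orb_params` object.
#' @export
orb_params <- function(n_keypoints = 500L, patch_radius = 8L, n_bits = 256L,
                       max_hamming = 64L, smooth_sigma = 1,
                       response_fraction = 0.005) {
  structure(list(n_keypoints = as.integer(n_keypoints),
                 patch_radius = as.integer(patch_radius),
                 n_bits = as.integer(n_bits),
                 max_hamming = as.integer(max_hamming),
                 smooth_sigma = smooth_sigma,
                 response_fraction = response_fraction),
            class = "orb_params")
}

as_gray_frame <- function(frame) {
  if (is.matrix(frame)) frame else rgb_to_gray(frame)
}

# Fixed BRIEF sampling pattern (deterministic package constant).
brief_pattern <- local({
  cache <- new.env(parent = emptyenv())
  function(n_bits, patch_radius) {
    key <- sprintf("%d_%d", n_bits, patch_radius)
    if (is.null(cache[[key]])) {
      cache[[key]] <- with_seed(987654L, {
        draw <- function() {
          v <- round(stats::rnorm(n_bits, sd = patch_radius / 2.5))
          pmin(pmax(v, -patch_radius), patch_radius)
        }
        list(y1 = draw(), x1 = draw(), y2 = draw(), x2 = draw())
      })
    }
    cache[[key]]
  }
})

# Harris corners + binary descriptors for one frame.
orb_features <- function(frame, params = orb_params()) {
  g <- as_gray_frame(frame)
  H <- nrow(g); W <- ncol(g)
  gs <- EBImage::gblur(g, sigma = params$smooth_sigma)
  ix <- matrix(0, H, W); iy <- matrix(0, H, W)
  ix[, 2:(W - 1)] <- (gs[, 3:W] - gs[, 1:(W - 2)]) / 2
  iy[2:(H - 1), ] <- (gs[3:H, ] - gs[1:(H - 2), ]) / 2
  sxx <- EBImage::gblur(ix * ix, sigma = 1.5)
  syy <- EBImage::gblur(iy * iy, sigma = 1.5)
  sxy <- EBImage::gblur(ix * iy, sigma = 1.5)
  resp <- (sxx * syy - sxy^2) - 0.04 * (sxx + syy)^2
  rmax <- max(resp)
  if (!is.finite(rmax) || rmax <= 1e-12)
    return(list(n = 0L, desc = NULL, keypoints = NULL))
  localmax <- resp >= EBImage::dilate(resp, EBImage::makeBrush(3L, "box")) - 1e-15
  border <- params$patch_radius + 2L
  ok <- localmax & resp > params$response_fraction * rmax
  ok[c(seq_len(border), H - seq_len(border) + 1L), ] <- FALSE
  ok[, c(seq_len(border), W - seq_len(border) + 1L)] <- FALSE
  if (!any(ok)) return(list(n = 0L, desc = NULL, keypoints = NULL))
  pos <- which(ok, arr.ind = TRUE)
  vals <- resp[ok]
  keep <- order(vals, decreasing = TRUE)[seq_len(min(length(vals),
                                                     params$n_keypoints))]
  pos <- pos[keep, , drop = FALSE]
  gd <- EBImage::gblur(g, sigma = 2)
  pat <- brief_pattern(params$n_bits, params$patch_radius)
  k <- nrow(pos)
  desc <- matrix(0L, k, params$n_bits)
  for (b in seq_len(params$n_bits)) {
    v1 <- gd[cbind(pos[, 1] + pat$y1[b], pos[, 2] + pat$x1[b])]
    v2 <- gd[cbind(pos[, 1] + pat$y2[b], pos[, 2] + pat$x2[b])]
    desc[, b] <- as.integer(v1 < v2)
  }
  list(n = k, desc = desc, keypoints = pos)
}

match_from_features <- function(fa, fb, params) {
  if (fa$n == 0L || fb$n == 0L) {
    score <- 0
    attr(score, "no_keypoints") <- TRUE
    return(score)
  }
  A <- fa$desc; B <- fb$desc
  dist <- A %*% t(1L - B) + (1L - A) %*% t(B)  # Hamming
  nn_ab <- apply(dist, 1L, which.min)
  nn_ba <- apply(dist, 2L, which.min)
  mutual <- which(nn_ba[nn_ab] == seq_len(fa$n))
  dmin <- dist[cbind(mutual, nn_ab[mutual])]
  mutual <- mutual[dmin <= params$max_hamming]
  if (!length(mutual)) return(0)
  # geometric verification: genuine frame-to-frame matches agree on a
  # common translation, coincidental descriptor matches do not
  dy <- fb$keypoints[nn_ab[mutual], 1] - fa$keypoints[mutual, 1]
  dx <- fb$keypoints[nn_ab[mutual], 2] - fa$keypoints[mutual, 2]
  inlier <- abs(dy - stats::median(dy)) <= 4 & abs(dx - stats::median(dx)) <= 4
  sum(inlier) / min(fa$n, fb$n)
}

#' Feature-matching score between two frames
#'
#' The fraction of accepted descriptor matches (mutual nearest neighbours
#' within the Hamming budget) relative to the keypoint count of the
#' poorer frame; 0 when either frame yields no keypoints (flagged with
#' attribute `no_keypoints`).
#'
#' @param frame_a,frame_b Same-size RGB arrays or grayscale matrices.
#' @param params An [orb_params()].
#' @return Score in \[0, 1\].
#' @export
match_score <- function(frame_a, frame_b, params = orb_params()) {
  ga <- as_gray_frame(frame_a); gb <- as_gray_frame(frame_b)
  if (!identical(dim(ga), dim(gb)))
    stop_input("frames differ in size: %s vs %s",
               paste(dim(ga), collapse = "x"), paste(dim(gb), collapse = "x"))
  match_from_features(orb_features(ga, params), orb_features(gb, params),
                      params)
}

#' Sharpness of a frame
#'
#' Variance of the Laplacian of the grayscale frame: gaussian blurring a
#' frame strictly reduces it, and a constant frame scores 0.
#'
#' @param frame RGB array or grayscale matrix.
#' @return Non-negative scalar.
#' @export
sharpness <- function(frame) {
  g <- as_gray_frame(frame)
  H <- nrow(g); W <- ncol(g)
  if (H < 3 || W < 3) return(0)
  lap <- 4 * g[2:(H - 1), 2:(W - 1)] - g[1:(H - 2), 2:(W - 1)] -
    g[3:H, 2:(W - 1)] - g[2:(H - 1), 1:(W - 2)] - g[2:(H - 1), 3:W]
  stats::var(as.vector(lap))
}

#' Decompose a video into scenes and select keyframes
#'
#' A new scene starts whenever the matching score between consecutive
#' frames falls below `match_threshold`; within each scene the frame with
#' the highest [sharpness()] is the keyframe (ties resolved to the
#' earliest frame). Frame indices are 1-based.
#'
#' @param frames Ordered list of frames (RGB arrays or grayscale
#'   matrices), or a `generate_video()` result.
#' @param match_threshold Scene-cut threshold on the match score
#'   (default 0.15).
#' @param params An [orb_params()].
#' @return A `scene_decomposition`: `frame_count`, `boundaries` (first
#'   frame of every scene after the first), `keyframes` (one per scene),
#'   `match_scores` (length `frame_count - 1`), `scene_of_frame`.
#' @export
select_keyframes <- function(frames, match_threshold = 0.15,
                             params = orb_params()) {
  if (is.list(frames) && !is.null(frames$frames)) frames <- frames$frames
  n <- length(frames)
  if (n < 1) stop_input("no frames supplied")
  feats <- lapply(frames, orb_features, params = params)
  scores <- if (n > 1)
    vapply(seq_len(n - 1), function(i)
      as.numeric(match_from_features(feats[[i]], feats[[i + 1]], params)), 0)
  else numeric(0)
  boundaries <- which(scores < match_threshold) + 1L
  starts <- c(1L, boundaries)
  ends <- c(boundaries - 1L, n)
  sharp <- vapply(frames, sharpness, 0)
  keyframes <- vapply(seq_along(starts), function(s) {
    idx <- starts[s]:ends[s]
    idx[which.max(sharp[idx])]
  }, 0L)
  scene_of_frame <- rep(seq_along(starts), times = ends - starts + 1L)
  structure(list(frame_count = n, boundaries = boundaries,
                 keyframes = keyframes, match_scores = scores,
                 sharpness = sharp, scene_of_frame = scene_of_frame),
            class = "scene_decomposition")
}

#' @export
print.scene_decomposition <- function(x, ...) {
  cat(sprintf("<scene_decomposition> %d frames, %d scenes\n",
              x$frame_count, length(x$keyframes)))
  cat("  keyframes:", paste(x$keyframes, collapse = ", "), "\n")
  invisible(x)
}
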