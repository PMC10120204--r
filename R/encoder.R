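#' Build an image embedding encoder
#'
#' Constructs the encoder `f` that maps a square RGB image to an
#' `embedding_dim`-dimensional real vector. The architecture follows the
#' deep-metric-learning template: a convolutional feature-extraction
#' backbone, global average pooling of the final feature map, and a single
#' affine encoding layer into the latent space (64-dimensional by default).
#'
#' The backbone is a stack of `length(channels)` blocks, each a 3x3
#' convolution, ReLU, and 2x2 average pooling, so `input_size` must be
#' divisible by `2^length(channels)`. Small configurations (e.g.
#' `input_size = 32`, `channels = c(8, 16)`) train in seconds on a CPU and
#' are the test-scale default throughout the package documentation; wider
#' and deeper stacks are the production configuration.
#'
#' @param input_size Side length in pixels of the (square) input images.
#' @param channels Integer vector of feature-map widths, one per conv block.
#' @param embedding_dim Dimension n of the embedding space (default 64).
#' @param seed Optional integer; fixes the random weight initialization.
#' @param weights Optional path to a checkpoint written by
#'   [save_encoder()]; when given, architecture fields are taken from the
#'   checkpoint and all other arguments are ignored.
#' @return An object of class `embedding_model`.
#' @examples
#' enc <- build_encoder(input_size = 32, channels = c(4, 8),
#'                      embedding_dim = 8, seed = 1)
#' z <- embed(enc, array(runif(32 * 32 * 3), c(32, 32, 3)))
#' dim(z)  # 1 x 8
#' @export
build_encoder <- function(input_size = 224, channels = c(16, 32, 64, 128),
                          embedding_dim = 64, seed = NULL, weights = NULL) {
  if (!is.null(weights)) return(load_encoder(weights))
  if (embedding_dim < 1) stop_input("embedding_dim must be >= 1")
  if (length(channels) < 1) stop_input("at least one conv block is required")
  if (input_size %% (2^length(channels)) != 0)
    stop_input("input_size (%d) must be divisible by 2^%d",
               input_size, length(channels))
  with_seed(seed, {
    in_ch <- 3L
    conv <- vector("list", length(channels))
    for (l in seq_along(channels)) {
      fan_in <- 9L * in_ch
      conv[[l]] <- list(
        W = matrix(stats::rnorm(fan_in * channels[l], sd = sqrt(2 / fan_in)),
                   fan_in, channels[l]),
        b = rep(0, channels[l]))
      in_ch <- channels[l]
    }
    head <- list(
      W = matrix(stats::rnorm(in_ch * embedding_dim, sd = sqrt(1 / in_ch)),
                 in_ch, embedding_dim),
      b = rep(0, embedding_dim))
    structure(list(input_size = as.integer(input_size),
                   channels = as.integer(channels),
                   embedding_dim = as.integer(embedding_dim),
                   params = list(conv = conv, head = head),
                   class_vocabulary = NULL),
              class = "embedding_model")
  })
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model> %dx%d RGB -> %d-d embedding\n",
              x$input_size, x$input_size, x$embedding_dim))
  cat(sprintf("  backbone: %s conv blocks (channels %s)\n",
              length(x$channels), paste(x$channels, collapse = ", ")))
  invisible(x)
}

# Full forward pass. x: (S, S, 3, N). Returns embeddings and, optionally,
# the per-layer caches needed for backpropagation.
encoder_forward <- function(model, x, keep_cache = FALSE) {
  d <- dim(x)
  if (d[1] != model$input_size || d[2] != model$input_size || d[3] != 3L)
    stop_input("expected %dx%dx3 input images, got %s",
               model$input_size, model$input_size, paste(d[1:3], collapse = "x"))
  cache <- if (keep_cache) vector("list", length(model$params$conv))
  for (l in seq_along(model$params$conv)) {
    p <- model$params$conv[[l]]
    dl <- dim(x)
    cf <- nn_conv_forward(x, p$W, p$b)
    act <- pmax(cf$out, 0)
    if (keep_cache)
      cache[[l]] <- list(cols = cf$cols, mask = cf$out > 0,
                         H = dl[1], W = dl[2], C = dl[3], N = dl[4],
                         act_dims = dim(act))
    x <- nn_avgpool2(act)
  }
  A <- nn_gap(x)
  z <- A %*% model$params$head$W +
    matrix(model$params$head$b, nrow(A), model$embedding_dim, byrow = TRUE)
  list(z = z, conv_cache = cache, A = A, gap_dims = dim(x))
}

# Backward pass; dz is N x embedding_dim. Returns gradients shaped like
# model$params.
encoder_backward <- function(model, fw, dz) {
  head <- model$params$head
  gh <- list(W = crossprod(fw$A, dz), b = colSums(dz))
  dx <- nn_gap_backward(dz %*% t(head$W), fw$gap_dims)
  gconv <- vector("list", length(model$params$conv))
  for (l in rev(seq_along(model$params$conv))) {
    cc <- fw$conv_cache[[l]]
    dact <- nn_avgpool2_backward(dx, cc$act_dims[1], cc$act_dims[2])
    dpre <- dact * cc$mask
    bk <- nn_conv_backward(dpre, cc$cols, model$params$conv[[l]]$W,
                           cc$H, cc$W, cc$C, cc$N)
    gconv[[l]] <- list(W = bk$dW, b = bk$db)
    dx <- bk$dx
  }
  list(conv = gconv, head = gh)
}

#' Embed images into the latent space
#'
#' Applies the encoder in inference mode. Deterministic: the same model and
#' images always produce the same matrix, and batching does not change the
#' result beyond floating-point round-off.
#'
#' @param model An `embedding_model`.
#' @param images A single H x W x 3 array, a list of such arrays, a list of
#'   `image_sample` objects, or a `polyp_dataset`.
#' @param batch_size Images per forward pass (memory knob only).
#' @return A numeric matrix with one embedding row per image.
#' @export
embed <- function(model, images, batch_size = 64L) {
  if (inherits(images, "polyp_dataset")) images <- images$samples
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  if (length(images) && inherits(images[[1]], "image_sample"))
    images <- sample_pixels(images)
  n <- length(images)
  out <- matrix(0, n, model$embedding_dim)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    x <- stack_images(images[i:j])
    out[i:j, ] <- encoder_forward(model, x)$z
    i <- j + 1L
  }
  out
}

#' Save / load encoder checkpoints
#'
#' A checkpoint bundles the architecture description, all trained weights,
#' and the class vocabulary the model was fine-tuned against (if any), so a
#' reloaded model reproduces embeddings bit for bit.
#'
#' @param model An `embedding_model`.
#' @param path File path for the checkpoint.
#' @return `save_encoder` returns `path` invisibly; `load_encoder` returns
#'   the restored `embedding_model`.
#' @export
save_encoder <- function(model, path) {
  stopifnot(inherits(model, "embedding_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  if (!file.exists(path)) stop_input("checkpoint not found: %s", path)
  structure(readRDS(path), class = "embedding_model")
}
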