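# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Run code under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive k reproducible child seeds from one parent seed (kept below 2^31).
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

assert_image <- function(img, name = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop_input("%s must be an H x W x 3 array", name)
  if (anyNA(img)) stop_input("%s contains missing values", name)
  invisible(img)
}

#' Convert an RGB image to luminance
#'
#' Rec. 601 luma weights; input is an H x W x 3 array in \[0, 1\].
#' @param img RGB array.
#' @return H x W matrix of gray values.
#' @keywords internal
rgb_to_gray <- function(img) {
  assert_image(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Stack a list of H x W x 3 images into the internal (H, W, C, N) tensor.
stack_images <- function(images) {
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  n <- length(images)
  if (n == 0L) stop_input("empty image list")
  d <- dim(images[[1]])
  out <- array(0, c(d[1], d[2], d[3], n))
  for (i in seq_len(n)) {
    di <- dim(images[[i]])
    if (!identical(di, d)) stop_input("image %d has shape %s, expected %s",
                                      i, paste(di, collapse = "x"),
                                      paste(d, collapse = "x"))
    out[, , , i] <- images[[i]]
  }
  out
}

sample_pixels <- function(samples) lapply(samples, function(s) s$pixels)
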