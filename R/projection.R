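#' Project embeddings to 2-D for inspection
#'
#' Produces one 2-D coordinate per embedding for error analysis and
#' cluster visualization; the projection is never used in any metric.
#' The default is an exact t-SNE (suitable for the few hundred points a
#' few-shot study produces) with deterministic output under a fixed seed;
#' `method = "pca"` gives the first two principal components.
#'
#' @param embeddings Numeric matrix with >= 3 rows.
#' @param seed Integer seed for the t-SNE initialization.
#' @param method `"tsne"` (default) or `"pca"`.
#' @param perplexity t-SNE perplexity; capped at `(n - 1) / 3`.
#' @param n_iter Gradient-descent iterations.
#' @return An n x 2 matrix of coordinates.
#' @export
project_2d <- function(embeddings, seed = 1L, method = c("tsne", "pca"),
                       perplexity = 30, n_iter = 400L) {
  method <- match.arg(method)
  x <- as.matrix(embeddings)
  if (nrow(x) < 3) stop_input("projection needs >= 3 points")
  if (method == "pca") {
    p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    k <- min(2L, ncol(p$x))
    out <- matrix(0, nrow(x), 2L)
    out[, seq_len(k)] <- p$x[, seq_len(k)]
    colnames(out) <- c("x", "y")
    return(out)
  }
  tsne_exact(x, seed = seed, perplexity = perplexity, n_iter = n_iter)
}

# Exact t-SNE, O(n^2); fine for the data sizes this package targets.
tsne_exact <- function(x, seed, perplexity, n_iter) {
  n <- nrow(x)
  perplexity <- max(2, min(perplexity, (n - 1) / 3))
  d2 <- cross_dist2(x, x)
  diag(d2) <- Inf
  P <- matrix(0, n, n)
  log_perp <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- 0; hi <- Inf
    for (iter in 1:50) {
      p <- exp(-d2[i, ] * beta)
      s <- sum(p)
      if (s <= 0) { beta <- beta / 2; hi <- beta * 2; next }
      p <- p / s
      h <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(h - log_perp) < 1e-5) break
      if (h > log_perp) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (beta + lo) / 2 }
    }
    P[i, ] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  y <- with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  gain <- matrix(1, n, 2); inc <- matrix(0, n, 2)
  momentum <- 0.5; eta <- 100
  exaggeration <- 4
  Puse <- P * exaggeration
  for (it in seq_len(n_iter)) {
    if (it == 101L) Puse <- P
    if (it == 21L) momentum <- 0.8
    num <- 1 / (1 + cross_dist2(y, y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Puse - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% y
    gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    inc <- momentum * inc - eta * gain * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
  }
  colnames(y) <- c("x", "y")
  y
}
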