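# Minimal convolutional-network engine used by the embedding encoder.
#
# Tensors are arrays with dims (H, W, C, N). Convolutions are 3x3, stride 1,
# zero padding 1, realized as im2col + matrix multiply so the heavy lifting
# runs through BLAS. Pooling is 2x2 average pooling (differentiable
# everywhere, which keeps gradient checks clean).

nn_pad1 <- function(x) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  xp[2:(d[1] + 1L), 2:(d[2] + 1L), , ] <- x
  xp
}

# Gather 3x3 neighbourhoods: rows ordered (i, j, n) with i fastest; columns
# ordered (di, dj, c) with di fastest. Weight matrices use the same layout.
nn_im2col <- function(xp, H, W) {
  C <- dim(xp)[3]
  N <- dim(xp)[4]
  cols <- matrix(0, H * W * N, 9L * C)
  k <- 0L
  for (c in seq_len(C)) for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    cols[, k] <- xp[di + seq_len(H), dj + seq_len(W), c, ]
  }
  cols
}

nn_conv_forward <- function(x, Wmat, b) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; N <- d[4]
  cols <- nn_im2col(nn_pad1(x), H, W)
  out <- cols %*% Wmat
  out <- out + matrix(b, nrow(out), length(b), byrow = TRUE)
  cout <- length(b)
  list(out = aperm(array(out, c(H, W, N, cout)), c(1L, 2L, 4L, 3L)),
       cols = cols)
}

nn_conv_backward <- function(dout, cols, Wmat, H, W, C, N) {
  cout <- dim(dout)[3]
  dmat <- matrix(aperm(dout, c(1L, 2L, 4L, 3L)), H * W * N, cout)
  dW <- crossprod(cols, dmat)
  db <- colSums(dmat)
  dcols <- dmat %*% t(Wmat)
  dxp <- array(0, c(H + 2L, W + 2L, C, N))
  k <- 0L
  for (c in seq_len(C)) for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    dxp[di + seq_len(H), dj + seq_len(W), c, ] <-
      dxp[di + seq_len(H), dj + seq_len(W), c, ] + array(dcols[, k], c(H, W, N))
  }
  list(dx = dxp[2:(H + 1L), 2:(W + 1L), , , drop = FALSE], dW = dW, db = db)
}

nn_avgpool2 <- function(x) {
  d <- dim(x)
  i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
  (x[i1, j1, , , drop = FALSE] + x[i1 + 1L, j1, , , drop = FALSE] +
     x[i1, j1 + 1L, , , drop = FALSE] + x[i1 + 1L, j1 + 1L, , , drop = FALSE]) / 4
}

nn_avgpool2_backward <- function(d, H, W) {
  dd <- dim(d)
  dx <- array(0, c(H, W, dd[3], dd[4]))
  g <- d / 4
  i1 <- seq(1L, H, 2L); j1 <- seq(1L, W, 2L)
  dx[i1, j1, , ] <- g
  dx[i1 + 1L, j1, , ] <- g
  dx[i1, j1 + 1L, , ] <- g
  dx[i1 + 1L, j1 + 1L, , ] <- g
  dx
}

# Global average pooling: (H, W, C, N) -> N x C.
nn_gap <- function(x) {
  d <- dim(x)
  t(matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
}

nn_gap_backward <- function(dA, dims) {
  val <- t(dA) / (dims[1] * dims[2])        # C x N
  array(rep(as.vector(val), each = dims[1] * dims[2]), dims)
}

# Adam optimizer over the two-level parameter structure
# list(conv = list(list(W, b), ...), head = list(W, b)).
nn_adam_init <- function(params) {
  list(m = rapply(params, function(v) v * 0, how = "replace"),
       v = rapply(params, function(v) v * 0, how = "replace"),
       t = 0L)
}

nn_adam_step <- function(params, grads, state, lr,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- mapply(walk, p, g, m, v, SIMPLIFY = FALSE)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      upd(p, g, m, v)
    }
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

nn_grads_add <- function(a, b) {
  if (is.list(a)) mapply(nn_grads_add, a, b, SIMPLIFY = FALSE) else a + b
}

nn_grads_scale <- function(a, s) {
  if (is.list(a)) lapply(a, nn_grads_scale, s = s) else a * s
}
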