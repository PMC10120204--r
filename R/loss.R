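#' Triplet loss configuration
#'
#' The contrastive triplet loss pairs an absolute margin `m` with a metric
#' `D` on the embedding space:
#' \deqn{L(a, p, n) = D(f(a), f(p)) + max(0, m - D(f(a), f(n)))}
#' The margin limits the loss decrease obtainable by pushing the negative
#' arbitrarily far away, which prevents the encoder from degenerating into
#' an ever-expanding map. Defaults are margin 20 with the l2 metric.
#'
#' @param margin Non-negative margin m, in embedding-distance units.
#' @param metric `"l2"` (euclidean, default) or `"cosine"` (1 - cosine
#'   similarity).
#' @return A `triplet_loss_config` list.
#' @export
triplet_loss_config <- function(margin = 20, metric = c("l2", "cosine")) {
  metric <- match.arg(metric)
  if (!is.numeric(margin) || length(margin) != 1L || margin < 0)
    stop_input("margin must be a single non-negative number")
  structure(list(margin = margin, metric = metric),
            class = "triplet_loss_config")
}

as_row_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1L) else unname(as.matrix(x))
}

embedding_distance <- function(a, b, metric) {
  a <- as_row_matrix(a); b <- as_row_matrix(b)
  if (!identical(dim(a), dim(b)))
    stop_input("embedding dimensions differ: %s vs %s",
               paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  if (metric == "l2") {
    sqrt(rowSums((a - b)^2))
  } else {
    na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
    1 - rowSums(a * b) / pmax(na * nb, 1e-12)
  }
}

#' Contrastive triplet loss
#'
#' Evaluates \eqn{D(z_a, z_p) + max(0, m - D(z_a, z_n))} for one triplet of
#' embedding vectors or row-wise for matrices of embeddings.
#'
#' @param z_anchor,z_positive,z_negative Embedding vectors (or matrices with
#'   one embedding per row).
#' @param cfg A [triplet_loss_config()].
#' @return Non-negative loss value(s), one per triplet.
#' @examples
#' cfg <- triplet_loss_config(margin = 20, metric = "l2")
#' triplet_loss(c(0, 0), c(3, 4), c(1, 0), cfg)  # 5 + (20 - 1) = 24
#' @export
triplet_loss <- function(z_anchor, z_positive, z_negative,
                         cfg = triplet_loss_config()) {
  stopifnot(inherits(cfg, "triplet_loss_config"))
  dp <- embedding_distance(z_anchor, z_positive, cfg$metric)
  dn <- embedding_distance(z_anchor, z_negative, cfg$metric)
  dp + pmax(0, cfg$margin - dn)
}

# Loss plus gradients w.r.t. the three embedding matrices (rows = triplets).
# Used by the training loop; the max() hinge uses the subgradient 0 at the
# kink, and the l2 distance gradient is guarded at coincident points.
triplet_loss_grad <- function(za, zp, zn, cfg) {
  za <- as_row_matrix(za); zp <- as_row_matrix(zp); zn <- as_row_matrix(zn)
  eps <- 1e-12
  if (cfg$metric == "l2") {
    dap <- za - zp
    dan <- za - zn
    dp <- sqrt(rowSums(dap^2))
    dn <- sqrt(rowSums(dan^2))
    loss <- dp + pmax(0, cfg$margin - dn)
    gp <- dap / pmax(dp, eps)              # d dp / d za
    active <- as.numeric(dn < cfg$margin)  # hinge active
    gn <- dan / pmax(dn, eps) * active
    list(loss = loss,
         d_anchor = gp - gn,
         d_positive = -gp,
         d_negative = gn)
  } else {
    grad_cos <- function(a, b) {
      # gradient of D = 1 - <a,b>/(|a||b|) w.r.t. a and b
      na <- pmax(sqrt(rowSums(a^2)), eps)
      nb <- pmax(sqrt(rowSums(b^2)), eps)
      dot <- rowSums(a * b)
      da <- -(b / (na * nb) - a * dot / (na^3 * nb))
      db <- -(a / (na * nb) - b * dot / (nb^3 * na))
      list(da = da, db = db, d = 1 - dot / (na * nb))
    }
    p <- grad_cos(za, zp)
    n <- grad_cos(za, zn)
    active <- as.numeric(n$d < cfg$margin)
    list(loss = p$d + pmax(0, cfg$margin - n$d),
         d_anchor = p$da - n$da * active,
         d_positive = p$db,
         d_negative = -n$db * active)
  }
}
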