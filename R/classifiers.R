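# Downstream discriminators over the embedding space. The embedded
# training images serve as the latent-space population; queries are
# classified by nearest neighbour, by nearest class reference (centroid),
# or by an RBF-kernel SVM fitted on the embeddings.

#' Fit a classifier head on embeddings
#'
#' @param kind One of `"one_nn"`, `"centroid"`, `"svm_rbf"`.
#' @param embeddings Numeric matrix, one embedding per row.
#' @param labels Character vector of class labels (>= 2 classes).
#' @param params Optional list of head parameters:
#'   * centroid: `rule = "class_mean"` (default; assign to the nearest
#'     class mean) or `"mean_distance"` (assign to the class with the
#'     smallest average distance to its members).
#'   * svm_rbf: `cost` (default 1) and `gamma` (default: median
#'     heuristic, `1 / (2 * median squared pairwise distance)`).
#'     Embeddings are deliberately not standardized: their scale is
#'     meaningful relative to the training margin.
#' @param class_vocabulary Ordered class ids; ties are broken towards the
#'   earlier class in this ordering.
#' @return A `classifier_head` object.
#' @export
fit_head <- function(kind = c("one_nn", "centroid", "svm_rbf"),
                     embeddings, labels, params = list(),
                     class_vocabulary = NULL) {
  kind <- match.arg(kind)
  embeddings <- as.matrix(embeddings)
  labels <- as.character(labels)
  if (nrow(embeddings) != length(labels))
    stop_input("embeddings and labels disagree in length")
  if (is.null(class_vocabulary)) class_vocabulary <- sort(unique(labels))
  if (length(unique(labels)) < 2)
    stop_input("classifier heads require >= 2 classes in the training data")
  state <- switch(kind,
    one_nn = list(train = embeddings, labels = labels),
    centroid = {
      rule <- params$rule %||% "class_mean"
      if (!rule %in% c("class_mean", "mean_distance"))
        stop_input("unknown centroid rule: %s", rule)
      cls <- class_vocabulary[class_vocabulary %in% labels]
      centroids <- t(vapply(cls, function(cl)
        colMeans(embeddings[labels == cl, , drop = FALSE]),
        numeric(ncol(embeddings))))
      rownames(centroids) <- cls
      list(rule = rule, centroids = centroids,
           train = embeddings, labels = labels)
    },
    svm_rbf = {
      cost <- params$cost %||% 1
      gamma <- params$gamma %||% {
        d2 <- as.numeric(stats::dist(embeddings))^2
        med <- stats::median(d2)
        if (med > 0) 1 / (2 * med) else 1 / ncol(embeddings)
      }
      fit <- e1071::svm(x = embeddings,
                        y = factor(labels, levels = class_vocabulary),
                        kernel = "radial", cost = cost, gamma = gamma,
                        scale = FALSE)
      list(fit = fit, cost = cost, gamma = gamma)
    })
  structure(list(kind = kind, state = state,
                 dim = ncol(embeddings),
                 class_vocabulary = class_vocabulary),
            class = "classifier_head")
}

#' Predict labels for query embeddings
#'
#' Deterministic given the fitted head. Exact distance ties are broken
#' towards the lowest training-sample index (1-nn) or the earliest class
#' in the vocabulary (centroid).
#'
#' @param object A `classifier_head`.
#' @param embeddings Query matrix with matching dimensionality.
#' @param ... Unused.
#' @return Character vector of predicted labels, one per query row.
#' @export
predict.classifier_head <- function(object, embeddings, ...) {
  embeddings <- as_row_matrix(embeddings)
  if (ncol(embeddings) != object$dim)
    stop_input("query dimensionality %d does not match head dimensionality %d",
               ncol(embeddings), object$dim)
  st <- object$state
  switch(object$kind,
    one_nn = {
      d <- cross_dist2(embeddings, st$train)
      st$labels[apply(d, 1L, which.min)]
    },
    centroid = {
      d <- if (st$rule == "class_mean") {
        cross_dist2(embeddings, st$centroids)
      } else {
        dall <- sqrt(cross_dist2(embeddings, st$train))
        cls <- rownames(st$centroids)
        vapply(cls, function(cl)
          rowMeans(dall[, st$labels == cl, drop = FALSE]),
          numeric(nrow(embeddings)))
      }
      d <- as_row_matrix(d)
      rownames(st$centroids)[apply(d, 1L, which.min)]
    },
    svm_rbf = as.character(stats::predict(st$fit, embeddings)))
}

# Squared euclidean cross-distance matrix (rows of a vs rows of b).
cross_dist2 <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d, 0)
}

#' Intra- and inter-class variances of an embedding
#'
#' The diagnostic behind compact-cluster analysis: `intra(c)` is the mean
#' squared l2 deviation of class-c embeddings from their class mean, and
#' `inter` is the mean squared l2 deviation of the class means from the
#' global mean of class means. All reported values are divided by the raw
#' inter-class variance, so the normalized inter-class variance is exactly
#' 1; a division-by-zero (all class means coincident) is reported as an
#' error, never silently.
#'
#' @param embeddings Numeric matrix, one embedding per row.
#' @param labels Class label per row (>= 2 classes, no empty class).
#' @return A `variance_report`: `intra` (named, normalized), `inter` (1),
#'   and the `raw` unnormalized values.
#' @export
class_variances <- function(embeddings, labels) {
  embeddings <- as.matrix(embeddings)
  labels <- as.character(labels)
  if (nrow(embeddings) != length(labels))
    stop_input("embeddings and labels disagree in length")
  cls <- unique(labels)
  if (length(cls) < 2) stop_input("variance report requires >= 2 classes")
  means <- t(vapply(cls, function(cl) {
    rows <- embeddings[labels == cl, , drop = FALSE]
    if (!nrow(rows)) stop_input("class '%s' is empty", cl)
    colMeans(rows)
  }, numeric(ncol(embeddings))))
  intra <- vapply(cls, function(cl) {
    rows <- embeddings[labels == cl, , drop = FALSE]
    mean(rowSums((rows - matrix(means[cl, ], nrow(rows), ncol(rows),
                                byrow = TRUE))^2))
  }, 0)
  grand <- colMeans(means)
  inter <- mean(rowSums((means - matrix(grand, nrow(means), ncol(means),
                                        byrow = TRUE))^2))
  if (inter <= 0)
    stop_input("inter-class variance is zero; normalization undefined")
  structure(list(intra = intra / inter, inter = 1,
                 raw = list(intra = intra, inter = inter)),
            class = "variance_report")
}

#' @export
print.variance_report <- function(x, ...) {
  cat("<variance_report> inter-class variance normalized to 1\n")
  for (cl in names(x$intra))
    cat(sprintf("  intra %-12s %.3f\n", cl, x$intra[cl]))
  invisible(x)
}
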