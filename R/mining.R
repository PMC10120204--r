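# Triplet construction under the three regimes used for training:
# class-supervised, multilabel class-disjoint, and self-supervised
# augmented-view. Mining is uniform over valid choices -- no hard-negative
# mining (informative mining is deliberately not used here; a custom miner
# can be substituted wherever a triplet source is accepted).

new_triplet <- function(anchor, positive, negative, regime) {
  structure(list(anchor = anchor, positive = positive, negative = negative,
                 regime = regime), class = "triplet")
}

# Index-level supervised miner: uniform anchor class among classes with
# >= 2 samples, anchor != positive, negative from a different class.
mine_supervised_idx <- function(labels, n_triplets) {
  classes <- unique(labels)
  if (length(classes) < 2)
    stop_input("supervised mining needs >= 2 classes, got %d",
               length(classes))
  counts <- table(labels)
  anchor_classes <- names(counts)[counts >= 2]
  if (!length(anchor_classes))
    stop_input("no class has >= 2 samples; cannot form anchor-positive pairs")
  by_class <- split(seq_along(labels), labels)
  out <- matrix(0L, n_triplets, 3L)
  for (t in seq_len(n_triplets)) {
    ca <- sample(anchor_classes, 1L)
    pair <- sample(by_class[[ca]], 2L)
    neg_pool <- which(labels != ca)
    out[t, ] <- c(pair[1L], pair[2L], neg_pool[sample.int(length(neg_pool), 1L)])
  }
  out
}

# Multilabel miner: positive shares >= 1 label with the anchor (and is a
# different sample); negative's label-set is disjoint from the anchor's.
mine_multilabel_idx <- function(label_sets, n_triplets) {
  n <- length(label_sets)
  overlaps <- function(a, b) length(intersect(a, b)) > 0
  # anchors admitting both a positive and a class-disjoint negative
  valid_anchor <- vapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    any(vapply(others, function(j)
      overlaps(label_sets[[i]], label_sets[[j]]), TRUE)) &&
      any(vapply(others, function(j)
        !overlaps(label_sets[[i]], label_sets[[j]]), TRUE))
  }, TRUE)
  if (!any(valid_anchor))
    stop_input("no anchor admits a class-disjoint negative; mining impossible")
  anchors <- which(valid_anchor)
  out <- matrix(0L, n_triplets, 3L)
  for (t in seq_len(n_triplets)) {
    a <- anchors[sample.int(length(anchors), 1L)]
    others <- setdiff(seq_len(n), a)
    ok_pos <- others[vapply(others, function(j)
      overlaps(label_sets[[a]], label_sets[[j]]), TRUE)]
    ok_neg <- others[vapply(others, function(j)
      !overlaps(label_sets[[a]], label_sets[[j]]), TRUE)]
    out[t, ] <- c(a, ok_pos[sample.int(length(ok_pos), 1L)],
                  ok_neg[sample.int(length(ok_neg), 1L)])
  }
  out
}

#' Mine class-supervised triplets
#'
#' Anchor and positive are distinct samples of the same class; the negative
#' comes from a different class. All choices are uniform over the valid
#' options; classes with a single sample are never used as anchor class
#' (mining fails only if no class has two samples or only one class
#' exists).
#'
#' @param dataset A labeled [polyp_dataset()].
#' @param n_triplets Number of triplets (the conventional epoch size is
#'   100).
#' @return List of `triplet` objects with regime `"supervised"`.
#' @export
mine_supervised <- function(dataset, n_triplets = 100L) {
  labels <- dataset_labels(dataset)
  if (anyNA(labels))
    stop_input("supervised mining refuses unlabeled samples")
  idx <- mine_supervised_idx(labels, n_triplets)
  lapply(seq_len(n_triplets), function(t)
    new_triplet(dataset$samples[[idx[t, 1]]], dataset$samples[[idx[t, 2]]],
                dataset$samples[[idx[t, 3]]], "supervised"))
}

#' Mine multilabel class-disjoint triplets
#'
#' For multilabel texture corpora: the positive shares at least one label
#' with the anchor, while the negative must be completely class-disjoint
#' from the anchor's label-set. With singleton label-sets this reduces
#' exactly to supervised mining.
#'
#' @param corpus A [polyp_dataset()] whose samples carry label-sets.
#' @param n_triplets Number of triplets.
#' @return List of `triplet` objects with regime `"multilabel"`.
#' @export
mine_multilabel <- function(corpus, n_triplets = 100L) {
  label_sets <- lapply(corpus$samples, `[[`, "label")
  if (any(vapply(label_sets, is.null, TRUE)))
    stop_input("multilabel mining refuses unlabeled samples")
  idx <- mine_multilabel_idx(label_sets, n_triplets)
  lapply(seq_len(n_triplets), function(t)
    new_triplet(corpus$samples[[idx[t, 1]]], corpus$samples[[idx[t, 2]]],
                corpus$samples[[idx[t, 3]]], "multilabel"))
}

#' Mine self-supervised augmented-view triplets
#'
#' The positive is an augmented view of the anchor image; the negative is a
#' different source image. Labels are never consulted, so unlabeled
#' corpora (e.g. keyframe-condensed video) are valid input.
#'
#' @param images List of [image_sample()] objects (>= 2) or a
#'   [polyp_dataset()].
#' @param aug An [augmentation_spec()] applied to build the positive view.
#' @param n_triplets Number of triplets.
#' @return List of `triplet` objects with regime `"self_supervised"`.
#' @export
mine_self_supervised <- function(images, aug, n_triplets = 100L) {
  if (inherits(images, "polyp_dataset")) images <- images$samples
  n <- length(images)
  if (n < 2) stop_input("self-supervised mining needs >= 2 source images")
  stopifnot(inherits(aug, "augmentation_spec"))
  lapply(seq_len(n_triplets), function(t) {
    a <- sample.int(n, 1L)
    pool <- setdiff(seq_len(n), a)
    neg <- pool[sample.int(length(pool), 1L)]
    anchor <- images[[a]]
    pos <- anchor
    pos$pixels <- augment_image(anchor$pixels, aug)
    new_triplet(anchor, pos, images[[neg]], "self_supervised")
  })
}

#' Check a triplet against its regime's invariant
#'
#' @param triplet A `triplet` object.
#' @return `TRUE` if the invariant holds.
#' @export
triplet_is_valid <- function(triplet) {
  a <- triplet$anchor$label; p <- triplet$positive$label
  n <- triplet$negative$label
  switch(triplet$regime,
    supervised = identical(a, p) && !identical(a, n) &&
      triplet$anchor$polyp_id != triplet$positive$polyp_id,
    multilabel = length(intersect(a, p)) > 0 &&
      length(intersect(a, n)) == 0 &&
      triplet$anchor$polyp_id != triplet$positive$polyp_id,
    self_supervised = triplet$anchor$polyp_id ==
      triplet$positive$polyp_id &&
      triplet$anchor$polyp_id != triplet$negative$polyp_id,
    stop_input("unknown regime: %s", triplet$regime))
}
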