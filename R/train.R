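#' Training configuration
#'
#' Settings shared by pretraining and fine-tuning. One epoch consists of
#' `triplets_per_epoch` freshly mined triplets (100 by default, the
#' conventional epoch size for fine-tuning on few-shot polyp data). A
#' fraction of the corpus is held back for validation; early stopping
#' monitors the validation triplet loss and the returned model carries the
#' parameters that achieved the best validation loss seen, not the last.
#'
#' @param epochs_max Maximum number of epochs (default 100).
#' @param triplets_per_epoch Triplets mined per epoch (default 100).
#' @param validation_fraction Fraction of the corpus held back for
#'   validation, in \[0, 1) (default 0.25).
#' @param patience Early-stopping patience in epochs without improvement
#'   (default 10).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Optional integer seed for mining/augmentation randomness.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs_max = 100L, triplets_per_epoch = 100L,
                         validation_fraction = 0.25, patience = 10L,
                         learning_rate = 1e-3, seed = NULL) {
  if (validation_fraction < 0 || validation_fraction >= 1)
    stop_input("validation_fraction must lie in [0, 1)")
  if (patience < 1) stop_input("patience must be >= 1")
  if (epochs_max < 1) stop_input("epochs_max must be >= 1")
  structure(list(epochs_max = as.integer(epochs_max),
                 triplets_per_epoch = as.integer(triplets_per_epoch),
                 validation_fraction = validation_fraction,
                 patience = as.integer(patience),
                 learning_rate = learning_rate, seed = seed),
            class = "train_config")
}

# --- triplet sources ------------------------------------------------------
# A triplet source binds a corpus to a mining regime and an augmentation
# spec; pretrain()/finetune() split it into train/validation portions and
# draw batches of image tensors from it.

#' Bind a corpus to a triplet-mining regime
#'
#' The resulting source is consumed by [pretrain()]. `supervised` mines by
#' class label, `multilabel` by label-set overlap/disjointness, and
#' `self_supervised` builds positives as augmented views (labels unused).
#'
#' @param data A [polyp_dataset()] (or list of samples for
#'   `self_supervised`).
#' @param aug An [augmentation_spec()]; for the self-supervised regime this
#'   is the view-generating augmentation and should be non-trivial.
#' @return A `triplet_source` object.
#' @export
triplet_source_supervised <- function(data, aug = augmentation_identity()) {
  new_triplet_source(data, aug, "supervised")
}

#' @rdname triplet_source_supervised
#' @export
triplet_source_multilabel <- function(data, aug = augmentation_identity()) {
  new_triplet_source(data, aug, "multilabel")
}

#' @rdname triplet_source_supervised
#' @export
triplet_source_self_supervised <- function(data, aug) {
  new_triplet_source(data, aug, "self_supervised")
}

new_triplet_source <- function(data, aug, regime) {
  samples <- if (inherits(data, "polyp_dataset")) data$samples else data
  stopifnot(inherits(aug, "augmentation_spec"))
  structure(list(samples = samples, aug = aug, regime = regime),
            class = "triplet_source")
}

# Draw a batch of triplet image tensors from a subset of a source.
source_batch <- function(source, subset, n, augment) {
  samples <- source$samples[subset]
  px <- sample_pixels(samples)
  if (source$regime == "self_supervised") {
    nsrc <- length(samples)
    a <- sample.int(nsrc, n, replace = TRUE)
    neg <- vapply(a, function(ai) {
      pool <- setdiff(seq_len(nsrc), ai)
      pool[sample.int(length(pool), 1L)]
    }, 0L)
    pos <- lapply(a, function(ai) augment_image(px[[ai]], source$aug))
    list(a = stack_images(px[a]), p = stack_images(pos),
         n = stack_images(px[neg]))
  } else {
    idx <- if (source$regime == "supervised") {
      labels <- vapply(samples, function(s) s$label[1], "")
      mine_supervised_idx(labels, n)
    } else {
      mine_multilabel_idx(lapply(samples, `[[`, "label"), n)
    }
    gather <- function(k) {
      imgs <- px[idx[, k]]
      if (augment) imgs <- lapply(imgs, augment_image, spec = source$aug)
      stack_images(imgs)
    }
    list(a = gather(1L), p = gather(2L), n = gather(3L))
  }
}

# Split a source into train/validation index sets. Supervised sources are
# stratified by (first) label so every class appears on both sides.
split_source <- function(source, validation_fraction) {
  n <- length(source$samples)
  if (validation_fraction == 0)
    return(list(train = seq_len(n), val = integer(0)))
  if (source$regime %in% c("supervised", "multilabel")) {
    labels <- vapply(source$samples, function(s) s$label[1], "")
    val <- integer(0)
    for (cls in unique(labels)) {
      members <- which(labels == cls)
      n_val <- max(1L, round(validation_fraction * length(members)))
      if (length(members) - n_val < 1L)
        stop_input(
          "class '%s' has too few samples (%d) to appear in both the training and validation portions",
          cls, length(members))
      val <- c(val, sample(members, n_val))
    }
  } else {
    n_val <- max(1L, round(validation_fraction * n))
    if (n - n_val < 2L)
      stop_input("corpus too small to hold back a validation portion")
    val <- sample.int(n, n_val)
  }
  list(train = setdiff(seq_len(n), val), val = sort(val))
}

# --- core loop ------------------------------------------------------------

train_triplet_model <- function(model, sample_train, val_batch, cfg,
                                loss_cfg) {
  adam <- nn_adam_init(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  val_loss_of <- function(params) {
    m <- model; m$params <- params
    mean(triplet_loss(encoder_forward(m, val_batch$a)$z,
                      encoder_forward(m, val_batch$p)$z,
                      encoder_forward(m, val_batch$n)$z, loss_cfg))
  }
  for (epoch in seq_len(cfg$epochs_max)) {
    batch <- sample_train(cfg$triplets_per_epoch)
    nb <- dim(batch$a)[4]
    fa <- encoder_forward(model, batch$a, keep_cache = TRUE)
    fp <- encoder_forward(model, batch$p, keep_cache = TRUE)
    fn <- encoder_forward(model, batch$n, keep_cache = TRUE)
    g <- triplet_loss_grad(fa$z, fp$z, fn$z, loss_cfg)
    train_loss <- mean(g$loss)
    if (!is.finite(train_loss))
      stop_input("training diverged (non-finite loss) at epoch %d", epoch)
    grads <- nn_grads_add(
      nn_grads_add(encoder_backward(model, fa, g$d_anchor / nb),
                   encoder_backward(model, fp, g$d_positive / nb)),
      encoder_backward(model, fn, g$d_negative / nb))
    step <- nn_adam_step(model$params, grads, adam, cfg$learning_rate)
    model$params <- step$params
    adam <- step$state
    vl <- val_loss_of(model$params)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = train_loss,
                                   val_loss = vl))
    if (vl < best$loss) {
      best <- list(loss = vl, params = model$params, epoch = epoch)
    } else if (epoch - best$epoch >= cfg$patience) {
      break
    }
  }
  model$params <- best$params
  list(model = model, history = hist, best_epoch = best$epoch)
}

#' Pretrain an encoder on a triplet source
#'
#' Splits the source's corpus into a training portion and a
#' `validation_fraction` hold-back, then optimizes the contrastive triplet
#' loss with Adam. Validation triplets are mined once (unaugmented for the
#' label-driven regimes; with their intrinsic view augmentation for the
#' self-supervised regime) and monitored for early stopping. The returned
#' model carries the best-validation parameters.
#'
#' @param model An `embedding_model` from [build_encoder()].
#' @param source A triplet source
#'   ([triplet_source_supervised()] and friends).
#' @param cfg A [train_config()].
#' @param loss_cfg A [triplet_loss_config()].
#' @return List with `model`, `history` (one train/validation loss row per
#'   completed epoch) and `best_epoch`.
#' @export
pretrain <- function(model, source, cfg = train_config(),
                     loss_cfg = triplet_loss_config()) {
  stopifnot(inherits(model, "embedding_model"),
            inherits(source, "triplet_source"),
            inherits(cfg, "train_config"))
  with_seed(cfg$seed, {
    parts <- split_source(source, cfg$validation_fraction)
    if (!length(parts$val))
      stop_input("pretraining requires a validation portion (validation_fraction > 0)")
    val_batch <- source_batch(source, parts$val, cfg$triplets_per_epoch,
                              augment = FALSE)
    sample_train <- function(n) source_batch(source, parts$train, n,
                                             augment = FALSE)
    train_triplet_model(model, sample_train, val_batch, cfg, loss_cfg)
  })
}

#' Fine-tune an encoder on labeled polyp data
#'
#' Triplets are formed according to class affiliation from the training
#' portion of the data, with the augmentation pipeline applied to every
#' triplet image; validation triplets come from the held-back portion
#' without augmentation. Fine-tuning does not act on classification
#' performance directly -- it improves the consistency of the learned
#' metric, and a downstream classifier head is fitted on the embeddings
#' afterwards.
#'
#' @param model An `embedding_model`.
#' @param dataset A labeled [polyp_dataset()] with >= 2 classes.
#' @param cfg A [train_config()].
#' @param aug An [augmentation_spec()] applied to training triplets.
#' @param loss_cfg A [triplet_loss_config()].
#' @return As [pretrain()].
#' @export
finetune <- function(model, dataset, cfg = train_config(),
                     aug = augmentation_spec(),
                     loss_cfg = triplet_loss_config()) {
  stopifnot(inherits(model, "embedding_model"),
            inherits(dataset, "polyp_dataset"))
  labels <- dataset_labels(dataset)
  if (anyNA(labels)) stop_input("fine-tuning requires fully labeled data")
  if (length(unique(labels)) < 2)
    stop_input("fine-tuning needs >= 2 classes")
  source <- new_triplet_source(dataset, aug, "supervised")
  with_seed(cfg$seed, {
    parts <- split_source(source, cfg$validation_fraction)
    if (!length(parts$val))
      stop_input("fine-tuning requires a validation hold-back (validation_fraction > 0)")
    val_batch <- source_batch(source, parts$val, cfg$triplets_per_epoch,
                              augment = FALSE)
    sample_train <- function(n) source_batch(source, parts$train, n,
                                             augment = TRUE)
    out <- train_triplet_model(model, sample_train, val_batch, cfg, loss_cfg)
    out$model$class_vocabulary <- dataset$class_vocabulary
    out
  })
}

#' Write a training log as CSV
#' @param history Data frame from [pretrain()]/[finetune()].
#' @param path Output CSV path.
#' @export
write_training_log <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
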