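# Shared fixtures, built lazily and cached for the whole test run.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- builder()
  .fx_cache[[name]]
}

# small two-class polyp set (6 per class, 32 px)
fx_polyp_small <- function() fx("polyp_small", function() {
  generate_polyp_set(synthetic_polyp_spec(n_polyps_per_class = 6,
                                          image_size = 32, seed = 101))
})

fx_texture_corpus <- function() fx("texture", function() {
  generate_texture_corpus(n_classes = 4, n_images_per_class = 6,
                          multilabel_fraction = 0.25, seed = 7,
                          image_size = 32)
})

fx_video <- function() fx("video", function() {
  generate_video(synthetic_video_spec(n_scenes = 3, frames_per_scene = 8,
                                      image_size = 64, seed = 11))
})

fx_bank <- function() fx("bank", function() generate_highlight_bank(6, seed = 3))

fx_tiny_encoder <- function() fx("tiny_encoder", function() {
  build_encoder(input_size = 32, channels = c(4, 8), embedding_dim = 16,
                seed = 202)
})

# a dataset of featureless miniature samples, for split/bookkeeping tests
make_dummy_dataset <- function(class_counts) {
  samples <- list()
  for (cls in names(class_counts)) {
    for (i in seq_len(class_counts[[cls]])) {
      samples[[length(samples) + 1L]] <-
        image_sample(array(0.5, c(4, 4, 3)), label = cls,
                     polyp_id = sprintf("%s_%03d", cls, i))
    }
  }
  polyp_dataset(samples)
}

# independent confusion-count oracle used against compute_metrics
oracle_metrics <- function(true, pred, vocab) {
  n <- length(true)
  per <- lapply(vocab, function(cl) {
    tp <- sum(true == cl & pred == cl)
    fp <- sum(true != cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    tn <- n - tp - fp - fn
    c(precision = if (tp + fp > 0) tp / (tp + fp) else 0,
      recall = if (tp + fn > 0) tp / (tp + fn) else 0,
      f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0,
      accuracy = (tp + tn) / n)
  })
  per <- do.call(rbind, per)
  list(accuracy = mean(true == pred),
       macro_precision = mean(per[, "precision"]),
       macro_recall = mean(per[, "recall"]),
       macro_f1 = mean(per[, "f1"]),
       per_class = per)
}
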