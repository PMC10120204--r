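#' Repeated-split specification
#'
#' Because every polyp contributes a single image, train/test splits are
#' drawn at polyp level and are therefore structurally disjoint in the
#' polyps they contain. With `balanced_test` the test side holds exactly
#' equal per-class counts: each class's nominal test allocation is
#' computed from `1 - train_fraction`, the smallest allocation across
#' classes is used for every class, and the excess returns to the train
#' side.
#'
#' @param train_fraction Fraction of data used for fitting (default 0.75).
#' @param balanced_test Force a class-balanced test set (default `TRUE`).
#' @param n_repeats Number of random splits (default 100).
#' @param seed Integer seed; the same spec and seed reproduce the same
#'   split sequence, so competing configurations can share splits.
#' @return A `split_spec` object.
#' @export
split_spec <- function(train_fraction = 0.75, balanced_test = TRUE,
                       n_repeats = 100L, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_input("train_fraction must lie in (0, 1)")
  if (n_repeats < 1) stop_input("n_repeats must be >= 1")
  structure(list(train_fraction = train_fraction,
                 balanced_test = isTRUE(balanced_test),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Generate polyp-disjoint train/test splits
#'
#' @param dataset A labeled [polyp_dataset()].
#' @param spec A [split_spec()].
#' @return List of `n_repeats` elements, each `list(train =, test =)` of
#'   polyp ids.
#' @export
make_splits <- function(dataset, spec) {
  stopifnot(inherits(dataset, "polyp_dataset"), inherits(spec, "split_spec"))
  labels <- dataset_labels(dataset)
  if (anyNA(labels)) stop_input("splitting requires labeled data")
  ids <- dataset_polyp_ids(dataset)
  by_class <- split(ids, labels)
  test_frac <- 1 - spec$train_fraction
  alloc <- vapply(by_class, function(v) round(test_frac * length(v)), 0)
  if (any(alloc < 1))
    stop_input("class '%s' is too small for any test representation",
               names(alloc)[which.min(alloc)])
  if (spec$balanced_test) alloc[] <- min(alloc)
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_repeats), function(r) {
      test <- unlist(lapply(names(by_class), function(cl)
        sample(by_class[[cl]], alloc[[cl]])), use.names = FALSE)
      list(train = setdiff(ids, test), test = test)
    })
  })
}

#' Classification metrics from true and predicted labels
#'
#' Counts per-class TP/FP/TN/FN one-vs-rest and evaluates
#' `Precision = TP / (TP + FP)`, `Recall = TP / (TP + FN)`,
#' `F1 = 2 TP / (2 TP + FP + FN)` and
#' `Accuracy = (TP + TN) / (TP + TN + FP + FN)` per class; macro values
#' are unweighted class means, and `accuracy` is the plain fraction of
#' correct predictions. On a class-balanced test set accuracy equals
#' macro recall. Empty denominators yield 0 (documented convention).
#'
#' @param true,predicted Equal-length label vectors.
#' @param class_vocabulary Ordered class ids covering every label.
#' @return A `metrics_report`: `accuracy`, `macro_precision`,
#'   `macro_recall`, `macro_f1`, `per_class` data frame, and the
#'   `confusion` matrix (true in rows).
#' @export
compute_metrics <- function(true, predicted, class_vocabulary) {
  true <- as.character(true); predicted <- as.character(predicted)
  if (length(true) != length(predicted))
    stop_input("label vectors differ in length")
  bad <- setdiff(unique(c(true, predicted)), class_vocabulary)
  if (length(bad))
    stop_input("labels outside the vocabulary: %s", paste(bad, collapse = ", "))
  conf <- table(factor(true, class_vocabulary),
                factor(predicted, class_vocabulary))
  n <- length(true)
  frac <- function(num, den) ifelse(den > 0, num / den, 0)
  per <- lapply(class_vocabulary, function(cl) {
    tp <- conf[cl, cl]
    fp <- sum(conf[, cl]) - tp
    fn <- sum(conf[cl, ]) - tp
    tn <- n - tp - fp - fn
    data.frame(class = cl,
               precision = frac(tp, tp + fp),
               recall = frac(tp, tp + fn),
               f1 = frac(2 * tp, 2 * tp + fp + fn),
               accuracy = frac(tp + tn, n),
               support = tp + fn)
  })
  per <- do.call(rbind, per)
  structure(list(accuracy = sum(diag(conf)) / n,
                 macro_precision = mean(per$precision),
                 macro_recall = mean(per$recall),
                 macro_f1 = mean(per$f1),
                 per_class = per,
                 confusion = unclass(conf)),
            class = "metrics_report")
}

#' Mean and confidence-interval half-width over repeated splits
#'
#' The symmetric interval `mean +/- z * sd` under the normal approximation
#' over repeats (`z = 1.6449` at the default 90% level); the percentile
#' form (5th-95th) is available via `method = "percentile"`, reported as
#' half the percentile range.
#'
#' @param values Numeric vector (>= 2 values).
#' @param level Confidence level (default 0.90).
#' @param method `"normal"` (default) or `"percentile"`.
#' @return Named numeric vector `c(mean, half_width)`.
#' @export
confidence_interval <- function(values, level = 0.90,
                                method = c("normal", "percentile")) {
  method <- match.arg(method)
  if (length(values) < 2)
    stop_input("confidence interval needs >= 2 values")
  m <- mean(values)
  hw <- if (method == "normal") {
    stats::qnorm((1 + level) / 2) * stats::sd(values)
  } else {
    q <- stats::quantile(values, c((1 - level) / 2, (1 + level) / 2),
                         names = FALSE)
    (q[2] - q[1]) / 2
  }
  c(mean = m, half_width = hw)
}

#' Run the repeated-split classification experiment
#'
#' For every split: (optionally) fine-tune a copy of the encoder on the
#' train side, embed both sides, fit the requested classifier head(s) on
#' the train embeddings, predict the test side, and compute metrics.
#' Results are aggregated as mean and 90% CI half-width per metric and
#' head. The split sequence depends only on `dataset` and `splits`, so
#' configurations that share a [split_spec()] (e.g. fine-tuned vs not)
#' are compared on identical splits.
#'
#' @param dataset A labeled, preprocessed [polyp_dataset()].
#' @param encoder An `embedding_model` (typically pretrained).
#' @param head_kinds Character vector from
#'   `c("one_nn", "centroid", "svm_rbf")`.
#' @param splits A [split_spec()] or a precomputed split list from
#'   [make_splits()].
#' @param fine_tune Fine-tune the encoder per split before embedding?
#' @param train_cfg,aug,loss_cfg Fine-tuning settings (ignored when
#'   `fine_tune = FALSE`).
#' @param head_params Optional list of per-head parameter lists.
#' @param seed Integer seed driving all per-split randomness.
#' @param project Also compute a 2-D projection of the full-data
#'   embeddings of the base encoder (for inspection only).
#' @return An `eval_report`.
#' @export
run_experiment <- function(dataset, encoder,
                           head_kinds = c("one_nn", "centroid", "svm_rbf"),
                           splits = split_spec(),
                           fine_tune = TRUE,
                           train_cfg = train_config(),
                           aug = augmentation_spec(),
                           loss_cfg = triplet_loss_config(),
                           head_params = list(),
                           seed = 1L,
                           project = FALSE) {
  stopifnot(inherits(dataset, "polyp_dataset"),
            inherits(encoder, "embedding_model"))
  split_list <- if (inherits(splits, "split_spec"))
    make_splits(dataset, splits) else splits
  n_repeats <- length(split_list)
  ids <- dataset_polyp_ids(dataset)
  labels <- dataset_labels(dataset)
  vocab <- dataset$class_vocabulary
  split_seeds <- derive_seeds(seed, n_repeats)
  per_repeat <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    tr <- match(split_list[[r]]$train, ids)
    te <- match(split_list[[r]]$test, ids)
    model <- encoder
    if (fine_tune) {
      cfg <- train_cfg
      cfg$seed <- split_seeds[r]
      sub <- polyp_dataset(dataset$samples[tr], class_vocabulary = vocab)
      model <- finetune(model, sub, cfg, aug, loss_cfg)$model
    }
    ztr <- embed(model, dataset$samples[tr])
    zte <- embed(model, dataset$samples[te])
    reports <- lapply(head_kinds, function(k) {
      head <- fit_head(k, ztr, labels[tr],
                       params = head_params[[k]] %||% list(),
                       class_vocabulary = vocab)
      compute_metrics(labels[te], predict(head, zte), vocab)
    })
    names(reports) <- head_kinds
    per_repeat[[r]] <- reports
  }
  metric_names <- c("accuracy", "macro_precision", "macro_recall", "macro_f1")
  summary <- do.call(rbind, lapply(head_kinds, function(k) {
    do.call(rbind, lapply(metric_names, function(m) {
      vals <- vapply(per_repeat, function(rep) rep[[k]][[m]], 0)
      ci <- if (n_repeats >= 2) confidence_interval(vals)
            else c(mean = vals, half_width = 0)
      data.frame(head = k, metric = m, mean = ci[["mean"]],
                 ci_half_width = ci[["half_width"]])
    }))
  }))
  z_all <- embed(encoder, dataset$samples)
  structure(list(head_kinds = head_kinds, n_repeats = n_repeats,
                 per_repeat = per_repeat, summary = summary,
                 variance_report = class_variances(z_all, labels),
                 projection_2d = if (project) project_2d(z_all, seed = seed),
                 fine_tune = fine_tune, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d repeats, fine_tune = %s\n",
              x$n_repeats, x$fine_tune))
  s <- x$summary
  for (k in x$head_kinds) {
    row <- function(m) s[s$head == k & s$metric == m, ]
    cat(sprintf("  %-8s Acc %.1f (+/- %.1f)  Pre %.1f  Rec %.1f  F1 %.1f\n",
                k, 100 * row("accuracy")$mean,
                100 * row("accuracy")$ci_half_width,
                100 * row("macro_precision")$mean,
                100 * row("macro_recall")$mean,
                100 * row("macro_f1")$mean))
  }
  invisible(x)
}

#' Export an evaluation report as JSON and CSV tables
#'
#' Writes `summary.csv` (one row per head with mean +/- half-width per
#' metric), `variances.csv`, `report.json`, and, when present,
#' `projection.csv`.
#'
#' @param report An `eval_report`.
#' @param dir Output directory.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  vr <- report$variance_report
  utils::write.csv(data.frame(class = c(names(vr$intra), "inter"),
                              variance = c(vr$intra, vr$inter)),
                   file.path(dir, "variances.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(summary = report$summary,
         variances = list(intra = as.list(vr$intra), inter = vr$inter),
         n_repeats = report$n_repeats, fine_tune = report$fine_tune,
         seed = report$seed),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(report$projection_2d))
    utils::write.csv(as.data.frame(report$projection_2d),
                     file.path(dir, "projection.csv"), row.names = FALSE)
  invisible(dir)
}
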