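# Experiment orchestration: a structured config file drives generation,
# pretraining, fine-tuning, evaluation and keyframe condensation. Every
# command writes a resolved-config snapshot next to its outputs so a run
# is reproducible from its output directory alone.

pe_log <- function(level = "info", fmt, ...) {
  message(sprintf("[%s] %-5s %s", format(Sys.time(), "%H:%M:%S"),
                  level, sprintf(fmt, ...)))
}

#' Load and validate an experiment configuration
#'
#' Configs are YAML (`.yml`/`.yaml`) or JSON files. Every section is
#' optional and falls back to package defaults; the global `seed`
#' deterministically derives all component seeds.
#'
#' @param path Config file path, or a named list already in memory.
#' @return An `experiment_config` list.
#' @export
load_experiment_config <- function(path) {
  cfg <- if (is.list(path)) path
  else if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_input("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_dir <- cfg$output_dir %||% "polypembed_out"
  cfg$fine_tune <- isTRUE(cfg$fine_tune %||% TRUE)
  cfg$heads <- cfg$heads %||% c("one_nn", "centroid", "svm_rbf")
  cfg$pretraining <- cfg$pretraining %||% list(regime = "none")
  if (!cfg$pretraining$regime %in%
      c("dtd_style_supervised", "self_supervised", "none"))
    stop_input("unknown pretraining regime: %s", cfg$pretraining$regime)
  structure(cfg, class = "experiment_config")
}

config_encoder <- function(cfg) {
  e <- cfg$encoder %||% list()
  build_encoder(input_size = e$input_size %||% 224L,
                channels = unlist(e$channels %||% c(16, 32, 64, 128)),
                embedding_dim = e$embedding_dim %||% 64L,
                seed = derive_seeds(cfg$seed, 1L))
}

config_train <- function(cfg) {
  tr <- cfg$train %||% list()
  train_config(epochs_max = tr$epochs_max %||% 100L,
               triplets_per_epoch = tr$triplets_per_epoch %||% 100L,
               validation_fraction = tr$validation_fraction %||% 0.25,
               patience = tr$patience %||% 10L,
               learning_rate = tr$learning_rate %||% 1e-3)
}

config_aug <- function(cfg, bank = NULL) {
  a <- cfg$augmentation %||% list()
  graft <- isTRUE(a$graft_highlights) && length(bank) > 0
  augmentation_spec(
    hue_delta = a$hue_delta %||% 0.05,
    contrast_range = unlist(a$contrast_range %||% c(0.7, 1.3)),
    brightness_range = unlist(a$brightness_range %||% c(0.7, 1.3)),
    saturation_range = unlist(a$saturation_range %||% c(0.7, 1.3)),
    noise_sigma = a$noise_sigma %||% 0.02,
    graft_highlights = graft,
    highlight_bank = if (graft) bank,
    n_highlights = a$n_highlights %||% 2L)
}

config_loss <- function(cfg) {
  l <- cfg$loss %||% list()
  triplet_loss_config(margin = l$margin %||% 20, metric = l$metric %||% "l2")
}

snapshot_config <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(cfg), file.path(dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Generate the synthetic fixture suite described by a config
#'
#' Writes a two-class polyp set, a multilabel texture corpus, a
#' scene-structured video, and a highlight bank under the config's
#' `output_dir`.
#'
#' @param config An `experiment_config` (or path to one).
#' @return Named list of output directories, invisibly.
#' @export
cmd_generate <- function(config) {
  cfg <- load_experiment_config(config)
  out <- cfg$output_dir
  parent <- dirname(normalizePath(out, mustWork = FALSE))
  if (!dir.exists(parent)) stop_input("output path parent missing: %s", parent)
  gen <- cfg$generate %||% list()
  seeds <- derive_seeds(cfg$seed, 4L)
  snapshot_config(cfg, out)

  g <- gen$polyps %||% list()
  pspec <- synthetic_polyp_spec(
    n_polyps_per_class = g$n_polyps_per_class %||% 20L,
    image_size = g$image_size %||% 224L,
    highlight_density = g$highlight_density %||% 3,
    noise_sigma = g$noise_sigma %||% 0.05,
    seed = seeds[1])
  pset <- generate_polyp_set(pspec)
  pe_log("info", "generated %d polyp images", length(pset$dataset$samples))
  write_image_dataset(pset$dataset, file.path(out, "polyps"),
                      ground_truth = pset$ground_truth)

  t <- gen$textures %||% list()
  corpus <- generate_texture_corpus(
    n_classes = t$n_classes %||% 8L,
    n_images_per_class = t$n_images_per_class %||% 10L,
    multilabel_fraction = t$multilabel_fraction %||% 0.3,
    image_size = t$image_size %||% 64L, seed = seeds[2])
  write_image_dataset(corpus, file.path(out, "textures"))

  v <- gen$video %||% list()
  vspec <- synthetic_video_spec(
    n_scenes = v$n_scenes %||% 5L,
    frames_per_scene = v$frames_per_scene %||% 20L,
    image_size = v$image_size %||% 64L, seed = seeds[3])
  video <- generate_video(vspec)
  vdir <- file.path(out, "video")
  dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(video$frames))
    png::writePNG(video$frames[[i]], file.path(vdir, sprintf("frame_%04d.png", i)))
  jsonlite::write_json(video$ground_truth,
                       file.path(vdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)

  b <- gen$highlight_bank %||% list()
  bank <- generate_highlight_bank(n = b$n %||% 20L, seed = seeds[4])
  write_highlight_bank(bank, file.path(out, "highlights"))
  pe_log("info", "fixture suite written to %s", out)
  invisible(list(polyps = file.path(out, "polyps"),
                 textures = file.path(out, "textures"),
                 video = vdir,
                 highlights = file.path(out, "highlights")))
}

load_corpus_images <- function(dir_or_manifest, target_size) {
  if (dir.exists(dir_or_manifest) &&
      !file.exists(file.path(dir_or_manifest, "manifest.csv"))) {
    files <- sort(list.files(dir_or_manifest, pattern = "\\.png$",
                             full.names = TRUE))
    samples <- lapply(seq_along(files), function(i)
      image_sample(read_image(files[i]),
                   polyp_id = basename(files[i]), source = files[i]))
    return(lapply(samples, preprocess, target_size = target_size))
  }
  man <- if (dir.exists(dir_or_manifest))
    file.path(dir_or_manifest, "manifest.csv") else dir_or_manifest
  ds <- preprocess_dataset(load_manifest(man), target_size)
  ds
}

#' Pretrain an encoder as specified by a config
#'
#' Regime `dtd_style_supervised` mines multilabel class-disjoint triplets
#' from the texture corpus (optionally with highlight grafting);
#' `self_supervised` mines augmented-view triplets from an unlabeled image
#' corpus (typically keyframe-condensed video frames).
#'
#' @param config An `experiment_config` (or path).
#' @return Path of the written checkpoint, invisibly.
#' @export
cmd_pretrain <- function(config) {
  cfg <- load_experiment_config(config)
  out <- cfg$output_dir
  snapshot_config(cfg, out)
  enc <- config_encoder(cfg)
  bank <- if (!is.null(cfg$data$highlight_bank))
    read_highlight_bank(cfg$data$highlight_bank)
  aug <- config_aug(cfg, bank)
  tcfg <- config_train(cfg)
  tcfg$seed <- derive_seeds(cfg$seed, 2L)[2]
  regime <- cfg$pretraining$regime
  pe_log("info", "pretraining regime: %s", regime)
  source <- switch(regime,
    dtd_style_supervised = {
      corpus <- load_corpus_images(cfg$data$texture_corpus, enc$input_size)
      triplet_source_multilabel(corpus, aug)
    },
    self_supervised = {
      imgs <- load_corpus_images(cfg$data$pretrain_corpus, enc$input_size)
      triplet_source_self_supervised(
        if (inherits(imgs, "polyp_dataset")) imgs$samples else imgs, aug)
    },
    none = stop_input("pretraining regime is 'none'"))
  fit <- pretrain(enc, source, tcfg, config_loss(cfg))
  ck <- file.path(out, "encoder_pretrained.rds")
  save_encoder(fit$model, ck)
  write_training_log(fit$history, file.path(out, "pretrain_log.csv"))
  pe_log("info", "checkpoint written: %s (best epoch %d)", ck, fit$best_epoch)
  invisible(ck)
}

#' Fine-tune a pretrained encoder on labeled polyp data
#' @param config An `experiment_config` (or path).
#' @return Path of the fine-tuned checkpoint, invisibly.
#' @export
cmd_finetune <- function(config) {
  cfg <- load_experiment_config(config)
  out <- cfg$output_dir
  snapshot_config(cfg, out)
  enc <- load_encoder(cfg$data$checkpoint %||%
                        file.path(out, "encoder_pretrained.rds"))
  ds <- preprocess_dataset(load_manifest(man_path(cfg$data$polyp_manifest)),
                           enc$input_size)
  tcfg <- config_train(cfg)
  tcfg$seed <- derive_seeds(cfg$seed, 3L)[3]
  bank <- if (!is.null(cfg$data$highlight_bank))
    read_highlight_bank(cfg$data$highlight_bank)
  fit <- finetune(enc, ds, tcfg, config_aug(cfg, bank), config_loss(cfg))
  ck <- file.path(out, "encoder_finetuned.rds")
  save_encoder(fit$model, ck)
  write_training_log(fit$history, file.path(out, "finetune_log.csv"))
  invisible(ck)
}

man_path <- function(p) {
  if (dir.exists(p %||% "")) file.path(p, "manifest.csv") else p
}

#' Run the repeated-split evaluation described by a config
#'
#' @param config An `experiment_config` (or path).
#' @return The `eval_report`, invisibly; report files are written under
#'   `output_dir/eval`.
#' @export
cmd_evaluate <- function(config) {
  cfg <- load_experiment_config(config)
  out <- cfg$output_dir
  snapshot_config(cfg, out)
  enc <- if (!is.null(cfg$data$checkpoint)) load_encoder(cfg$data$checkpoint)
         else config_encoder(cfg)
  ds <- preprocess_dataset(load_manifest(man_path(cfg$data$polyp_manifest)),
                           enc$input_size)
  sp <- cfg$split %||% list()
  spec <- split_spec(train_fraction = sp$train_fraction %||% 0.75,
                     balanced_test = sp$balanced_test %||% TRUE,
                     n_repeats = sp$n_repeats %||% 100L,
                     seed = derive_seeds(cfg$seed, 4L)[4])
  bank <- if (!is.null(cfg$data$highlight_bank))
    read_highlight_bank(cfg$data$highlight_bank)
  report <- run_experiment(ds, enc, head_kinds = cfg$heads, splits = spec,
                           fine_tune = cfg$fine_tune,
                           train_cfg = config_train(cfg),
                           aug = config_aug(cfg, bank),
                           loss_cfg = config_loss(cfg),
                           seed = cfg$seed, project = TRUE)
  write_eval_report(report, file.path(out, "eval"))
  pe_log("info", "evaluation report written to %s", file.path(out, "eval"))
  invisible(report)
}

#' Condense a frame directory into keyframes
#'
#' @param config An `experiment_config` (or path); `data$frames_dir` names
#'   an ordered directory of PNG frames.
#' @return The `scene_decomposition`, invisibly; keyframes are copied to
#'   `output_dir/keyframes` with a JSON report.
#' @export
cmd_keyframes <- function(config) {
  cfg <- load_experiment_config(config)
  out <- cfg$output_dir
  snapshot_config(cfg, out)
  fdir <- cfg$data$frames_dir
  files <- sort(list.files(fdir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop_input("no PNG frames in %s", fdir)
  frames <- lapply(files, read_image)
  kf <- cfg$keyframes %||% list()
  dec <- select_keyframes(frames,
                          match_threshold = kf$match_threshold %||% 0.15)
  kdir <- file.path(out, "keyframes")
  dir.create(kdir, recursive = TRUE, showWarnings = FALSE)
  for (i in dec$keyframes)
    file.copy(files[i], file.path(kdir, basename(files[i])), overwrite = TRUE)
  jsonlite::write_json(
    list(frame_count = dec$frame_count, boundaries = dec$boundaries,
         keyframes = dec$keyframes, match_scores = dec$match_scores,
         input = fdir),
    file.path(kdir, "scene_decomposition.json"),
    auto_unbox = TRUE, digits = NA)
  pe_log("info", "%d frames condensed to %d keyframes",
         dec$frame_count, length(dec$keyframes))
  invisible(dec)
}
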