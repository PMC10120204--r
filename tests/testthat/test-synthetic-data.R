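# Generators: bookkeeping, determinism, separability properties.

test_that("polyp set has the right counts, ids and pixel range", {
  ps <- fx_polyp_small()
  ds <- ps$dataset
  expect_length(ds$samples, 12L)
  ids <- vapply(ds$samples, `[[`, "", "polyp_id")
  expect_false(anyDuplicated(ids) > 0)
  labs <- vapply(ds$samples, function(s) s$label, "")
  expect_equal(unname(table(labs)[c("spotted", "tubular")]), c(6L, 6L),
               ignore_attr = TRUE)
  rng <- range(vapply(ds$samples, function(s) range(s$pixels), numeric(2)))
  expect_gte(rng[1], 0); expect_lte(rng[2], 1)
  # masks are binary and image-sized
  expect_true(all(vapply(ps$ground_truth$highlight_masks, function(m)
    is.logical(m) && all(dim(m) == c(32L, 32L)), TRUE)))
})

test_that("generation is a pure function of the spec (seed included)", {
  spec <- synthetic_polyp_spec(n_polyps_per_class = 2, image_size = 32,
                               seed = 55)
  a <- generate_polyp_set(spec)
  b <- generate_polyp_set(spec)
  expect_identical(lapply(a$dataset$samples, `[[`, "pixels"),
                   lapply(b$dataset$samples, `[[`, "pixels"))
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("invalid polyp specs are rejected", {
  expect_error(synthetic_polyp_spec(n_polyps_per_class = 0), ">= 1")
  expect_error(synthetic_polyp_spec(image_size = 16), ">= 32")
})

test_that("texture corpus honours label-set bookkeeping", {
  corpus <- generate_texture_corpus(4, 10, multilabel_fraction = 0,
                                    seed = 7, image_size = 32)
  expect_length(corpus$samples, 40L)
  expect_true(all(lengths(lapply(corpus$samples, `[[`, "label")) == 1L))
  multi <- generate_texture_corpus(4, 10, multilabel_fraction = 0.5,
                                   seed = 7, image_size = 32)
  sizes <- lengths(lapply(multi$samples, `[[`, "label"))
  expect_equal(sum(sizes >= 2), 20L)
  expect_true(all(sizes >= 1))
  again <- generate_texture_corpus(4, 10, multilabel_fraction = 0.5,
                                   seed = 7, image_size = 32)
  expect_identical(lapply(multi$samples, `[[`, "label"),
                   lapply(again$samples, `[[`, "label"))
  expect_error(generate_texture_corpus(1, 5), ">= 2")
})

test_that("video has planted scene structure and sharp frames", {
  vid <- fx_video()
  expect_length(vid$frames, 24L)
  expect_equal(vid$ground_truth$scene_boundaries, c(9L, 17L))
  sh <- vapply(vid$frames, sharpness, 0)
  for (sc in 1:3) {
    idx <- ((sc - 1) * 8 + 1):(sc * 8)
    planted <- vid$ground_truth$planted_keyframe_indices[sc]
    expect_equal(idx[which.max(sh[idx])], planted)
    expect_true(all(sh[planted] > sh[setdiff(idx, planted)]))
  }
  single <- generate_video(synthetic_video_spec(n_scenes = 1,
                                                frames_per_scene = 1,
                                                image_size = 48, seed = 2))
  expect_length(single$frames, 1L)
  expect_length(single$ground_truth$scene_boundaries, 0L)
  expect_error(synthetic_video_spec(n_scenes = 0), ">= 1")
})

test_that("highlight bank entries are bright non-empty masked patches", {
  bank <- fx_bank()
  expect_length(bank, 6L)
  expect_true(all(vapply(bank, function(h) sum(h$mask) >= 1, TRUE)))
  # bank determinism
  again <- generate_highlight_bank(6, seed = 3)
  expect_identical(lapply(bank, `[[`, "patch"), lapply(again, `[[`, "patch"))
  # patch pixels under the mask exceed the 95th percentile of generated
  # polyp-image intensities
  ps <- fx_polyp_small()
  corpus_vals <- unlist(lapply(ps$dataset$samples[1:4], function(s)
    as.vector(s$pixels)))
  q95 <- quantile(corpus_vals, 0.95)
  for (h in bank) {
    under <- apply(h$patch, 3, function(ch) ch[h$mask])
    expect_gt(min(rowMeans(under)), q95)
  }
})

test_that("zero pattern contrast makes classes unrecoverable (chance level)", {
  flat <- list(spotted = list(spot_density = 0.03, tubule_frequency = 0,
                              pattern_contrast = 0),
               tubular = list(spot_density = 0, tubule_frequency = 9,
                              pattern_contrast = 0))
  ps <- generate_polyp_set(synthetic_polyp_spec(
    n_polyps_per_class = 12, image_size = 32,
    class_texture_params = flat, seed = 909))
  rep <- run_experiment(ps$dataset, fx_tiny_encoder(), head_kinds = "svm_rbf",
                        splits = split_spec(n_repeats = 8, seed = 3),
                        fine_tune = FALSE, seed = 3)
  acc <- rep$summary[rep$summary$metric == "accuracy", "mean"]
  # 8 splits x 6 balanced test images: binomial fluctuation around 0.5
  expect_gt(acc, 0.5 - 3 * sqrt(0.25 / 48))
  expect_lt(acc, 0.5 + 3 * sqrt(0.25 / 48))
})

test_that("class separability is monotone in pattern contrast", {
  acc_at <- function(contrast, seed) {
    pars <- list(spotted = list(spot_density = 0.03, tubule_frequency = 0,
                                pattern_contrast = contrast),
                 tubular = list(spot_density = 0, tubule_frequency = 9,
                                pattern_contrast = contrast))
    ps <- generate_polyp_set(synthetic_polyp_spec(
      n_polyps_per_class = 8, image_size = 32,
      class_texture_params = pars, seed = seed))
    rep <- run_experiment(ps$dataset, fx_tiny_encoder(),
                          head_kinds = "svm_rbf",
                          splits = split_spec(n_repeats = 4, seed = seed),
                          fine_tune = FALSE, seed = seed)
    rep$summary[rep$summary$metric == "accuracy", "mean"]
  }
  for (seed in 1:5)
    expect_gte(acc_at(0.8, seed), acc_at(0.2, seed))
})
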