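# Augmentation operators: exact contracts first, stochastic behaviour second.

test_that("flips are involutions and compose to a 180-degree rotation", {
  set.seed(8)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(flip_image(img), img)
  expect_identical(flip_image(flip_image(img, horizontal = TRUE),
                              horizontal = TRUE), img)
  expect_identical(flip_image(flip_image(img, vertical = TRUE),
                              vertical = TRUE), img)
  both <- flip_image(img, horizontal = TRUE, vertical = TRUE)
  rot180 <- img[16:1, 16:1, , drop = FALSE]
  expect_identical(both, rot180)
})

test_that("identity-parameter jitter returns the input bit for bit", {
  set.seed(9)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(photometric_jitter(img, augmentation_identity()), img)
  expect_identical(augment_image(img, augmentation_identity()), img)
})

test_that("jitter obeys brightness/contrast fixed points", {
  set.seed(10)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  dark <- photometric_jitter(img, augmentation_spec(
    hue_delta = 0, contrast_range = c(1, 1), saturation_range = c(1, 1),
    brightness_range = c(0, 0), noise_sigma = 0))
  expect_true(all(dark == 0))
  const <- array(0.37, c(12, 12, 3))
  contrasted <- photometric_jitter(const, augmentation_spec(
    hue_delta = 0, contrast_range = c(1.8, 1.8), saturation_range = c(1, 1),
    brightness_range = c(1, 1), noise_sigma = 0))
  expect_equal(contrasted, const, tolerance = 1e-12)
  out <- photometric_jitter(img, augmentation_spec(noise_sigma = 0))
  expect_true(min(out) >= 0 && max(out) <= 1)
  expect_error(augmentation_spec(contrast_range = c(1.3, 0.7)), "interval")
})

test_that("gaussian noise has the requested scale and clips", {
  img <- array(0.5, c(64, 64, 3))  # > 10^4 pixels
  set.seed(11)
  noisy <- add_gaussian_noise(img, 0.1)
  expect_equal(sd(noisy - img), 0.1, tolerance = 0.01)
  expect_identical(add_gaussian_noise(img, 0), img)
  extreme <- add_gaussian_noise(img, 5)
  expect_true(min(extreme) >= 0 && max(extreme) <= 1)
  expect_error(add_gaussian_noise(img, -1), "non-negative")
})

test_that("highlight detector finds planted blobs and reports empty masks", {
  black <- array(0, c(32, 32, 3))
  det <- detect_specular_highlights(black)
  expect_false(det$found)
  expect_equal(sum(det$mask), 0L)
  # full working resolution: at 1-2 px blob radius the mask boundary would
  # dominate the Jaccard index, so this contract is checked at 160 px
  ps <- generate_polyp_set(synthetic_polyp_spec(n_polyps_per_class = 2,
                                                image_size = 160,
                                                highlight_density = 4,
                                                seed = 77))
  jac <- vapply(seq_along(ps$dataset$samples), function(i) {
    gt <- ps$ground_truth$highlight_masks[[i]]
    if (!any(gt)) return(NA_real_)
    d <- detect_specular_highlights(ps$dataset$samples[[i]]$pixels)
    sum(d$mask & gt) / sum(d$mask | gt)
  }, 0)
  expect_true(all(stats::na.omit(jac) >= 0.8))
  # dilation_radius = 0 equals the raw thresholded mask
  img <- ps$dataset$samples[[1]]$pixels
  raw <- detect_specular_highlights(img, dilation_radius = 0)
  vmax <- pmax(img[, , 1], img[, , 2], img[, , 3])
  vmin <- pmin(img[, , 1], img[, , 2], img[, , 3])
  manual <- vmax >= 0.95 & ifelse(vmax > 0, (vmax - vmin) / vmax, 0) <= 0.25
  expect_identical(raw$mask, manual)
  expect_error(detect_specular_highlights(img, brightness_threshold = 1.2),
               "\\[0, 1\\]")
})

test_that("grafting replaces only pixels under the returned mask", {
  set.seed(12)
  img <- array(runif(48 * 48 * 3), c(48, 48, 3))
  bank <- fx_bank()
  out <- graft_highlights(img, bank, n_highlights = 3)
  expect_true(any(out$mask))
  m3 <- array(out$mask, dim(img))
  expect_identical(out$image[!m3], img[!m3])  # exhaustive outside-mask check
  none <- graft_highlights(img, bank, n_highlights = 0)
  expect_identical(none$image, img)
  expect_false(any(none$mask))
  expect_error(graft_highlights(img, list(), n_highlights = 1), "empty bank")
})

test_that("grafted highlights are recovered by the detector", {
  set.seed(13)
  base <- fx_polyp_small()$dataset$samples[[3]]$pixels
  # work on a highlight-free canvas: remove existing saturated pixels
  base <- pmin(base, 0.9)
  out <- graft_highlights(base, fx_bank(), n_highlights = 2)
  det <- detect_specular_highlights(out$image, dilation_radius = 1)
  coverage <- sum(det$mask & out$mask) / sum(out$mask)
  expect_gte(coverage, 0.8)
})

test_that("composed augmentation stays in range and is RNG-reproducible", {
  img <- fx_polyp_small()$dataset$samples[[1]]$pixels
  spec <- augmentation_spec(noise_sigma = 0.05, graft_highlights = TRUE,
                            highlight_bank = fx_bank(), n_highlights = 1)
  set.seed(77); a <- augment_image(img, spec)
  set.seed(77); b <- augment_image(img, spec)
  expect_identical(a, b)
  expect_true(min(a) >= 0 && max(a) <= 1)
})

test_that("highlight banks serialize and reload", {
  bank <- fx_bank()
  dir <- tempfile()
  write_highlight_bank(bank, dir)
  back <- read_highlight_bank(dir)
  expect_length(back, length(bank))
  expect_identical(back[[2]]$mask, bank[[2]]$mask)
  expect_equal(back[[2]]$patch, bank[[2]]$patch, tolerance = 1 / 255)
  unlink(dir, recursive = TRUE)
})
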