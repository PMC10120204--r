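# Manifest IO and preprocessing.

test_that("write -> load round-trips labels, ids and bboxes exactly", {
  set.seed(21)
  samples <- list(
    image_sample(array(runif(24 * 24 * 3), c(24, 24, 3)), label = "a",
                 polyp_id = "p1", bbox = c(2, 3, 10, 12)),
    image_sample(array(runif(24 * 24 * 3), c(24, 24, 3)), label = "b",
                 polyp_id = "p2"),
    image_sample(array(runif(24 * 24 * 3), c(24, 24, 3)),
                 label = c("a", "b"), polyp_id = "p3"))
  dir <- tempfile()
  write_image_dataset(samples, dir)
  ds <- load_manifest(file.path(dir, "manifest.csv"))
  expect_length(ds$samples, 3L)
  expect_equal(vapply(ds$samples, `[[`, "", "polyp_id"), c("p1", "p2", "p3"))
  expect_equal(ds$samples[[1]]$label, "a")
  expect_equal(ds$samples[[3]]$label, c("a", "b"))
  expect_equal(ds$samples[[1]]$bbox, c(2, 3, 10, 12))
  expect_null(ds$samples[[2]]$bbox)
  # pixels survive the 8-bit PNG round trip to within quantization
  expect_equal(ds$samples[[2]]$pixels, samples[[2]]$pixels,
               tolerance = 1 / 255)
  unlink(dir, recursive = TRUE)
})

test_that("missing files and malformed boxes are reported by row", {
  dir <- tempfile(); dir.create(dir)
  write.csv(data.frame(path = "nope.png", polyp_id = "x"),
            file.path(dir, "manifest.csv"), row.names = FALSE)
  expect_error(load_manifest(file.path(dir, "manifest.csv")), "row 1")
  expect_error(load_manifest(file.path(dir, "absent.csv")), "not found")
  img <- array(0.5, c(10, 10, 3))
  expect_error(image_sample(img, polyp_id = "p", bbox = c(5, 5, 10, 2)),
               "outside")
  expect_error(image_sample(img, polyp_id = "p", bbox = c(0, 0, 0, 4)),
               "area")
  unlink(dir, recursive = TRUE)
})

test_that("manifests without labels load as unlabeled and are refused by supervised ops", {
  dir <- tempfile()
  samples <- lapply(1:4, function(i)
    image_sample(array(0.5, c(8, 8, 3)), polyp_id = sprintf("u%d", i)))
  write_image_dataset(samples, dir)
  ds <- load_manifest(file.path(dir, "manifest.csv"))
  expect_true(all(vapply(ds$samples, function(s) is.null(s$label), TRUE)))
  expect_error(mine_supervised(ds, 5), "unlabeled")
  expect_error(make_splits(ds, split_spec(n_repeats = 2)), "labeled")
  unlink(dir, recursive = TRUE)
})

test_that("preprocess crops to the bbox and resamples to the target shape", {
  set.seed(4)
  big <- array(runif(48 * 48 * 3), c(48, 48, 3))
  s <- image_sample(big, label = "a", polyp_id = "p")
  out <- preprocess(s, target_size = 24)
  expect_equal(dim(out$pixels), c(24L, 24L, 3L))
  expect_null(out$bbox)
  # bbox equal to the full image is identical to the no-bbox path
  s_full <- image_sample(big, label = "a", polyp_id = "p",
                         bbox = c(0, 0, 48, 48))
  expect_equal(preprocess(s_full, 24)$pixels, out$pixels)
  # a genuine crop reproduces direct resizing of the sub-image
  s_crop <- image_sample(big, label = "a", polyp_id = "p",
                         bbox = c(8, 4, 20, 30))
  manual <- image_sample(big[5:34, 9:28, , drop = FALSE], label = "a",
                         polyp_id = "p")
  expect_equal(preprocess(s_crop, 16)$pixels, preprocess(manual, 16)$pixels)
})

test_that("resampling preserves constants and is idempotent at target size", {
  const <- image_sample(array(0.42, c(30, 30, 3)), polyp_id = "c")
  out <- preprocess(const, 224)
  expect_equal(range(out$pixels), c(0.42, 0.42), tolerance = 1e-12)
  once <- preprocess(image_sample(array(runif(40 * 40 * 3), c(40, 40, 3)),
                                  polyp_id = "r"), 24)
  twice <- preprocess(once, 24)
  expect_equal(twice$pixels, once$pixels, tolerance = 1e-7)
})

test_that("dataset constructor enforces vocabulary and polyp uniqueness", {
  s <- function(id, lab) image_sample(array(0.1, c(4, 4, 3)), label = lab,
                                      polyp_id = id)
  expect_error(polyp_dataset(list(s("a", "x"), s("a", "y"))), "duplicate")
  expect_error(polyp_dataset(list(s("a", "x")), class_vocabulary = "y"),
               "outside")
  ds <- polyp_dataset(list(s("a", "x"), s("b", "y")))
  expect_equal(ds$class_vocabulary, c("x", "y"))
})
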