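# Splits, metric formulas, confidence intervals, repeated experiments.

test_that("splits are polyp-disjoint and class-balanced on 34+27 polyps", {
  ds <- make_dummy_dataset(c(nice1 = 34, nice2 = 27))
  splits <- make_splits(ds, split_spec(n_repeats = 100, seed = 13))
  expect_length(splits, 100L)
  labs <- setNames(vapply(ds$samples, function(s) s$label, ""),
                   vapply(ds$samples, `[[`, "", "polyp_id"))
  for (sp in splits) {
    expect_length(intersect(sp$train, sp$test), 0L)  # id-disjoint
    tab <- table(labs[sp$test])
    expect_equal(unname(tab["nice1"]), unname(tab["nice2"]))  # balanced
    expect_setequal(c(sp$train, sp$test), names(labs))
  }
  # test side is roughly a quarter of the data
  n_test <- length(splits[[1]]$test)
  expect_gte(n_test, floor(0.2 * 61)); expect_lte(n_test, ceiling(0.3 * 61))
})

test_that("identical spec and seed reproduce identical splits", {
  ds <- make_dummy_dataset(c(a = 10, b = 8))
  s1 <- make_splits(ds, split_spec(n_repeats = 10, seed = 5))
  s2 <- make_splits(ds, split_spec(n_repeats = 10, seed = 5))
  expect_identical(s1, s2)
})

test_that("unbalanced splits preserve class proportions within one sample", {
  ds <- make_dummy_dataset(c(a = 20, b = 12))
  splits <- make_splits(ds, split_spec(balanced_test = FALSE,
                                       n_repeats = 20, seed = 7))
  labs <- setNames(vapply(ds$samples, function(s) s$label, ""),
                   vapply(ds$samples, `[[`, "", "polyp_id"))
  for (sp in splits) {
    tab <- table(labs[sp$test])
    expect_equal(unname(tab["a"]), round(0.25 * 20), tolerance = 1)
    expect_equal(unname(tab["b"]), round(0.25 * 12), tolerance = 1)
  }
  tiny <- make_dummy_dataset(c(a = 10, b = 1))
  expect_error(make_splits(tiny, split_spec()), "too small")
})

test_that("metrics match the worked confusion-matrix example", {
  # binary: TP=2, TN=2, FP=1, FN=1 for the positive class
  true <- c("pos", "pos", "pos", "neg", "neg", "neg")
  pred <- c("pos", "pos", "neg", "pos", "neg", "neg")
  m <- compute_metrics(true, pred, c("pos", "neg"))
  pos <- m$per_class[m$per_class$class == "pos", ]
  expect_equal(pos$precision, 2 / 3)
  expect_equal(pos$recall, 2 / 3)
  expect_equal(pos$f1, 2 / 3)
  expect_equal(pos$accuracy, 2 / 3)
  expect_equal(m$accuracy, 2 / 3)
  perfect <- compute_metrics(true, true, c("pos", "neg"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_f1, 1)
})

test_that("metrics agree with an independent oracle on all binary vectors of length <= 6", {
  vocab <- c("n", "p")
  for (len in 1:6) {
    grid <- expand.grid(rep(list(vocab), len), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(grid))) {
      true <- unlist(grid[i, ], use.names = FALSE)
      for (j in seq_len(nrow(grid))) {
        pred <- unlist(grid[j, ], use.names = FALSE)
        got <- compute_metrics(true, pred, vocab)
        want <- oracle_metrics(true, pred, vocab)
        expect_equal(got$accuracy, want$accuracy)
        expect_equal(got$macro_precision, want$macro_precision)
        expect_equal(got$macro_recall, want$macro_recall)
        expect_equal(got$macro_f1, want$macro_f1)
      }
    }
  }
})

test_that("accuracy equals macro recall exactly on balanced test sets", {
  set.seed(31)
  vocab <- c("a", "b")
  for (i in 1:1000) {
    n_per <- sample(2:6, 1)
    true <- rep(vocab, each = n_per)  # balanced by construction
    pred <- sample(vocab, 2 * n_per, replace = TRUE)
    m <- compute_metrics(true, pred, vocab)
    expect_equal(m$accuracy, m$macro_recall, tolerance = 1e-12)
  }
})

test_that("micro-averaged F1 equals accuracy in binary single-label tasks", {
  set.seed(32)
  vocab <- c("a", "b")
  for (i in 1:200) {
    n <- sample(4:12, 1)
    true <- sample(vocab, n, replace = TRUE)
    pred <- sample(vocab, n, replace = TRUE)
    m <- compute_metrics(true, pred, vocab)
    conf <- m$confusion
    tp_micro <- sum(diag(conf))
    fp_micro <- sum(conf) - tp_micro  # every error is one FP and one FN
    micro_f1 <- 2 * tp_micro / (2 * tp_micro + fp_micro + fp_micro)
    expect_equal(micro_f1, m$accuracy)
  }
})

test_that("metrics are invariant under simultaneous permutation", {
  set.seed(33)
  vocab <- c("a", "b", "c")
  true <- sample(vocab, 30, replace = TRUE)
  pred <- sample(vocab, 30, replace = TRUE)
  perm <- sample(30)
  m1 <- compute_metrics(true, pred, vocab)
  m2 <- compute_metrics(true[perm], pred[perm], vocab)
  expect_equal(m1$accuracy, m2$accuracy)
  expect_equal(m1$per_class, m2$per_class)
  expect_error(compute_metrics(c("a", "z"), c("a", "a"), vocab), "vocabulary")
})

test_that("confidence intervals match hand computations", {
  expect_equal(confidence_interval(rep(0.7, 10)),
               c(mean = 0.7, half_width = 0))
  v <- rep(c(0, 1), each = 50)
  ci <- confidence_interval(v)
  expect_equal(unname(ci["mean"]), 0.5)
  expect_equal(unname(ci["half_width"]), qnorm(0.95) * sd(v),
               tolerance = 1e-12)
  expect_equal(unname(ci["half_width"]), 0.8266, tolerance = 1e-4)
  # homogeneity under scaling
  set.seed(34)
  x <- runif(20)
  expect_equal(unname(confidence_interval(3 * x)["half_width"]),
               3 * unname(confidence_interval(x)["half_width"]))
  expect_error(confidence_interval(1), ">= 2")
  # percentile variant is available
  ci_p <- confidence_interval(v, method = "percentile")
  expect_equal(unname(ci_p["half_width"]), 0.5)
})

test_that("run_experiment is deterministic and bookkeeps repeats", {
  ds <- fx_polyp_small()$dataset
  enc <- fx_tiny_encoder()
  sp <- split_spec(n_repeats = 4, seed = 21)
  r1 <- run_experiment(ds, enc, head_kinds = c("one_nn", "centroid"),
                       splits = sp, fine_tune = FALSE, seed = 11)
  r2 <- run_experiment(ds, enc, head_kinds = c("one_nn", "centroid"),
                       splits = sp, fine_tune = FALSE, seed = 11)
  expect_length(r1$per_repeat, 4L)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$per_repeat[[2]]$one_nn$confusion,
                   r2$per_repeat[[2]]$one_nn$confusion)
  expect_true(all(r1$summary$ci_half_width >= 0))
})

test_that("eval reports export to JSON and CSV", {
  ds <- fx_polyp_small()$dataset
  rep <- run_experiment(ds, fx_tiny_encoder(), head_kinds = "centroid",
                        splits = split_spec(n_repeats = 2, seed = 2),
                        fine_tune = FALSE, seed = 2)
  dir <- tempfile()
  write_eval_report(rep, dir)
  expect_true(file.exists(file.path(dir, "summary.csv")))
  expect_true(file.exists(file.path(dir, "variances.csv")))
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$n_repeats, 2L)
  unlink(dir, recursive = TRUE)
})
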