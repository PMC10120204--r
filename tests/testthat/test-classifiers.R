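# Embedding-space discriminators and the variance diagnostic.

test_that("1-nn predictions equal an exhaustive-distance oracle", {
  set.seed(23)
  for (trial in 1:100) {
    d <- sample(2:8, 1)
    train <- matrix(rnorm(30 * d), 30, d)
    labels <- sample(c("x", "y", "z"), 30, replace = TRUE)
    while (length(unique(labels)) < 2)
      labels <- sample(c("x", "y", "z"), 30, replace = TRUE)
    query <- matrix(rnorm(10 * d), 10, d)
    head <- fit_head("one_nn", train, labels)
    got <- predict(head, query)
    oracle <- apply(query, 1, function(q) {
      labels[which.min(colSums((t(train) - q)^2))]
    })
    expect_identical(got, unname(oracle))
  }
})

test_that("one_nn stores the training embeddings verbatim", {
  set.seed(24)
  z <- matrix(rnorm(20), 10, 2)
  labs <- rep(c("a", "b"), 5)
  head <- fit_head("one_nn", z, labs)
  expect_identical(head$state$train, z)
  expect_identical(head$state$labels, labs)
  # single training point per class: every query near it gets that label
  h1 <- fit_head("one_nn", rbind(c(0, 0), c(10, 10)), c("a", "b"))
  expect_equal(predict(h1, rbind(c(1, 1), c(9, 9))), c("a", "b"))
})

test_that("centroid head matches a class-mean oracle and breaks ties low", {
  set.seed(25)
  z <- rbind(matrix(rnorm(20, mean = 0), 10, 2),
             matrix(rnorm(20, mean = 6), 10, 2))
  labs <- rep(c("a", "b"), each = 10)
  head <- fit_head("centroid", z, labs)
  expect_equal(head$state$centroids["a", ], colMeans(z[1:10, ]))
  expect_equal(head$state$centroids["b", ], colMeans(z[11:20, ]))
  q <- matrix(rnorm(16, mean = 3), 8, 2)
  oracle <- apply(q, 1, function(p) {
    c("a", "b")[which.min(c(sum((p - colMeans(z[1:10, ]))^2),
                            sum((p - colMeans(z[11:20, ]))^2)))]
  })
  expect_identical(predict(head, q), unname(oracle))
  # forced tie: query equidistant from both centroids -> earlier class
  sym <- fit_head("centroid", rbind(c(-1, 0), c(1, 0)), c("a", "b"),
                  class_vocabulary = c("a", "b"))
  expect_equal(predict(sym, rbind(c(0, 5))), "a")
})

test_that("mean-distance centroid rule is available and differs when it should", {
  # class a: tight pair; class b: two far-apart members whose mean sits at
  # the origin-side -- the two rules can disagree on mid queries
  z <- rbind(c(0, 0), c(0.2, 0), c(5, 5), c(5, -5))
  labs <- c("a", "a", "b", "b")
  h_mean <- fit_head("centroid", z, labs, params = list(rule = "class_mean"))
  h_dist <- fit_head("centroid", z, labs,
                     params = list(rule = "mean_distance"))
  q <- rbind(c(3.5, 0))
  expect_equal(predict(h_mean, q), "b")  # nearer to mean of b = (5, 0)
  expect_equal(predict(h_dist, q), "a")  # b members are far individually
})

test_that("RBF-SVM separates a linearly separable toy set perfectly", {
  set.seed(26)
  z <- rbind(matrix(rnorm(20, mean = 0, sd = 0.3), 10, 2),
             matrix(rnorm(20, mean = 4, sd = 0.3), 10, 2))
  labs <- rep(c("lo", "hi"), each = 10)
  head <- fit_head("svm_rbf", z, labs)
  expect_identical(predict(head, z), labs)  # 100% training accuracy
})

test_that("heads validate dimensionality and class counts", {
  z <- matrix(rnorm(20), 10, 2)
  expect_error(fit_head("one_nn", z, rep("a", 10)), ">= 2 classes")
  head <- fit_head("one_nn", z, rep(c("a", "b"), 5))
  expect_error(predict(head, matrix(0, 2, 3)), "dimensionality")
})

test_that("1-nn and centroid are invariant under global isometries", {
  set.seed(27)
  z <- matrix(rnorm(60), 30, 2)
  labs <- sample(c("a", "b"), 30, replace = TRUE)
  while (length(unique(labs)) < 2) labs <- sample(c("a", "b"), 30, TRUE)
  q <- matrix(rnorm(20), 10, 2)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shift <- c(3, -7)
  iso <- function(m) sweep(m %*% R, 2, -shift)
  for (kind in c("one_nn", "centroid")) {
    before <- predict(fit_head(kind, z, labs), q)
    after <- predict(fit_head(kind, iso(z), labs), iso(q))
    expect_identical(before, after)
  }
})

test_that("centroid predictions are invariant under duplicating every point", {
  set.seed(28)
  z <- matrix(rnorm(40), 20, 2)
  labs <- rep(c("a", "b"), 10)
  q <- matrix(rnorm(10), 5, 2)
  h1 <- fit_head("centroid", z, labs)
  h2 <- fit_head("centroid", rbind(z, z), c(labs, labs))
  expect_identical(predict(h1, q), predict(h2, q))
  expect_equal(h1$state$centroids, h2$state$centroids)
})

test_that("variance report matches closed forms on planted clusters", {
  # two point-mass classes at distance d: intra = 0, normalized inter = 1
  z <- rbind(matrix(1, 5, 3), matrix(4, 7, 3))
  labs <- c(rep("p", 5), rep("q", 7))
  vr <- class_variances(z, labs)
  expect_equal(unname(vr$intra), c(0, 0))
  expect_identical(vr$inter, 1)
  # all embeddings identical: normalization must fail loudly
  expect_error(class_variances(matrix(2, 10, 3), rep(c("a", "b"), 5)),
               "zero")
  # planted isotropic gaussians: intra recovers d * sigma^2 within 10%
  set.seed(29)
  n <- 1000; d <- 8; sigma <- 1.7
  z <- rbind(matrix(rnorm(n * d, 0, sigma), n, d),
             matrix(rnorm(n * d, 3, sigma), n, d))
  labs <- rep(c("a", "b"), each = n)
  vr <- class_variances(z, labs)
  expect_equal(unname(vr$raw$intra["a"]), d * sigma^2, tolerance = 0.1)
  expect_equal(unname(vr$raw$intra["b"]), d * sigma^2, tolerance = 0.1)
  expect_identical(vr$inter, 1)
})
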