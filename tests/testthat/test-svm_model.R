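test_that("the PUK kernel matches hand-evaluated points", {
  set.seed(1)
  x <- stats::rnorm(5)
  expect_equal(puk_kernel(x, x), 1.0)
  # omega = 1, sigma = 1, distance 1: 2^(1/1)-1 = 1, (2*1)^2 = 4, 1/(1+4)
  expect_equal(puk_kernel(c(0, 0), c(1, 0), omega = 1, sigma = 1), 0.2)
  for (i in 1:20) {
    a <- stats::rnorm(4); b <- stats::rnorm(4)
    om <- stats::runif(1, 0.5, 20); sg <- stats::runif(1, 0.5, 10)
    expect_equal(puk_kernel(a, b, om, sg), puk_kernel(b, a, om, sg))
  }
  expect_error(puk_kernel(1:3, 1:4), "dimension")
  expect_error(puk_kernel(1:3, 1:3, omega = -1), "positive")
})

test_that("the vectorized Gram matrix agrees with the scalar kernel", {
  set.seed(2)
  x <- matrix(stats::rnorm(30), 6, 5)
  y <- matrix(stats::rnorm(20), 4, 5)
  g <- puk_gram(x, y, omega = 3, sigma = 2)
  for (i in 1:6) for (j in 1:4) {
    expect_equal(g[i, j], puk_kernel(x[i, ], y[j, ], 3, 2), tolerance = 1e-12)
  }
})

test_that("PUK is a valid decreasing kernel", {
  # strictly decreasing in distance, vanishing at infinity
  d <- seq(0, 50, by = 0.5)
  k <- vapply(d, function(dd) puk_kernel(0, dd, omega = 2, sigma = 1), 0)
  expect_true(all(diff(k) < 0))
  expect_lt(k[length(k)], 1e-3)
  # Gram matrices are positive semidefinite on random feature sets
  set.seed(3)
  for (i in 1:20) {
    n <- sample(5:50, 1); p <- sample(2:10, 1)
    x <- matrix(stats::rnorm(n * p), n, p)
    om <- sample(c(0.5, 1, 2, 21), 1); sg <- sample(c(0.5, 1, 7), 1)
    ev <- eigen(puk_gram(x, omega = om, sigma = sg), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
})

test_that("training separates well-separated blobs and errors sensibly", {
  toy <- make_separable_toy(40, gap = 10, seed = 21)
  model <- puk_svm(toy)
  expect_equal(model$training_accuracy, 1.0)
  expect_true(all(predict(model, toy, type = "class") == toy$labels))
  expect_error(puk_svm(toy$values, labels = rep(TRUE, 40)), "each class")
  bad <- toy$values; bad[1, 1] <- NA
  expect_error(puk_svm(bad, labels = toy$labels), "non-finite")
})

test_that("duplicating every row leaves the decision boundary unchanged", {
  toy <- make_separable_toy(30, gap = 6, seed = 22)
  m1 <- puk_svm(toy, calibrate = FALSE)
  dup <- descriptor_matrix(
    rbind(toy$values,
          `rownames<-`(toy$values, paste0(rownames(toy$values), "_b"))),
    labels = rep(toy$labels, 2))
  m2 <- puk_svm(dup, calibrate = FALSE)
  expect_identical(predict(m1, toy, type = "class"),
                   predict(m2, toy, type = "class"))
})

test_that("probabilities are calibrated, complementary and column-order safe", {
  toy <- make_separable_toy(60, gap = 8, seed = 23)
  model <- puk_svm(toy)
  p <- predict(model, toy, type = "probability")
  expect_true(all(p >= 0 & p <= 1))
  # the two class probabilities sum to one by construction
  expect_equal(p + (1 - p), rep(1, 60), ignore_attr = TRUE)
  expect_true(mean(p[toy$labels]) > 0.9)
  expect_true(mean(p[!toy$labels]) < 0.1)
  # permuting columns must not change predictions (name-based alignment)
  perm <- toy$values[, c("F2", "F1")]
  expect_identical(predict(model, perm, type = "class"),
                   predict(model, toy, type = "class"))
  expect_error(predict(model, toy$values[, "F1", drop = FALSE]), "missing")
})

test_that("models survive the portable archive round-trip", {
  toy <- make_separable_toy(40, gap = 6, seed = 24)
  model <- puk_svm(toy)
  path <- tempfile(fileext = ".json")
  save_model(model, path, recipe = list(family = "0d"))
  back <- load_model(path)
  expect_equal(predict(back, toy, type = "decision"),
               predict(model, toy, type = "decision"), tolerance = 1e-10)
  expect_equal(predict(back, toy, type = "probability"),
               predict(model, toy, type = "probability"), tolerance = 1e-10)
  expect_identical(attr(back, "recipe")$family, "0d")
})

test_that("repeated stratified CV reports run-level mean and spread", {
  toy <- make_separable_toy(200, gap = 8, seed = 25)
  rep1 <- crossvalidate(toy, folds = 10, n_runs = 3, base_seed = 9)
  expect_gte(rep1$mean_accuracy, 0.95)
  expect_identical(nrow(rep1$runs), 3L)
  expect_gte(rep1$sd_accuracy, 0)
  # identical protocol and seed reproduces the report exactly
  rep2 <- crossvalidate(toy, folds = 10, n_runs = 3, base_seed = 9)
  expect_identical(rep1$runs, rep2$runs)
  # class smaller than the fold count is rejected
  tiny <- make_separable_toy(10, gap = 8, seed = 26)
  expect_error(crossvalidate(tiny, folds = 10), "folds")
})

test_that("gap-free blobs cross-validate at chance level", {
  toy <- make_separable_toy(200, gap = 0, seed = 27)
  rep <- crossvalidate(toy, folds = 5, n_runs = 2, base_seed = 31)
  # 99% binomial band around 0.5 at n = 200
  half_width <- stats::qnorm(0.995) * sqrt(0.25 / 200)
  expect_lt(abs(rep$mean_accuracy - 0.5), half_width + 0.02)
})

test_that("grid tuning picks the clearly superior configuration", {
  # moderate separation so an absurdly small penalty visibly underfits
  toy <- make_separable_toy(60, gap = 2, seed = 28)
  tuned <- grid_tune(toy, C = c(1e-6, 1), omega = 1, sigma = 1,
                     folds = 5, n_runs = 1, base_seed = 3)
  expect_equal(tuned$best$C, 1)
  expect_identical(nrow(tuned$results), 2L)
  # single-point grid returns that point; repeated call is deterministic
  one <- grid_tune(toy, C = 2, omega = 3, sigma = 2, folds = 5,
                   n_runs = 1, base_seed = 3)
  expect_equal(one$best$C, 2)
  expect_equal(one$best$omega, 3)
  expect_identical(grid_tune(toy, C = c(1e-6, 1), omega = 1, sigma = 1,
                             folds = 5, n_runs = 1, base_seed = 3)$results,
                   tuned$results)
})
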