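test_that("equal-frequency discretization splits and handles ties", {
  expect_identical(discretize(1:10, 2), rep(0:1, each = 5L))
  expect_identical(discretize(rep(3.3, 8), 2), rep(0L, 8))
  # tied values stay together: each distinct value occupies one bin
  expect_identical(discretize(c(1, 1, 1, 1, 2, 2, 2, 2), 2),
                   rep(0:1, each = 4L))
  expect_identical(discretize(c(5, 1, 3), 3), c(2L, 0L, 1L))
  expect_error(discretize(numeric(0)), "empty")
})

test_that("information gain matches hand cases and is bounded", {
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(information_gain(c(0, 0, 1, 1), lab)$ig, 1)   # perfect split
  expect_equal(information_gain(c(0, 1, 0, 1), lab)$ig, 0)   # independent
  # class entropy of a 691 / 487 split
  lab2 <- rep(c(TRUE, FALSE), c(691, 487))
  res <- information_gain(rep(0L, 1178), lab2)
  expect_equal(res$ig, 0)
  expect_equal(res$class_entropy, 0.9784, tolerance = 1e-3)
})

test_that("information gain agrees with a brute-force contingency oracle", {
  set.seed(404)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    binned <- sample.int(sample(2:6, 1), n, replace = TRUE)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
    expect_equal(information_gain(binned, labels)$ig,
                 ig_bruteforce(binned, labels), tolerance = 1e-12)
  }
})

test_that("information gain is symmetric under bin relabeling and label swap", {
  set.seed(405)
  for (i in 1:30) {
    n <- 40
    binned <- sample.int(4, n, replace = TRUE)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
    base <- information_gain(binned, labels)$ig
    relab <- c(3L, 1L, 4L, 2L)[binned]
    expect_equal(information_gain(relab, labels)$ig, base, tolerance = 1e-12)
    expect_equal(information_gain(binned, !labels)$ig, base, tolerance = 1e-12)
  }
})

# a small matrix with one perfect separator, one redundant copy pair and noise
make_selection_fixture <- function(n = 40, seed = 9) {
  set.seed(seed)
  labels <- rep(c(FALSE, TRUE), each = n / 2)
  sep <- ifelse(labels, 1, -1) + stats::rnorm(n, sd = 0.05)
  f <- stats::rnorm(n)
  m <- cbind(SEP = sep, F1 = f, F2 = 2 * f + 1e-9 * stats::rnorm(n),
             G1 = stats::rnorm(n), G2 = stats::rnorm(n))
  rownames(m) <- sprintf("i%02d", seq_len(n))
  descriptor_matrix(m, labels = labels)
}

test_that("the IG filter keeps separators and honours the threshold", {
  dm <- make_selection_fixture()
  sub <- ig_filter(dm)
  expect_true("SEP" %in% sub$names)
  expect_identical(sub$names[1], "SEP")           # ordered by descending IG
  expect_true(all(sub$ig[sub$names] >= sub$threshold))
  # fraction 0 keeps everything
  expect_length(ig_filter(dm, fraction = 0)$names, 5L)
  # IG never exceeds the class entropy
  expect_true(all(sub$ig <= sub$class_entropy + 1e-12))
})

test_that("the IG filter warns when nothing passes", {
  set.seed(10)
  m <- matrix(stats::rnorm(40), 20, 2,
              dimnames = list(sprintf("i%02d", 1:20), c("A", "B")))
  dm <- descriptor_matrix(m, labels = rep(c(TRUE, FALSE), 10))
  expect_warning(sub <- ig_filter(dm, fraction = 0.999), "no feature")
  expect_length(sub$names, 0L)
})

test_that("redundancy reduction collapses correlated clusters to centroids", {
  dm <- make_selection_fixture()
  sub <- redundancy_reduce(dm, colnames(dm$values))
  # F1 and F2 are rank-identical: exactly one survives
  expect_identical(sum(c("F1", "F2") %in% sub$names), 1L)
  expect_true(all(c("SEP", "G1", "G2") %in% sub$names))
  # two identical columns collapse to one representative
  m2 <- cbind(dm$values, F3 = dm$values[, "F1"])
  dm2 <- descriptor_matrix(m2, labels = dm$labels)
  sub2 <- redundancy_reduce(dm2, colnames(m2))
  expect_identical(sum(c("F1", "F2", "F3") %in% sub2$names), 1L)
})

test_that("anticorrelated duplicates are redundant under the default |rho|", {
  set.seed(11)
  f <- stats::rnorm(30)
  m <- cbind(A = f, B = -f, C = stats::rnorm(30))
  rownames(m) <- sprintf("i%02d", 1:30)
  dm <- descriptor_matrix(m, labels = rep(c(TRUE, FALSE), 15))
  expect_identical(sum(c("A", "B") %in%
                         redundancy_reduce(dm, colnames(m))$names), 1L)
  # signed linkage keeps both
  expect_identical(sum(c("A", "B") %in%
                         redundancy_reduce(dm, colnames(m),
                                           absolute = FALSE)$names), 2L)
})

test_that("single linkage chains transitive correlations into one cluster", {
  # brute-force check on the documented 3-column instance {f, 2f, g}
  set.seed(12)
  f <- stats::rnorm(25)
  g <- stats::rnorm(25)
  m <- cbind(f = f, f2 = 2 * f, g = g)
  rownames(m) <- sprintf("i%02d", 1:25)
  dm <- descriptor_matrix(m, labels = rep(c(TRUE, FALSE), c(13, 12)))
  sub <- redundancy_reduce(dm, colnames(m))
  expect_identical(length(sub$names), 2L)
  expect_true("g" %in% sub$names)
  expect_identical(unname(sub$clusters["f"]), unname(sub$clusters["f2"]))
  # no surviving pair is linked at the threshold, and no cluster vanished
  surv <- dm$values[, sub$names]
  rho <- abs(stats::cor(surv, method = "spearman"))
  diag(rho) <- 0
  expect_true(all(rho < 0.95))
  expect_setequal(unique(sub$clusters),
                  unique(sub$clusters[sub$names]))
})

test_that("the genetic wrapper finds a perfect separator and is reproducible", {
  dm <- make_selection_fixture()
  sub1 <- ga_wrapper_select(dm, colnames(dm$values), seed = 5)
  expect_true("SEP" %in% sub1$names)
  expect_equal(sub1$fitness, 1.0)
  sub2 <- ga_wrapper_select(dm, colnames(dm$values), seed = 5)
  expect_identical(sub1$names, sub2$names)
  expect_identical(sub1$fitness, sub2$fitness)
})

test_that("degenerate wrapper configurations still return a subset", {
  dm <- make_selection_fixture(n = 8)
  expect_warning(
    sub <- ga_wrapper_select(dm, colnames(dm$values),
                             ga = ga_params(pop_size = 1L, generations = 0L,
                                            elitism = 1L),
                             folds = 5L, seed = 3),
    "reducing")
  expect_s3_class(sub, "feature_subset")
  expect_true(length(sub$names) >= 0)
})

test_that("stage sizes never increase along the pipeline", {
  dm <- make_selection_fixture()
  stages <- select_features(dm, seed = 2, min_keep = 1L)
  expect_lte(length(stages$wrapper$names), length(stages$redundancy$names))
  expect_lte(length(stages$redundancy$names), length(stages$ig$names))
  expect_lte(length(stages$ig$names), ncol(dm$values))
})

test_that("the selection report tabulates every input feature", {
  dm <- make_selection_fixture()
  stages <- select_features(dm, seed = 2, min_keep = 1L)
  path <- tempfile(fileext = ".tsv")
  write_selection_report(stages, path)
  rep <- utils::read.delim(path)
  expect_setequal(rep$feature, colnames(dm$values))
  expect_true(all(rep$stage_survived %in%
                    c("none", "ig", "redundancy", "wrapper")))
})
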