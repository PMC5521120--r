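# Three-stage feature selection: information-gain filter, single-linkage
# Spearman redundancy clustering, genetic-search wrapper.

#' Equal-frequency discretization
#'
#' Bins a numeric column into (at most) `n_bins` equal-frequency bins. Tied
#' values always share one bin (the bin of their lowest sorted position), so
#' heavily tied columns may occupy fewer bins; a constant column occupies a
#' single bin.
#'
#' @param column Numeric vector.
#' @param n_bins Number of bins (>= 2).
#' @return Integer vector of 0-based bin ids.
#' @export
#' @examples
#' discretize(1:10, 2)
discretize <- function(column, n_bins = 10L) {
  stopifnot(n_bins >= 2L)
  n <- length(column)
  if (n == 0L) stop("empty column", call. = FALSE)
  r <- rank(column, ties.method = "min")
  as.integer(floor((r - 1) * n_bins / n))
}

# entropy (bits) of a count vector
.entropy <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Information gain of a binned feature about a binary class
#'
#' `IG = H(X) - H(X|Y)` in bits, where `X` is the class variable and `Y` the
#' binned feature; `H(X|Y) = sum_j P(y_j) H(X | y_j)` from the joint counts.
#' Empty cells contribute nothing.
#'
#' @param binned Integer vector of bin ids (any integer coding).
#' @param labels Logical vector, `TRUE` = positive class.
#' @return List with `ig` and `class_entropy` (both in bits).
#' @export
#' @examples
#' information_gain(c(0, 0, 1, 1), c(TRUE, TRUE, FALSE, FALSE))$ig # 1 bit
information_gain <- function(binned, labels) {
  stopifnot(length(binned) == length(labels), is.logical(labels),
            length(binned) >= 1L)
  n <- length(labels)
  hx <- .entropy(c(sum(labels), sum(!labels)))
  bins <- match(binned, unique(binned))
  k <- max(bins)
  pos <- tabulate(bins[labels], nbins = k)
  tot <- tabulate(bins, nbins = k)
  hxy <- 0
  for (j in seq_len(k)) {
    if (tot[j] > 0) {
      hxy <- hxy + tot[j] / n * .entropy(c(pos[j], tot[j] - pos[j]))
    }
  }
  list(ig = max(hx - hxy, 0), class_entropy = hx)
}

#' A selected feature subset
#'
#' @param names Ordered feature names.
#' @param stage One of `"ig"`, `"redundancy"`, `"wrapper"`.
#' @param ... Stage details (`ig` values, `clusters`, `fitness`, ...).
#' @return An object of class `feature_subset`.
#' @export
feature_subset <- function(names, stage, ...) {
  stopifnot(!anyDuplicated(names))
  structure(c(list(names = names, stage = stage), list(...)),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat(sprintf("Feature subset (stage: %s): %d feature(s)\n",
              x$stage, length(x$names)))
  if (!is.null(x$fitness) && is.finite(x$fitness)) {
    cat(sprintf("  wrapper fitness (positive-class F1): %.4f\n", x$fitness))
  }
  cat("  ", paste(utils::head(x$names, 8L), collapse = ", "),
      if (length(x$names) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.feature_subset <- function(x) length(x$names)

# per-column IG for a matrix of features (fast path used by ig_filter)
.column_igs <- function(m, labels, n_bins) {
  n <- nrow(m)
  hx <- .entropy(c(sum(labels), sum(!labels)))
  igs <- vapply(seq_len(ncol(m)), function(j) {
    b <- floor((rank(m[, j], ties.method = "min") - 1) * n_bins / n)
    bins <- match(b, unique(b))
    k <- max(bins)
    pos <- tabulate(bins[labels], nbins = k)
    tot <- tabulate(bins, nbins = k)
    nz <- tot > 0
    hxy <- sum(vapply(which(nz), function(i) {
      tot[i] / n * .entropy(c(pos[i], tot[i] - pos[i]))
    }, 0))
    max(hx - hxy, 0)
  }, 0)
  list(ig = stats::setNames(igs, colnames(m)), class_entropy = hx)
}

#' Information-gain filter
#'
#' Keeps every feature whose information gain about the class reaches
#' `fraction` of the class entropy `H(X)` (default 15%). Features are
#' returned in decreasing IG order.
#'
#' @param dm A labelled `descriptor_matrix`.
#' @param fraction Fraction of `H(X)` a feature must attain.
#' @param n_bins Bins for equal-frequency discretization.
#' @return A `feature_subset` (stage `"ig"`) carrying the per-feature `ig`
#'   values and `class_entropy`.
#' @export
ig_filter <- function(dm, fraction = 0.15, n_bins = 10L) {
  stopifnot(inherits(dm, "descriptor_matrix"))
  check_two_classes(dm$labels)
  res <- .column_igs(dm$values, dm$labels, n_bins)
  thr <- fraction * res$class_entropy
  keep <- res$ig[res$ig >= thr]
  keep <- keep[order(-keep)]
  if (!length(keep)) {
    warning("no feature reaches the information-gain threshold (",
            signif(thr, 4), " bits)", call. = FALSE)
  }
  feature_subset(names(keep), stage = "ig", ig = res$ig,
                 class_entropy = res$class_entropy, threshold = thr)
}

#' Redundancy reduction by single-linkage Spearman clustering
#'
#' Links two features when the magnitude of their Spearman rank correlation
#' reaches `rho`; connected components of this link graph form the clusters
#' (single linkage). One representative per cluster survives: the column
#' closest (Euclidean, after z-scoring) to the cluster's mean column.
#'
#' @param dm A `descriptor_matrix`.
#' @param subset A `feature_subset` (or character vector) to reduce.
#' @param rho Spearman linkage threshold (default 0.95).
#' @param absolute Link on `|rho|` (default) rather than signed `rho`.
#' @return A `feature_subset` (stage `"redundancy"`) with a `clusters`
#'   assignment over the input features.
#' @export
redundancy_reduce <- function(dm, subset, rho = 0.95, absolute = TRUE) {
  stopifnot(inherits(dm, "descriptor_matrix"))
  feats <- if (inherits(subset, "feature_subset")) subset$names else subset
  stopifnot(length(feats) >= 1L)
  x <- dm$values[, feats, drop = FALSE]
  p <- ncol(x)
  rk <- apply(x, 2L, rank)
  rk <- scale(rk)
  rk[is.na(rk)] <- 0                      # constant column: no links
  cors <- crossprod(rk) / (nrow(x) - 1)
  if (absolute) cors <- abs(cors)
  adj <- cors >= rho
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  z <- scale(x)
  z[is.na(z)] <- 0
  reps <- vapply(split(seq_len(p), comp), function(ix) {
    if (length(ix) == 1L) return(feats[ix])
    centroid <- rowMeans(z[, ix, drop = FALSE])
    d2 <- colSums((z[, ix, drop = FALSE] - centroid)^2)
    feats[ix[which.min(d2)]]
  }, "")
  reps <- feats[feats %in% reps]          # keep the input ordering
  feature_subset(reps, stage = "redundancy",
                 clusters = stats::setNames(as.integer(comp), feats))
}

#' Genetic-search wrapper parameters
#'
#' @param pop_size Population size.
#' @param generations Number of generations.
#' @param crossover Crossover probability.
#' @param mutation Per-bit mutation probability.
#' @param elitism Number of best chromosomes copied unchanged.
#' @return A `ga_params` list.
#' @export
ga_params <- function(pop_size = 20L, generations = 20L, crossover = 0.6,
                      mutation = 0.033, elitism = 1L) {
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 crossover = crossover, mutation = mutation,
                 elitism = as.integer(elitism)),
            class = "ga_params")
}

#' Genetic-search wrapper feature selection
#'
#' Searches bitmask chromosomes over the candidate features with a generational
#' genetic algorithm (fitness-proportional selection, single-point crossover,
#' per-bit mutation, elitism). Each chromosome is scored by the positive-class
#' F1 of a PUK-kernel SVM in stratified 5-fold cross-validation; the best
#' subset ever evaluated is returned. Fully deterministic given `seed`.
#'
#' @param dm A labelled `descriptor_matrix`.
#' @param subset Candidate features (a `feature_subset` or character vector).
#' @param ga A [ga_params()] list.
#' @param svm An [svm_params()] list used for the fitness SVM.
#' @param folds Folds for the fitness cross-validation (auto-reduced with a
#'   warning when a class has fewer members).
#' @param seed Integer seed controlling the whole search.
#' @return A `feature_subset` (stage `"wrapper"`) with the winning `fitness`.
#' @export
ga_wrapper_select <- function(dm, subset, ga = ga_params(),
                              svm = svm_params(), folds = 5L,
                              seed = 1L) {
  stopifnot(inherits(dm, "descriptor_matrix"))
  check_two_classes(dm$labels)
  feats <- if (inherits(subset, "feature_subset")) subset$names else subset
  stopifnot(length(feats) >= 1L)
  x <- dm$values[, feats, drop = FALSE]
  y <- dm$labels
  min_class <- min(sum(y), sum(!y))
  if (min_class < folds) {
    warning("reducing wrapper CV folds from ", folds, " to ", min_class,
            call. = FALSE)
    folds <- max(2L, min_class)
  }
  p <- length(feats)
  set.seed(seed)
  fold_ids <- stratified_fold_ids(y, folds)
  cache <- new.env(parent = emptyenv())
  fitness_of <- function(mask) {
    if (!any(mask)) return(0)
    key <- paste(which(mask), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    f1 <- cv_fold_f1(x[, mask, drop = FALSE], y, fold_ids, svm)
    cache[[key]] <- f1
    f1
  }
  pop <- matrix(stats::runif(ga$pop_size * p) < 0.5, ga$pop_size, p)
  fit <- apply(pop, 1L, fitness_of)
  best_mask <- pop[which.max(fit), ]
  best_fit <- max(fit)
  for (gen in seq_len(ga$generations)) {
    probs <- if (sum(fit) > 0) fit / sum(fit) else rep(1 / length(fit), length(fit))
    newpop <- matrix(FALSE, ga$pop_size, p)
    elite <- order(-fit)[seq_len(min(ga$elitism, ga$pop_size))]
    newpop[seq_along(elite), ] <- pop[elite, , drop = FALSE]
    i <- length(elite)
    while (i < ga$pop_size) {
      parents <- sample.int(ga$pop_size, 2L, replace = TRUE, prob = probs)
      c1 <- pop[parents[1L], ]; c2 <- pop[parents[2L], ]
      if (stats::runif(1) < ga$crossover && p > 1L) {
        cut <- sample.int(p - 1L, 1L)
        tmp <- c1
        c1 <- c(c1[seq_len(cut)], c2[(cut + 1L):p])
        c2 <- c(c2[seq_len(cut)], tmp[(cut + 1L):p])
      }
      for (child in list(c1, c2)) {
        if (i >= ga$pop_size) break
        flip <- stats::runif(p) < ga$mutation
        i <- i + 1L
        newpop[i, ] <- xor(child, flip)
      }
    }
    pop <- newpop
    fit <- apply(pop, 1L, fitness_of)
    if (max(fit) > best_fit) {
      best_fit <- max(fit)
      best_mask <- pop[which.max(fit), ]
    }
  }
  feature_subset(feats[best_mask], stage = "wrapper", fitness = best_fit)
}

#' Run the full three-stage selection pipeline
#'
#' Information-gain filter, then Spearman redundancy clustering, then the
#' genetic-search wrapper. When fewer than `min_keep` features pass the IG
#' threshold (i.e. the data carry no class signal), a seeded random subset of
#' `min_keep` features is kept instead, with a warning, so downstream stages
#' remain runnable. The fallback is deliberately label-independent: ranking
#' uninformative features by their (spurious) IG would re-introduce the
#' selection bias the threshold exists to prevent.
#'
#' @param dm A labelled `descriptor_matrix`.
#' @param fraction,n_bins Passed to [ig_filter()].
#' @param rho Passed to [redundancy_reduce()].
#' @param ga,svm,wrapper_folds Passed to [ga_wrapper_select()].
#' @param seed Seed for the wrapper search.
#' @param min_keep Minimum number of features carried past the IG stage.
#' @param skip_wrapper Stop after redundancy reduction.
#' @return List of `feature_subset`s: `ig`, `redundancy` and (unless skipped)
#'   `wrapper`.
#' @export
select_features <- function(dm, fraction = 0.15, n_bins = 10L, rho = 0.95,
                            ga = ga_params(), svm = svm_params(),
                            wrapper_folds = 5L, seed = 1L, min_keep = 10L,
                            skip_wrapper = FALSE) {
  ig_sub <- suppressWarnings(ig_filter(dm, fraction = fraction,
                                       n_bins = n_bins))
  if (length(ig_sub$names) < min_keep) {
    k <- min(min_keep, length(ig_sub$ig))
    warning("only ", length(ig_sub$names), " feature(s) pass the IG ",
            "threshold; keeping a seeded random subset of ", k, call. = FALSE)
    set.seed(seed)
    keep <- sample(names(ig_sub$ig), k)
    ig_sub <- feature_subset(keep, stage = "ig", ig = ig_sub$ig,
                             class_entropy = ig_sub$class_entropy,
                             threshold = ig_sub$threshold, fallback = TRUE)
  }
  red_sub <- redundancy_reduce(dm, ig_sub, rho = rho)
  out <- list(ig = ig_sub, redundancy = red_sub)
  if (!skip_wrapper) {
    if (isTRUE(ig_sub$fallback)) {
      # nothing was informative at the threshold: a supervised wrapper run
      # over these features could only fit noise, so pass them through
      warning("no informative features at the IG threshold; ",
              "skipping the supervised wrapper", call. = FALSE)
      out$wrapper <- feature_subset(red_sub$names, stage = "wrapper",
                                    fitness = NA_real_, skipped = TRUE)
    } else {
      out$wrapper <- ga_wrapper_select(dm, red_sub, ga = ga, svm = svm,
                                       folds = wrapper_folds, seed = seed)
    }
  }
  out
}

#' Write a selection report as TSV
#'
#' One row per feature entering the pipeline: IG value, redundancy cluster id
#' and the last stage the feature survived.
#'
#' @param stages Result of [select_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(stages, path) {
  feats <- names(stages$ig$ig)
  stage <- rep("none", length(feats))
  stage[feats %in% stages$ig$names] <- "ig"
  stage[feats %in% stages$redundancy$names] <- "redundancy"
  if (!is.null(stages$wrapper)) {
    stage[feats %in% stages$wrapper$names] <- "wrapper"
  }
  cl <- stages$redundancy$clusters[feats]
  df <- data.frame(feature = feats, ig = unname(stages$ig$ig),
                   cluster = ifelse(is.na(cl), "", as.character(cl)),
                   stage_survived = stage, stringsAsFactors = FALSE)
  df <- df[order(-df$ig), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
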