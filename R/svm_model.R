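# Pearson VII universal kernel (PUK) SVM: kernel, training with logistic
# probability calibration, repeated stratified cross-validation, grid tuning.

#' Pearson VII universal kernel
#'
#' `K(x, y) = 1 / [1 + (2 ||x-y|| sqrt(2^(1/omega) - 1) / sigma)^2]^omega`.
#' `omega` controls the tail shape of the Pearson VII peak (omega = 1 gives a
#' Lorentzian, omega -> Inf a Gaussian); `sigma` its width. `K(x, x) = 1` and
#' K decreases strictly with distance.
#'
#' @param x,y Numeric vectors of equal length.
#' @param omega,sigma Positive kernel parameters.
#' @return Similarity in (0, 1].
#' @export
#' @examples
#' puk_kernel(c(0, 0), c(1, 0), omega = 1, sigma = 1) # 0.2
puk_kernel <- function(x, y, omega = 1, sigma = 1) {
  if (length(x) != length(y)) stop("dimension mismatch", call. = FALSE)
  if (omega <= 0 || sigma <= 0) stop("omega and sigma must be positive",
                                     call. = FALSE)
  d2 <- sum((x - y)^2)
  1 / (1 + 4 * d2 * (2^(1 / omega) - 1) / sigma^2)^omega
}

#' PUK Gram matrix between two sets of row vectors
#'
#' @param x Numeric matrix (instances x features).
#' @param y Numeric matrix with the same columns, or `NULL` for `x` vs `x`.
#' @param omega,sigma Kernel parameters.
#' @return `nrow(x)` x `nrow(y)` kernel matrix.
#' @export
puk_gram <- function(x, y = NULL, omega = 1, sigma = 1) {
  if (omega <= 0 || sigma <= 0) stop("omega and sigma must be positive",
                                     call. = FALSE)
  if (is.null(y)) y <- x
  if (ncol(x) != ncol(y)) stop("dimension mismatch", call. = FALSE)
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  1 / (1 + 4 * d2 * (2^(1 / omega) - 1) / sigma^2)^omega
}

#' SVM hyperparameters
#'
#' @param C Soft-margin penalty (> 0).
#' @param omega,sigma PUK kernel shape and width (> 0).
#' @param standardize Z-score features using training statistics (default
#'   `TRUE`; PUK distances are scale-sensitive).
#' @return An `svm_params` list.
#' @export
svm_params <- function(C = 1, omega = 1, sigma = 1, standardize = TRUE) {
  stopifnot(C > 0, omega > 0, sigma > 0)
  structure(list(C = C, omega = omega, sigma = sigma,
                 standardize = standardize),
            class = "svm_params")
}

# stratified fold assignment: integer fold id per instance
stratified_fold_ids <- function(labels, k) {
  ids <- integer(length(labels))
  for (cls in c(TRUE, FALSE)) {
    ix <- which(labels == cls)
    ids[ix] <- sample(rep_len(seq_len(k), length(ix)))
  }
  ids
}

# z-scoring statistics from a training matrix (zero-variance columns get
# scale 1 so they map to a constant, not NaN)
.std_stats <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

.std_apply <- function(x, st) {
  sweep(sweep(x, 2L, st$center, "-"), 2L, st$scale, "/")
}

# core QP fit on a standardized matrix; returns sv rows, alpha*y coefs, bias
# and the sign that orients positive decisions toward the positive class
.fit_core <- function(xs, y, params) {
  k <- kernlab::as.kernelMatrix(puk_gram(xs, omega = params$omega,
                                         sigma = params$sigma))
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  fit <- kernlab::ksvm(k, yf, C = params$C, prob.model = FALSE)
  svi <- kernlab::SVindex(fit)
  coef <- kernlab::coef(fit)[[1L]]
  b <- kernlab::b(fit)
  d <- drop(k[, svi, drop = FALSE] %*% coef) - b
  # orient: decision > 0 must mean positive class
  sgn <- if (mean((d > 0) == y) >= mean((d < 0) == y)) 1 else -1
  list(sv = xs[svi, , drop = FALSE], coef = coef, b = b, sign = sgn,
       decision = sgn * d, n_sv = length(svi))
}

.core_decision <- function(core, xs, params) {
  kt <- puk_gram(xs, core$sv, omega = params$omega, sigma = params$sigma)
  core$sign * (drop(kt %*% core$coef) - core$b)
}

#' Train a PUK-kernel SVM classifier
#'
#' Fits a soft-margin SVM on the PUK Gram matrix of the (optionally z-scored)
#' features. Probability calibration is a logistic regression of the class on
#' the SVM decision value, fitted on out-of-fold decisions from an internal
#' stratified split so the calibration never sees its own training
#' predictions.
#'
#' @param x A labelled `descriptor_matrix`, or a numeric matrix with `labels`
#'   given separately.
#' @param labels Logical class vector (`TRUE` = positive) when `x` is a bare
#'   matrix.
#' @param params An [svm_params()] list.
#' @param calibrate Fit the out-of-fold logistic calibration (default `TRUE`).
#'   When `FALSE`, predicted probabilities fall back to a plain sigmoid of the
#'   decision value.
#' @param calib_folds Folds of the internal calibration split.
#' @return An object of class `puk_svm` with `predict`, `print` and `summary`
#'   methods.
#' @export
puk_svm <- function(x, labels = NULL, params = svm_params(),
                    calibrate = TRUE, calib_folds = 5L) {
  if (inherits(x, "descriptor_matrix")) {
    labels <- x$labels
    x <- x$values
  }
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  check_two_classes(labels)
  st <- if (params$standardize) .std_stats(x) else
    list(center = rep(0, ncol(x)), scale = rep(1, ncol(x)))
  xs <- .std_apply(x, st)
  core <- .fit_core(xs, labels, params)
  calib <- NULL
  if (calibrate) {
    k <- min(calib_folds, min(sum(labels), sum(!labels)))
    if (k >= 2L) {
      fold <- stratified_fold_ids(labels, k)
      d_oof <- numeric(length(labels))
      for (f in seq_len(k)) {
        tr <- fold != f
        sub <- .fit_core(xs[tr, , drop = FALSE], labels[tr], params)
        d_oof[!tr] <- .core_decision(sub, xs[!tr, , drop = FALSE], params)
      }
      g <- suppressWarnings(
        stats::glm(labels ~ d_oof, family = stats::binomial()))
      calib <- unname(stats::coef(g))
    }
  }
  structure(
    list(feature_names = colnames(x), params = params, center = st$center,
         scale = st$scale, sv = core$sv, coef = core$coef, b = core$b,
         sign = core$sign, n_sv = core$n_sv, calibration = calib,
         n_train = length(labels), class_balance = mean(labels),
         training_accuracy = mean((core$decision > 0) == labels)),
    class = "puk_svm")
}

#' @export
print.puk_svm <- function(x, ...) {
  cat("PUK-kernel SVM classifier\n")
  cat(sprintf("  C = %g, omega = %g, sigma = %g%s\n",
              x$params$C, x$params$omega, x$params$sigma,
              if (x$params$standardize) ", standardized features" else ""))
  cat(sprintf("  %d features, %d training instances, %d support vectors\n",
              length(x$feature_names), x$n_train, x$n_sv))
  cat(sprintf("  calibration: %s\n",
              if (is.null(x$calibration)) "none (sigmoid fallback)"
              else sprintf("logistic (a = %.3f, b = %.3f)",
                           x$calibration[2L], x$calibration[1L])))
  invisible(x)
}

#' @method summary puk_svm
#' @export
summary.puk_svm <- function(object, ...) {
  print(object)
  cat(sprintf("  training accuracy: %.2f%%\n",
              100 * object$training_accuracy))
  invisible(object)
}

#' Predict classes and probabilities from a PUK SVM
#'
#' Feature columns of `newdata` are aligned to the model by name, so column
#' order does not matter; missing columns are an error.
#'
#' @param object A `puk_svm` model.
#' @param newdata A `descriptor_matrix` or numeric matrix with named columns.
#' @param type `"class"` (logical, `TRUE` = positive), `"probability"`
#'   (positive-class probability) or `"decision"` (raw oriented decision
#'   value).
#' @param ... Unused.
#' @return Vector of predictions, named by instance id when available.
#' @method predict puk_svm
#' @export
predict.puk_svm <- function(object, newdata,
                            type = c("class", "probability", "decision"),
                            ...) {
  type <- match.arg(type)
  if (inherits(newdata, "descriptor_matrix")) newdata <- newdata$values
  miss <- setdiff(object$feature_names, colnames(newdata))
  if (length(miss)) {
    stop("missing feature column(s): ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  x <- newdata[, object$feature_names, drop = FALSE]
  xs <- .std_apply(x, list(center = object$center, scale = object$scale))
  kt <- puk_gram(xs, object$sv, omega = object$params$omega,
                 sigma = object$params$sigma)
  d <- object$sign * (drop(kt %*% object$coef) - object$b)
  names(d) <- rownames(newdata)
  switch(type,
         decision = d,
         class = d > 0,
         probability = if (is.null(object$calibration)) stats::plogis(d)
         else stats::plogis(object$calibration[1L] + object$calibration[2L] * d))
}

# positive-class F1 from logical truth/prediction
.f1_positive <- function(truth, pred) {
  tp <- sum(truth & pred)
  if (tp == 0) return(0)
  prec <- tp / sum(pred)
  rec <- tp / sum(truth)
  2 * prec * rec / (prec + rec)
}

# pooled positive-class F1 over pre-assigned folds (wrapper fitness path;
# no calibration, standardization fitted per training fold)
cv_fold_f1 <- function(x, labels, fold_ids, params) {
  pred <- logical(length(labels))
  for (f in sort(unique(fold_ids))) {
    tr <- fold_ids != f
    if (length(unique(labels[tr])) < 2L) next
    st <- if (params$standardize) .std_stats(x[tr, , drop = FALSE]) else
      list(center = rep(0, ncol(x)), scale = rep(1, ncol(x)))
    core <- .fit_core(.std_apply(x[tr, , drop = FALSE], st), labels[tr],
                      params)
    pred[!tr] <- .core_decision(core, .std_apply(x[!tr, , drop = FALSE], st),
                                params) > 0
  }
  .f1_positive(labels, pred)
}

#' Repeated stratified cross-validation of a PUK SVM
#'
#' Runs `n_runs` rounds of stratified `folds`-fold cross-validation; the fold
#' split of run `r` is drawn with seed `base_seed + r`, so runs differ only by
#' the random split. Standardization is fitted inside each training fold (no
#' leakage). Per run, accuracy and positive-class F1 are pooled over the
#' folds; the report gives their mean and standard deviation across runs.
#'
#' @param x A labelled `descriptor_matrix`, or matrix plus `labels`.
#' @param labels Logical class vector when `x` is a bare matrix.
#' @param params An [svm_params()] list.
#' @param folds Folds per run (each class must have at least `folds` members).
#' @param n_runs Number of repetitions.
#' @param base_seed Integer; run `r` uses seed `base_seed + r`.
#' @return A `cv_report`: data frame `runs` plus summary fields.
#' @export
crossvalidate <- function(x, labels = NULL, params = svm_params(),
                          folds = 10L, n_runs = 10L, base_seed = 1L) {
  if (inherits(x, "descriptor_matrix")) {
    labels <- x$labels
    x <- x$values
  }
  check_two_classes(labels)
  stopifnot(folds >= 2L)
  if (min(sum(labels), sum(!labels)) < folds) {
    stop("each class must have at least `folds` members", call. = FALSE)
  }
  acc <- f1 <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(base_seed + r)
    fold_ids <- stratified_fold_ids(labels, folds)
    pred <- logical(length(labels))
    for (f in seq_len(folds)) {
      tr <- fold_ids != f
      st <- if (params$standardize) .std_stats(x[tr, , drop = FALSE]) else
        list(center = rep(0, ncol(x)), scale = rep(1, ncol(x)))
      core <- .fit_core(.std_apply(x[tr, , drop = FALSE], st), labels[tr],
                        params)
      pred[!tr] <- .core_decision(core,
                                  .std_apply(x[!tr, , drop = FALSE], st),
                                  params) > 0
    }
    acc[r] <- mean(pred == labels)
    f1[r] <- .f1_positive(labels, pred)
  }
  structure(
    list(runs = data.frame(run = seq_len(n_runs), accuracy = acc, f1 = f1),
         mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
         mean_f1 = mean(f1), sd_f1 = stats::sd(f1),
         folds = folds, n_runs = n_runs,
         seeds = base_seed + seq_len(n_runs), params = params),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d x %d-fold cross-validation\n", x$n_runs, x$folds))
  cat(sprintf("  accuracy: %.2f +/- %.2f %%\n",
              100 * x$mean_accuracy,
              100 * ifelse(is.na(x$sd_accuracy), 0, x$sd_accuracy)))
  cat(sprintf("  positive-class F1: %.4f +/- %.4f\n",
              x$mean_f1, ifelse(is.na(x$sd_f1), 0, x$sd_f1)))
  invisible(x)
}

#' Write a cross-validation report as TSV
#'
#' @param report A `cv_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  utils::write.table(report$runs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Exhaustive grid search over SVM hyperparameters
#'
#' Maximizes mean cross-validated accuracy over the Cartesian grid; ties are
#' broken toward smaller `C`, then smaller `omega`.
#'
#' @param x A labelled `descriptor_matrix`, or matrix plus `labels`.
#' @param labels Logical class vector when `x` is a bare matrix.
#' @param C,omega,sigma Numeric vectors spanning the grid.
#' @param folds,n_runs,base_seed Passed to [crossvalidate()].
#' @param standardize Passed to [svm_params()].
#' @return List with `best` (an `svm_params`) and `results` (a data frame of
#'   all grid points with their mean accuracy).
#' @export
grid_tune <- function(x, labels = NULL, C = c(0.5, 1, 8, 64),
                      omega = c(1, 21), sigma = c(1, 7), folds = 10L,
                      n_runs = 1L, base_seed = 1L, standardize = TRUE) {
  grid <- expand.grid(C = C, omega = omega, sigma = sigma)
  if (!nrow(grid)) stop("empty grid", call. = FALSE)
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    p <- svm_params(grid$C[i], grid$omega[i], grid$sigma[i],
                    standardize = standardize)
    crossvalidate(x, labels, params = p, folds = folds, n_runs = n_runs,
                  base_seed = base_seed)$mean_accuracy
  }, 0)
  ord <- order(-grid$accuracy, grid$C, grid$omega, grid$sigma)
  best <- grid[ord[1L], ]
  list(best = svm_params(best$C, best$omega, best$sigma,
                         standardize = standardize),
       results = grid)
}

#' Save a trained model as a portable JSON archive
#'
#' @param model A `puk_svm`.
#' @param path Output path.
#' @param recipe Optional featurization recipe (a [featurize_config()] or any
#'   serializable list) stored alongside the model so prediction can
#'   re-featurize raw sequences.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, recipe = NULL) {
  stopifnot(inherits(model, "puk_svm"))
  obj <- list(
    format = "afseq-puk-svm", version = 1L,
    feature_names = model$feature_names,
    params = unclass(model$params),
    center = unname(model$center), scale = unname(model$scale),
    sv = unname(model$sv), coef = model$coef, b = model$b, sign = model$sign,
    n_sv = model$n_sv, calibration = model$calibration,
    n_train = model$n_train, class_balance = model$class_balance,
    training_accuracy = model$training_accuracy,
    recipe = if (is.null(recipe)) NULL else unclass(recipe))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model archive written by [save_model()]
#'
#' @param path Path to the JSON archive.
#' @return A `puk_svm` model; any stored featurization recipe is attached as
#'   attribute `"recipe"`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "afseq-puk-svm")) {
    stop("not an afseq model archive: ", path, call. = FALSE)
  }
  p <- obj$params
  model <- structure(
    list(feature_names = obj$feature_names,
         params = svm_params(p$C, p$omega, p$sigma,
                             standardize = isTRUE(p$standardize)),
         center = stats::setNames(obj$center, obj$feature_names),
         scale = stats::setNames(obj$scale, obj$feature_names),
         sv = matrix(unlist(obj$sv), nrow = obj$n_sv,
                     dimnames = list(NULL, obj$feature_names)),
         coef = obj$coef, b = obj$b, sign = obj$sign, n_sv = obj$n_sv,
         calibration = obj$calibration, n_train = obj$n_train,
         class_balance = obj$class_balance,
         training_accuracy = obj$training_accuracy),
    class = "puk_svm")
  if (!is.null(obj$recipe)) attr(model, "recipe") <- obj$recipe
  model
}
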