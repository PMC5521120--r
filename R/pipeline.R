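# End-to-end orchestration: featurize -> select -> cross-validate / train /
# predict, with file-based subcommands and reproducibility manifests.

#' Build a descriptor matrix for a descriptor family
#'
#' Families: `"0d"` (composition only), `"1d"` (electrotopological-state
#' columns only), `"0d1d"` (both sequence families), `"2d"` (pseudo-fold
#' spectral moments) and `"all"` (everything).
#'
#' @param dataset A `labeled_dataset`.
#' @param family One of `"0d"`, `"1d"`, `"0d1d"`, `"2d"`, `"all"`.
#' @param indices Index codes to encode with.
#' @param drop_constant Drop constant columns (disable for prediction so the
#'   column set matches a trained model).
#' @return A `descriptor_matrix`.
#' @export
build_features <- function(dataset, family = c("0d1d", "0d", "1d", "2d", "all"),
                           indices = list_indices(), drop_constant = TRUE) {
  family <- match.arg(family)
  parts <- list()
  if (family %in% c("0d", "1d", "0d1d", "all")) {
    vic <- switch(family, "0d" = "NO", "1d" = "ES", c("NO", "ES"))
    parts$seq <- featurize(dataset,
                           featurize_config(indices = indices, vicinity = vic),
                           drop_constant = drop_constant)
  }
  if (family %in% c("2d", "all")) {
    parts$fold <- featurize_2d(dataset, properties = indices,
                               drop_constant = drop_constant)
  }
  if (length(parts) == 1L) return(parts[[1L]])
  descriptor_matrix(do.call(cbind, lapply(parts, `[[`, "values")),
                    labels = dataset$labels,
                    dropped = unlist(lapply(parts, `[[`, "dropped"),
                                     use.names = FALSE))
}

#' Run the full classification pipeline on a labelled dataset
#'
#' Featurization, three-stage feature selection and repeated stratified
#' cross-validation of the PUK SVM on the winning subset. All randomness
#' (wrapper search, CV splits) derives from `seed`.
#'
#' @param dataset A `labeled_dataset`.
#' @param family Descriptor family, see [build_features()].
#' @param params [svm_params()] for the final model and CV.
#' @param folds,n_runs Cross-validation protocol (default 10 x 10).
#' @param fraction,rho,ga,min_keep,skip_wrapper Passed to
#'   [select_features()]; the wrapper's fitness SVM also uses `params`.
#' @param seed Master seed.
#' @return An `afseq_pipeline` list: `matrix`, `stages`, `subset`, `cv`,
#'   `sizes`.
#' @export
run_pipeline <- function(dataset, family = "0d1d", params = svm_params(),
                         folds = 10L, n_runs = 10L, fraction = 0.15,
                         rho = 0.95, ga = ga_params(), min_keep = 10L,
                         skip_wrapper = FALSE, seed = 1L) {
  dm <- build_features(dataset, family = family)
  stages <- select_features(dm, fraction = fraction, rho = rho, ga = ga,
                            svm = params, seed = seed, min_keep = min_keep,
                            skip_wrapper = skip_wrapper)
  final <- if (skip_wrapper) stages$redundancy else stages$wrapper
  if (!length(final$names)) final <- stages$redundancy
  cv <- crossvalidate(dm_select(dm, final$names), params = params,
                      folds = folds, n_runs = n_runs, base_seed = seed)
  sizes <- c(all = ncol(dm$values), ig = length(stages$ig$names),
             redundancy = length(stages$redundancy$names))
  if (!skip_wrapper) sizes["wrapper"] <- length(stages$wrapper$names)
  structure(list(matrix = dm, stages = stages, subset = final, cv = cv,
                 sizes = sizes, family = family, seed = seed),
            class = "afseq_pipeline")
}

#' @export
print.afseq_pipeline <- function(x, ...) {
  cat(sprintf("afseq pipeline (%s family, seed %d)\n", x$family, x$seed))
  cat("  features per stage: ",
      paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = " -> "),
      "\n", sep = "")
  print(x$cv)
  invisible(x)
}

# ---------------------------------------------------------------------------
# file-level subcommands

write_manifest <- function(dir, command, config, inputs = character(),
                           seed = NULL) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else NULL
  obj <- list(command = command, config = config, input_md5 = hashes,
              seed = seed,
              tool = paste0("afseq ",
                            as.character(utils::packageVersion("afseq"))),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(obj, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(obj)
}

#' Write / read a feature-subset file (one feature name per line)
#'
#' @param subset A `feature_subset` or character vector.
#' @param path File path.
#' @return `write_subset`: `path` invisibly; `read_subset`: character vector.
#' @export
write_subset <- function(subset, path) {
  names <- if (inherits(subset, "feature_subset")) subset$names else subset
  writeLines(names, path)
  invisible(path)
}

#' @rdname write_subset
#' @export
read_subset <- function(path) readLines(path, warn = FALSE)

#' Subcommand: simulate a synthetic labelled dataset to files
#'
#' @param out_fasta,out_labels Output paths.
#' @param n_per_class,length_range,shift,motif Passed to [synthetic_spec()].
#' @param seed Integer seed.
#' @return The generated `labeled_dataset`, invisibly.
#' @export
cmd_simulate <- function(out_fasta, out_labels, n_per_class = 100L,
                         length_range = c(50L, 200L),
                         shift = c(G = 3, H = 3, R = 3), motif = NULL,
                         seed = 1L) {
  spec <- synthetic_spec(n_per_class = n_per_class,
                         length_range = length_range, shift = shift,
                         motif = motif)
  ds <- generate_dataset(spec, seed = seed)
  write_dataset(ds, out_fasta, out_labels)
  write_manifest(dirname(out_fasta), "simulate",
                 config = list(n_per_class = n_per_class,
                               length_range = length_range,
                               shift = as.list(shift), motif = motif),
                 seed = seed)
  invisible(ds)
}

#' Subcommand: featurize a FASTA (+ optional labels) into a matrix file
#'
#' @param fasta Input FASTA path.
#' @param labels Optional label TSV path.
#' @param out Output matrix TSV path.
#' @param family Descriptor family, see [build_features()].
#' @param policy Canonicalization policy.
#' @return The `descriptor_matrix`, invisibly.
#' @export
cmd_featurize <- function(fasta, labels = NULL, out, family = "0d1d",
                          policy = "strict") {
  ds <- load_labeled_dataset(fasta, labels, policy = policy)
  dm <- build_features(ds, family = family)
  write_descriptor_matrix(dm, out)
  write_manifest(dirname(out), "featurize",
                 config = list(family = family, policy = policy),
                 inputs = c(fasta, labels))
  invisible(dm)
}

#' Subcommand: run the selection pipeline on a matrix file
#'
#' Writes one subset file per stage (`subset_ig.txt`, `subset_redundancy.txt`,
#' `subset_wrapper.txt`) plus a per-feature report `selection_report.tsv` into
#' `out_dir`, and logs the shrinking stage sizes.
#'
#' @param matrix Path to a labelled matrix TSV.
#' @param out_dir Output directory (created if needed).
#' @param fraction,rho,skip_wrapper,min_keep Passed to [select_features()].
#' @param C,omega,sigma Wrapper fitness SVM parameters.
#' @param seed Wrapper seed.
#' @return The stage list from [select_features()], invisibly.
#' @export
cmd_select <- function(matrix, out_dir, fraction = 0.15, rho = 0.95,
                       skip_wrapper = FALSE, min_keep = 10L, C = 1,
                       omega = 1, sigma = 1, seed = 1L) {
  dm <- read_descriptor_matrix(matrix)
  if (is.null(dm$labels)) stop("matrix has no label column", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- select_features(dm, fraction = fraction, rho = rho,
                            svm = svm_params(C, omega, sigma),
                            seed = seed, min_keep = min_keep,
                            skip_wrapper = skip_wrapper)
  for (st in names(stages)) {
    write_subset(stages[[st]], file.path(out_dir, paste0("subset_", st, ".txt")))
  }
  write_selection_report(stages, file.path(out_dir, "selection_report.tsv"))
  sizes <- vapply(stages, function(s) length(s$names), 0L)
  message("stage sizes: ", ncol(dm$values), " -> ",
          paste(sprintf("%s=%d", names(sizes), sizes), collapse = " -> "))
  write_manifest(out_dir, "select",
                 config = list(fraction = fraction, rho = rho,
                               skip_wrapper = skip_wrapper, C = C,
                               omega = omega, sigma = sigma),
                 inputs = matrix, seed = seed)
  invisible(stages)
}

#' Subcommand: cross-validate a PUK SVM on a matrix file
#'
#' @param matrix Path to a labelled matrix TSV.
#' @param subset Optional path to a feature-subset file.
#' @param out Optional path for the per-run TSV report.
#' @param C,omega,sigma,standardize SVM parameters.
#' @param folds,runs,seed CV protocol.
#' @return The `cv_report`, invisibly; the `mean +/- sd %` summary is printed.
#' @export
cmd_cv <- function(matrix, subset = NULL, out = NULL, C = 1, omega = 1,
                   sigma = 1, standardize = TRUE, folds = 10L, runs = 10L,
                   seed = 1L) {
  dm <- read_descriptor_matrix(matrix)
  if (is.null(dm$labels)) stop("matrix has no label column", call. = FALSE)
  if (!is.null(subset)) dm <- dm_select(dm, read_subset(subset))
  rep <- crossvalidate(dm, params = svm_params(C, omega, sigma, standardize),
                       folds = folds, n_runs = runs, base_seed = seed)
  print(rep)
  if (!is.null(out)) {
    write_cv_report(rep, out)
    write_manifest(dirname(out), "cv",
                   config = list(C = C, omega = omega, sigma = sigma,
                                 folds = folds, runs = runs),
                   inputs = c(matrix, subset), seed = seed)
  }
  invisible(rep)
}

#' Subcommand: train a model and save its archive
#'
#' The featurization recipe (family, subset) is stored in the archive so
#' [cmd_predict()] can re-apply it to raw sequences.
#'
#' @param fasta,labels Training data paths.
#' @param out Model archive path.
#' @param subset Optional feature-subset file restricting the model.
#' @param family Descriptor family.
#' @param policy Canonicalization policy.
#' @param C,omega,sigma,standardize SVM parameters.
#' @return The `puk_svm`, invisibly.
#' @export
cmd_train <- function(fasta, labels, out, subset = NULL, family = "0d1d",
                      policy = "strict", C = 1, omega = 1, sigma = 1,
                      standardize = TRUE) {
  ds <- load_labeled_dataset(fasta, labels, policy = policy)
  dm <- build_features(ds, family = family)
  if (!is.null(subset)) dm <- dm_select(dm, read_subset(subset))
  model <- puk_svm(dm, params = svm_params(C, omega, sigma, standardize))
  save_model(model, out,
             recipe = list(family = family, policy = policy,
                           features = colnames(dm$values)))
  write_manifest(dirname(out), "train",
                 config = list(family = family, C = C, omega = omega,
                               sigma = sigma),
                 inputs = c(fasta, labels, subset))
  invisible(model)
}

#' Subcommand: predict classes for new sequences
#'
#' Re-applies the model's stored featurization recipe to the input sequences
#' and writes one row per record: id, predicted class (1 = positive),
#' positive-class probability. Records that fail canonicalization under the
#' chosen policy are reported and skipped.
#'
#' @param model Path to a model archive from [cmd_train()] / [save_model()].
#' @param fasta Input FASTA.
#' @param out Output TSV path.
#' @param policy Canonicalization policy (default `skip_unknown` so real
#'   proteome records with ambiguity codes are still scored).
#' @return Data frame of predictions, invisibly.
#' @export
cmd_predict <- function(model, fasta, out, policy = "skip_unknown") {
  mod <- load_model(model)
  recipe <- attr(mod, "recipe")
  if (is.null(recipe)) stop("model archive has no featurization recipe",
                            call. = FALSE)
  seqs <- read_fasta(fasta)
  kept <- character(0)
  for (id in names(seqs)) {
    res <- tryCatch(as.character(canonicalize(seqs[[id]], policy)),
                    error = function(e) {
                      warning("skipping record ", id, ": ",
                              conditionMessage(e), call. = FALSE)
                      NA_character_
                    })
    if (!is.na(res) && !nzchar(res)) {
      warning("skipping record ", id, ": empty after residue removal",
              call. = FALSE)
    }
    if (!is.na(res) && nzchar(res)) kept[id] <- res
  }
  if (!length(kept)) {
    warning("no scorable records in ", fasta, call. = FALSE)
    df <- data.frame(id = character(), class = integer(),
                     probability = numeric())
  } else {
    ds <- labeled_dataset(kept)
    dm <- build_features(ds, family = recipe$family, drop_constant = FALSE)
    dm <- dm_select(dm, mod$feature_names)
    cls <- predict(mod, dm, type = "class")
    prob <- predict(mod, dm, type = "probability")
    df <- data.frame(id = names(kept), class = as.integer(cls),
                     probability = prob, row.names = NULL)
  }
  utils::write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(dirname(out), "predict", config = list(policy = policy),
                 inputs = c(model, fasta))
  invisible(df)
}

# ---------------------------------------------------------------------------
# argv dispatcher (thin shell entry point lives in inst/cli/afseq.R)

.parse_argv <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- args[[i + 1L]]
      i <- i + 2L
    }
  }
  out
}

.num <- function(x, default) if (is.null(x)) default else as.numeric(x)
.int <- function(x, default) if (is.null(x)) default else as.integer(x)
.chr <- function(x, default = NULL) if (is.null(x)) default else x

#' Command-line dispatcher
#'
#' Implements `afseq simulate|featurize|select|cv|train|predict`. Invoked by
#' the installed `afseq.R` script; exposed so the interface is scriptable and
#' testable from R. Exit semantics are encoded in the return value: 0 on
#' success, 2 on validation errors, 1 on internal errors.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code, invisibly.
#' @export
afseq_main <- function(args) {
  usage <- paste(
    "usage: afseq <command> [--flag value ...]",
    "commands:",
    "  simulate  --fasta F --labels L [--n 100] [--seed 1] [--motif M]",
    "  featurize --fasta F [--labels L] --out M [--family 0d1d] [--policy strict]",
    "  select    --matrix M --out DIR [--fraction 0.15] [--rho 0.95]",
    "            [--skip-wrapper] [--C 1] [--omega 1] [--sigma 1] [--seed 1]",
    "  cv        --matrix M [--subset S] [--out R] [--C 1] [--omega 1] [--sigma 1]",
    "            [--folds 10] [--runs 10] [--seed 1]",
    "  train     --fasta F --labels L --out MODEL [--subset S] [--family 0d1d]",
    "            [--C 1] [--omega 1] [--sigma 1]",
    "  predict   --model MODEL --fasta F --out P [--policy skip_unknown]",
    sep = "\n")
  if (!length(args) || args[[1L]] %in% c("-h", "--help", "help")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  cmd <- args[[1L]]
  rc <- tryCatch({
    o <- .parse_argv(args[-1L])
    switch(cmd,
      simulate = cmd_simulate(o$fasta, o$labels,
                              n_per_class = .int(o$n, 100L),
                              motif = .chr(o$motif), seed = .int(o$seed, 1L)),
      featurize = cmd_featurize(o$fasta, .chr(o$labels), out = o$out,
                                family = .chr(o$family, "0d1d"),
                                policy = .chr(o$policy, "strict")),
      select = cmd_select(o$matrix, o$out,
                          fraction = .num(o$fraction, 0.15),
                          rho = .num(o$rho, 0.95),
                          skip_wrapper = isTRUE(o[["skip-wrapper"]]),
                          C = .num(o$C, 1), omega = .num(o$omega, 1),
                          sigma = .num(o$sigma, 1), seed = .int(o$seed, 1L)),
      cv = cmd_cv(o$matrix, subset = .chr(o$subset), out = .chr(o$out),
                  C = .num(o$C, 1), omega = .num(o$omega, 1),
                  sigma = .num(o$sigma, 1), folds = .int(o$folds, 10L),
                  runs = .int(o$runs, 10L), seed = .int(o$seed, 1L)),
      train = cmd_train(o$fasta, o$labels, out = o$out,
                        subset = .chr(o$subset),
                        family = .chr(o$family, "0d1d"),
                        C = .num(o$C, 1), omega = .num(o$omega, 1),
                        sigma = .num(o$sigma, 1)),
      predict = cmd_predict(o$model, o$fasta, out = o$out,
                            policy = .chr(o$policy, "skip_unknown")),
      stop("unknown command: ", cmd, call. = FALSE))
    0L
  }, error = function(e) {
    message("afseq ", cmd, ": ", conditionMessage(e))
    2L
  })
  invisible(rc)
}
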