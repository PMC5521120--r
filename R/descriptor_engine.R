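# 0D/1D descriptor generation: residue encoding, electrotopological-state
# vicinity modification, residue grouping, invariant aggregation.

#' Residue groups used for descriptor generation
#'
#' Thirty groups: the 20 single-residue groups (three-letter codes), nine
#' physicochemical groups and the whole-protein group `PRT`. The
#' physicochemical memberships follow standard partitions: aliphatic
#' hydrophobic `AHR`, aromatic `ARM`, polar `PLR`, positively charged `PCG`,
#' negatively charged `NCG`, charged `CHG`, turn-promoting `TRN`, small `SML`
#' and uncharged-polar `UNC`.
#'
#' @return Named list mapping group code to a character vector of residue
#'   letters.
#' @export
residue_groups <- function() {
  singles <- stats::setNames(as.list(aa_alphabet()), c(
    "ALA", "CYS", "ASP", "GLU", "PHE", "GLY", "HIS", "ILE", "LYS", "LEU",
    "MET", "ASN", "PRO", "GLN", "ARG", "SER", "THR", "VAL", "TRP", "TYR"))
  pcg <- c("K", "R", "H")
  ncg <- c("D", "E")
  plr <- c("S", "T", "N", "Q", "C", "Y")
  phys <- list(
    AHR = c("A", "V", "L", "I", "M"),
    ARM = c("F", "W", "Y", "H"),
    PLR = plr,
    PCG = pcg,
    NCG = ncg,
    CHG = c(pcg, ncg),
    TRN = c("G", "P", "N", "D", "S"),
    SML = c("G", "A", "S", "C", "T"),
    UNC = c(plr, "G")
  )
  c(singles, phys, list(PRT = aa_alphabet()))
}

#' Aggregation operator codes
#'
#' The 17 invariant operators that collapse a group's residue values into one
#' scalar: p-norms `N1`-`N3`; central tendency `AR` (mean), `GM`, `HM`, `MD`;
#' extremes `MX`, `MN`; dispersion/distribution `VA`, `SK`, `KU`, `Q1`, `Q3`,
#' `RG`, `IQ`; and Shannon entropy `SE`.
#'
#' @return Character vector of the 17 operator codes.
#' @export
aggregation_operators <- function() {
  c("N1", "N2", "N3", "AR", "GM", "HM", "MD", "MX", "MN",
    "VA", "SK", "KU", "Q1", "Q3", "RG", "IQ", "SE")
}

# type-7 quantile on an already-sorted vector
.q7 <- function(xs, p) {
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- min(lo + 1L, n)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

#' Apply all 17 aggregation operators to a vector
#'
#' Degenerate inputs are made total: the empty vector maps to 0 under every
#' operator; `GM`/`HM`/`SE` act on absolute values and return 0 when a zero
#' entry (or, for `SE`, an all-zero vector) makes them undefined; `SK`/`KU`
#' of a zero-variance vector are 0.
#'
#' @param x Numeric vector (may be empty).
#' @return Named numeric vector of length 17 (names as
#'   [aggregation_operators()]).
#' @export
aggregate_all <- function(x) {
  ops <- aggregation_operators()
  n <- length(x)
  if (n == 0L) return(stats::setNames(numeric(17L), ops))
  ax <- abs(x)
  s1 <- sum(ax)
  m <- sum(x) / n
  xc <- x - m
  v <- sum(xc * xc) / n              # population variance
  xs <- sort(x)
  q1 <- .q7(xs, 0.25); md <- .q7(xs, 0.5); q3 <- .q7(xs, 0.75)
  gm <- if (any(ax == 0)) 0 else exp(sum(log(ax)) / n)
  hm <- if (any(ax == 0)) 0 else n / sum(1 / ax)
  if (v > 0) {
    sdv <- sqrt(v)
    sk <- sum(xc^3) / n / sdv^3
    ku <- sum(xc^4) / n / sdv^4
  } else {
    sk <- 0; ku <- 0
  }
  se <- if (s1 > 0) {
    p <- ax[ax > 0] / s1
    -sum(p * log2(p))
  } else 0
  stats::setNames(
    c(s1, sqrt(sum(x * x)), sum(ax^3)^(1 / 3), m, gm, hm, md,
      xs[n], xs[1L], v, sk, ku, q1, q3, xs[n] - xs[1L], q3 - q1, se),
    ops)
}

#' Apply one aggregation operator
#'
#' @param x Numeric vector (may be empty).
#' @param op One of [aggregation_operators()].
#' @return Scalar.
#' @export
#' @examples
#' aggregate_op(c(3, 4), "N2") # 5
aggregate_op <- function(x, op) {
  op <- match.arg(op, aggregation_operators())
  unname(aggregate_all(x)[op])
}

#' Encode a sequence with an amino-acid index
#'
#' @param sequence Canonical sequence string.
#' @param index An `aa_index_table` (see [get_index()]) or an index code.
#' @return Numeric vector, one entry per residue.
#' @export
#' @examples
#' encode_residues("III", get_index("HP")) # 4.5 4.5 4.5
encode_residues <- function(sequence, index) {
  if (is.character(index)) index <- get_index(index)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  unname(index$values[chars])
}

# inverse-square sequence-separation weights, zero diagonal; reused across the
# 16 index arrays of one sequence
es_weight_matrix <- function(n) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  w <- 1 / (d + 1)^2
  diag(w) <- 0
  w
}

#' Electrotopological-state vicinity operator
#'
#' Modifies each residue's intrinsic index value `I_i` by a distance-damped sum
#' of its differences with every other residue:
#' `ES_i = I_i + sum_{j != i} (I_i - I_j) / (d_ij + 1)^2`, with `d_ij = |j - i|`
#' the sequence separation. The pairwise terms are antisymmetric, so the total
#' `sum(ES) == sum(I)` is conserved. This is the operator that converts a
#' composition (0D) array into a sequence-order-aware (1D) array.
#'
#' @param values Numeric vector of intrinsic index values (one per residue).
#' @param w Optional precomputed weight matrix from `es_weight_matrix()` (an
#'   internal speed-up when many indices are applied to one sequence).
#' @return Numeric vector of modified values, same length.
#' @export
#' @examples
#' apply_es(c(1, 2, 3))
apply_es <- function(values, w = NULL) {
  n <- length(values)
  if (n <= 1L) return(values)
  if (is.null(w)) w <- es_weight_matrix(n)
  # pairwise-difference form: exact on constant arrays (all terms are 0)
  diffs <- values - matrix(values, n, n, byrow = TRUE)
  values + rowSums(diffs * w)
}

#' Autocorrelation vicinity operator (not implemented)
#'
#' Placeholder for the restricted-vicinity autocorrelation operator; only the
#' global electrotopological-state operator is implemented.
#'
#' @param values Numeric vector.
#' @param lag Integer lag.
#' @export
apply_ac <- function(values, lag = 1L) {
  stop("autocorrelation vicinity operator is not implemented; use apply_es()",
       call. = FALSE)
}

#' Extract the subvector of an array over a residue group
#'
#' @param values Numeric vector (residue array).
#' @param sequence The sequence the array was computed from.
#' @param group Group code (see [residue_groups()]) or character vector of
#'   residue letters.
#' @return Numeric subvector (possibly empty), order preserved.
#' @export
extract_group <- function(values, sequence, group) {
  if (length(group) == 1L && group %in% names(residue_groups())) {
    group <- residue_groups()[[group]]
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  stopifnot(length(chars) == length(values))
  values[chars %in% group]
}

#' Descriptor matrix container
#'
#' @param values Numeric matrix, instances x features, with rownames (ids) and
#'   colnames (feature names).
#' @param labels Optional logical vector (`TRUE` = positive class) aligned with
#'   rows.
#' @param dropped Character vector of constant feature names removed during
#'   generation.
#' @return An object of class `descriptor_matrix`.
#' @export
descriptor_matrix <- function(values, labels = NULL, dropped = character()) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyDuplicated(colnames(values))) stop("duplicate feature names")
  if (!all(is.finite(values))) stop("non-finite descriptor values")
  if (!is.null(labels)) stopifnot(length(labels) == nrow(values))
  structure(list(values = values, labels = labels, dropped = dropped),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("Descriptor matrix: %d instances x %d features\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$labels)) {
    cat(sprintf("  labels: %d positive / %d negative\n",
                sum(x$labels), sum(!x$labels)))
  }
  if (length(x$dropped)) {
    cat(sprintf("  %d constant feature(s) dropped at generation\n",
                length(x$dropped)))
  }
  invisible(x)
}

#' @export
dim.descriptor_matrix <- function(x) dim(x$values)

#' Restrict a descriptor matrix to a set of features
#'
#' @param dm A `descriptor_matrix`.
#' @param features Character vector of feature names to keep (order kept).
#' @return A `descriptor_matrix` over the requested features.
#' @export
dm_select <- function(dm, features) {
  miss <- setdiff(features, colnames(dm$values))
  if (length(miss)) {
    stop("missing feature column(s): ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  descriptor_matrix(dm$values[, features, drop = FALSE], labels = dm$labels)
}

#' Featurization configuration
#'
#' @param indices Index codes to use (default: all 16 bundled).
#' @param vicinity Subset of `c("NO", "ES")`: `NO` yields composition (0D)
#'   columns, `ES` yields sequence-order (1D) columns.
#' @param groups Group codes (default: all 30, see [residue_groups()]).
#' @param operators Operator codes (default: all 17).
#' @return A `featurize_config` list.
#' @export
featurize_config <- function(indices = list_indices(),
                             vicinity = c("NO", "ES"),
                             groups = names(residue_groups()),
                             operators = aggregation_operators()) {
  stopifnot(length(indices) >= 1L, length(groups) >= 1L,
            length(operators) >= 1L, length(vicinity) >= 1L)
  vicinity <- match.arg(vicinity, c("NO", "ES"), several.ok = TRUE)
  operators <- vapply(operators, match.arg, "",
                      choices = aggregation_operators())
  bad <- setdiff(groups, names(residue_groups()))
  if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "))
  structure(list(indices = indices, vicinity = vicinity, groups = groups,
                 operators = unname(operators)),
            class = "featurize_config")
}

# all 0D/1D descriptor values for one sequence under a config;
# returns a numeric vector in canonical column order
.featurize_one <- function(sequence, config, tables, group_list) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  pos <- lapply(group_list, function(g) which(chars %in% g))
  w <- if ("ES" %in% config$vicinity && n > 1L) es_weight_matrix(n) else NULL
  n_ops <- length(config$operators)
  blocks <- vector("list",
                   length(tables) * length(config$vicinity) * length(pos))
  b <- 0L
  for (tab in tables) {
    base <- unname(tab$values[chars])
    for (mod in config$vicinity) {
      arr <- if (mod == "NO") base else apply_es(base, w)
      for (p in pos) {
        b <- b + 1L
        vals <- aggregate_all(arr[p])
        blocks[[b]] <- if (n_ops == 17L) vals else vals[config$operators]
      }
    }
  }
  unlist(blocks, use.names = FALSE)
}

#' Generate the 0D/1D descriptor matrix for a dataset
#'
#' For every combination of index, vicinity operator (`NO` = none, `ES` =
#' electrotopological state), residue group and aggregation operator, one
#' column named `<Index>_<Mod>_<Group>_<Aggr>` is produced (e.g.
#' `HP_NO_ARM_AR`, the mean hydropathy over aromatic residues). Columns that
#' are constant across all instances carry no information and are dropped
#' (their names are kept in the result's `dropped` field).
#'
#' @param dataset A `labeled_dataset`.
#' @param config A [featurize_config()].
#' @param drop_constant Drop columns constant across instances (default
#'   `TRUE`; prediction paths keep them so column sets match a trained
#'   model).
#' @return A `descriptor_matrix`; row order matches the dataset.
#' @export
featurize <- function(dataset, config = featurize_config(),
                      drop_constant = TRUE) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(config, "featurize_config"))
  tables <- lapply(config$indices, get_index)
  group_list <- residue_groups()[config$groups]
  feat_names <- as.vector(vapply(
    config$indices,
    function(ix) vapply(
      config$vicinity,
      function(mod) vapply(
        config$groups,
        function(g) paste(ix, mod, g, config$operators, sep = "_"),
        character(length(config$operators))),
      character(length(config$operators) * length(config$groups))),
    character(length(config$operators) * length(config$groups) *
                length(config$vicinity))))
  vals <- vapply(dataset$sequences, .featurize_one,
                 numeric(length(feat_names)),
                 config = config, tables = tables, group_list = group_list)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(feat_names))
  m <- t(vals)
  dimnames(m) <- list(dataset$ids, feat_names)
  if (!drop_constant) {
    return(descriptor_matrix(m, labels = dataset$labels))
  }
  rng <- apply(m, 2L, function(col) {
    r <- range(col)
    r[2L] - r[1L]
  })
  keep <- rng > 1e-12 * pmax(1, apply(abs(m), 2L, max))
  dropped <- feat_names[!keep]
  if (!any(keep)) stop("all descriptor columns are constant", call. = FALSE)
  descriptor_matrix(m[, keep, drop = FALSE], labels = dataset$labels,
                    dropped = dropped)
}

#' Write a descriptor matrix as TSV
#'
#' First column `id`, then (when present) `label` (1 = positive class), then
#' one column per feature.
#'
#' @param dm A `descriptor_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptor_matrix <- function(dm, path) {
  df <- data.frame(id = rownames(dm$values), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(dm$labels)) df$label <- as.integer(dm$labels)
  df <- cbind(df, as.data.frame(dm$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a descriptor matrix written by [write_descriptor_matrix()]
#'
#' @param path Path to the TSV file.
#' @return A `descriptor_matrix`.
#' @export
read_descriptor_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  stopifnot("id" %in% colnames(df))
  labels <- NULL
  feat_cols <- setdiff(colnames(df), c("id", "label"))
  if ("label" %in% colnames(df)) labels <- df$label == 1L
  m <- as.matrix(df[, feat_cols, drop = FALSE])
  rownames(m) <- df$id
  descriptor_matrix(m, labels = labels)
}
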