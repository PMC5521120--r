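#' @importFrom methods as is
NULL

#' The 20 standard amino-acid one-letter codes
#'
#' Alphabet over which all descriptor indices are defined, in the conventional
#' alphabetical order of the one-letter codes.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Canonicalize a raw protein sequence
#'
#' Uppercases a sequence and enforces the 20-letter standard alphabet.
#' Under `policy = "strict"` any other character (ambiguity codes such as
#' X/B/Z/J, the rare residues U/O, gaps, stops) is an error; under
#' `policy = "skip_unknown"` such characters are removed and the number of
#' removals is attached as an attribute.
#'
#' @param sequence Character scalar, the raw sequence.
#' @param policy Either `"strict"` (default) or `"skip_unknown"`.
#' @return Canonical sequence string. Under `skip_unknown`, attribute
#'   `n_removed` gives the number of characters dropped.
#' @export
#' @examples
#' canonicalize("acdw")
#' canonicalize("ACXD", policy = "skip_unknown")
canonicalize <- function(sequence, policy = c("strict", "skip_unknown")) {
  policy <- match.arg(policy)
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  ok <- chars %in% aa_alphabet()
  if (policy == "strict") {
    if (!all(ok)) {
      bad <- which(!ok)[1L]
      stop(sprintf("non-standard residue '%s' at position %d (strict policy)",
                   chars[bad], bad), call. = FALSE)
    }
    return(paste(chars, collapse = ""))
  }
  out <- paste(chars[ok], collapse = "")
  attr(out, "n_removed") <- sum(!ok)
  out
}

#' Read protein sequences from a FASTA file
#'
#' Headers are truncated at the first whitespace to form record ids; multi-line
#' bodies are joined. Duplicate ids are rejected. Sequences are returned raw
#' (not canonicalized); see [canonicalize()].
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are record ids), in file
#'   order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("no records in FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stop("malformed header: empty id", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- as.character(set)
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector (names become headers).
#' @param path Output path.
#' @param width Line width for sequence bodies.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  stopifnot(!is.null(names(sequences)), all(nzchar(names(sequences))))
  set <- Biostrings::BStringSet(unname(unlist(sequences)))
  names(set) <- names(sequences)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read a two-column label table
#'
#' Headerless delimited text with one `id<delim>label` pair per line. Labels
#' must take exactly one or two distinct values; the positive class is
#' identified by `positive` (matched case-insensitively), or, when `positive`
#' is absent from the data, by treating the literals `1`, `enzyme`, `pos`,
#' `positive`, `TRUE` as positive.
#'
#' @param path Path to the label table.
#' @param delim Field delimiter (default tab).
#' @param positive Literal(s) denoting the positive (enzyme) class.
#' @return Named logical vector: `TRUE` = positive class, names are ids.
#' @export
read_labels <- function(path, delim = "\t",
                        positive = c("1", "enzyme", "pos", "positive", "true")) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = delim, header = FALSE,
                           colClasses = "character", strip.white = TRUE,
                           col.names = c("id", "label"))
  if (anyDuplicated(tab$id)) {
    stop("duplicate id(s) in label file: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- unique(tab$label)
  if (length(vals) > 2L) {
    stop("labels must be binary; found values: ",
         paste(vals, collapse = ", "), call. = FALSE)
  }
  lab <- tolower(tab$label) %in% tolower(positive)
  if (!any(lab) && length(vals) == 2L) {
    stop("none of the label values (", paste(vals, collapse = ", "),
         ") matches a positive-class literal", call. = FALSE)
  }
  stats::setNames(lab, tab$id)
}

#' Load a labelled protein dataset
#'
#' Reads sequences and labels, canonicalizes every sequence under the given
#' policy, and matches labels to records by id.
#'
#' @param fasta Path to the FASTA file.
#' @param labels Path to the label table, or `NULL` for prediction-only use.
#' @param policy Canonicalization policy, see [canonicalize()].
#' @param delim,positive Passed to [read_labels()].
#' @return A `labeled_dataset`: list with `ids`, `sequences` (canonical, named
#'   by id), `labels` (logical, `TRUE` = positive/enzyme; `NULL` when no label
#'   file given) and `class_names`.
#' @export
load_labeled_dataset <- function(fasta, labels = NULL,
                                 policy = c("strict", "skip_unknown"),
                                 delim = "\t",
                                 positive = c("1", "enzyme", "pos", "positive", "true")) {
  policy <- match.arg(policy)
  seqs <- read_fasta(fasta)
  can <- vapply(seqs, function(s) as.character(canonicalize(s, policy)), "")
  empty <- !nzchar(can)
  if (any(empty)) {
    stop("sequence(s) empty after canonicalization: ",
         paste(names(can)[empty], collapse = ", "), call. = FALSE)
  }
  lab <- NULL
  if (!is.null(labels)) {
    lab_tab <- read_labels(labels, delim = delim, positive = positive)
    unknown <- setdiff(names(lab_tab), names(can))
    if (length(unknown)) {
      stop("label(s) for unknown id(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    missing <- setdiff(names(can), names(lab_tab))
    if (length(missing)) {
      stop("unlabeled record(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    lab <- unname(lab_tab[names(can)])
  }
  labeled_dataset(can, labels = lab)
}

#' Construct a labelled dataset from in-memory sequences
#'
#' @param sequences Named character vector of canonical sequences.
#' @param labels Optional logical vector (`TRUE` = positive class) aligned with
#'   `sequences`, or `NULL`.
#' @param class_names Length-2 character: names of the negative and positive
#'   class, in that order.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(sequences, labels = NULL,
                            class_names = c("non-enzyme", "enzyme")) {
  stopifnot(is.character(sequences), length(sequences) >= 1L,
            !is.null(names(sequences)), !anyDuplicated(names(sequences)))
  if (!is.null(labels)) {
    stopifnot(is.logical(labels), length(labels) == length(sequences),
              !anyNA(labels))
  }
  structure(
    list(ids = names(sequences), sequences = sequences, labels = labels,
         class_names = class_names),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("Labelled protein dataset: %d sequences\n", length(x$ids)))
  if (!is.null(x$labels)) {
    cat(sprintf("  %s: %d   %s: %d\n",
                x$class_names[2L], sum(x$labels),
                x$class_names[1L], sum(!x$labels)))
  } else {
    cat("  (unlabelled)\n")
  }
  lens <- nchar(x$sequences)
  cat(sprintf("  length range: %d-%d (median %d)\n",
              min(lens), max(lens), as.integer(stats::median(lens))))
  invisible(x)
}

#' @export
length.labeled_dataset <- function(x) length(x$ids)

# Both classes present? (training requires this.)
check_two_classes <- function(labels) {
  if (is.null(labels)) stop("dataset is unlabelled", call. = FALSE)
  if (!any(labels) || all(labels)) {
    stop("training requires at least one instance of each class", call. = FALSE)
  }
  invisible(TRUE)
}
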