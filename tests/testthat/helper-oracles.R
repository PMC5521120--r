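# Independent oracles and small fixture builders shared across test files.
# Each oracle is a direct, unoptimized transcription of the defining formula,
# deliberately separate from the package's implementation paths.

# electrotopological state by the naive O(n^2) double loop
es_naive <- function(values) {
  n <- length(values)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- values[i]
    for (j in seq_len(n)) {
      if (j != i) {
        acc <- acc + (values[i] - values[j]) / (abs(j - i) + 1)^2
      }
    }
    out[i] <- acc
  }
  out
}

# information gain from an explicit contingency table, summing entropies
# term by term
ig_bruteforce <- function(binned, labels) {
  n <- length(labels)
  ent <- function(p) if (p %in% c(0, 1)) 0 else -p * log2(p) - (1 - p) * log2(1 - p)
  hx <- ent(mean(labels))
  hxy <- 0
  for (b in unique(binned)) {
    sel <- binned == b
    hxy <- hxy + sum(sel) / n * ent(mean(labels[sel]))
  }
  hx - hxy
}

# write a temporary FASTA file from a named character vector
tmp_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  path
}

# write a temporary two-column label TSV
tmp_labels <- function(ids, labels) {
  path <- tempfile(fileext = ".tsv")
  writeLines(paste(ids, labels, sep = "\t"), path)
  path
}

# random canonical sequence
random_seq <- function(len) {
  paste(sample(aa_alphabet(), len, replace = TRUE), collapse = "")
}

# tiny labelled dataset with an obvious compositional difference
tiny_dataset <- function(n_per_class = 5, len = 30, seed = 1) {
  set.seed(seed)
  neg <- vapply(seq_len(n_per_class), function(i) random_seq(len), "")
  pos <- vapply(seq_len(n_per_class), function(i) {
    s <- sample(c("G", "H", "R", sample(aa_alphabet(), len - 3, TRUE)))
    paste(s, collapse = "")
  }, "")
  seqs <- c(neg, pos)
  names(seqs) <- sprintf("s%02d", seq_along(seqs))
  labeled_dataset(seqs, labels = rep(c(FALSE, TRUE), each = n_per_class))
}
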