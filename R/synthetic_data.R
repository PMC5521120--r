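# Synthetic labelled two-class sequence sets with controllable compositional
# effect sizes, so every pipeline stage is testable without external data.

#' Background residue frequencies
#'
#' `"uniform"` gives 1/20 per residue (keeps analytic expectations trivial);
#' `"proteome"` gives Swiss-Prot-like background frequencies.
#'
#' @param type `"uniform"` or `"proteome"`.
#' @return Named numeric 20-vector summing to 1.
#' @export
aa_background_frequencies <- function(type = c("uniform", "proteome")) {
  type <- match.arg(type)
  if (type == "uniform") {
    return(stats::setNames(rep(1 / 20, 20), aa_alphabet()))
  }
  f <- c(A = 8.25, C = 1.38, D = 5.45, E = 6.75, F = 3.86, G = 7.07,
         H = 2.27, I = 5.96, K = 5.84, L = 9.66, M = 2.42, N = 4.06,
         P = 4.70, Q = 3.93, R = 5.53, S = 6.56, T = 5.34, V = 6.87,
         W = 1.08, Y = 2.92)
  f <- f[aa_alphabet()]
  f / sum(f)
}

#' Specification of a synthetic two-class sequence set
#'
#' The positive class's residue frequencies are the base frequencies with the
#' `shift` multipliers applied (then renormalized); the default triples
#' glycine, histidine and arginine, emulating a composition signal carried by
#' turn-promoting and catalytically prominent residues. Per sequence, a
#' frequency vector is drawn from a Dirichlet centred on the class
#' frequencies; `dirichlet_concentration` scales the Dirichlet parameters, so
#' larger values give less sequence-to-sequence compositional noise.
#' Optionally a fixed motif is planted in positive sequences, giving an
#' order-dependent signal that composition-only (0D) descriptors cannot see.
#'
#' @param n_per_class Sequences per class.
#' @param length_range Integer `[min, max]` sequence length (uniform draw).
#' @param base_frequencies Named 20-vector (renormalized internally).
#' @param shift Named multipliers applied to the positive class's frequencies.
#' @param dirichlet_concentration Positive scalar.
#' @param motif Optional residue string planted in positive sequences.
#' @param motif_prob Probability a positive sequence receives the motif.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_per_class = 100L, length_range = c(50L, 200L),
                           base_frequencies = aa_background_frequencies(),
                           shift = c(G = 3, H = 3, R = 3),
                           dirichlet_concentration = 100,
                           motif = NULL, motif_prob = 1) {
  stopifnot(n_per_class >= 1L, length(length_range) == 2L,
            length_range[1L] >= 10L,
            length_range[1L] <= length_range[2L],
            dirichlet_concentration > 0,
            setequal(names(base_frequencies), aa_alphabet()),
            all(base_frequencies > 0))
  if (!is.null(shift)) {
    stopifnot(all(names(shift) %in% aa_alphabet()), all(shift > 0))
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 length_range = as.integer(length_range),
                 base_frequencies = base_frequencies[aa_alphabet()] /
                   sum(base_frequencies),
                 shift = shift,
                 dirichlet_concentration = dirichlet_concentration,
                 motif = motif, motif_prob = motif_prob),
            class = "synthetic_spec")
}

# class frequency vectors implied by a spec
.class_frequencies <- function(spec) {
  neg <- spec$base_frequencies
  pos <- neg
  if (!is.null(spec$shift)) {
    pos[names(spec$shift)] <- pos[names(spec$shift)] * spec$shift
    pos <- pos / sum(pos)
  }
  list(neg = neg, pos = pos)
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Generate a synthetic labelled sequence dataset
#'
#' Deterministic given `seed`; negative-class records come first, ids are
#' `neg_###` / `pos_###`.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return A `labeled_dataset`.
#' @export
generate_dataset <- function(spec = synthetic_spec(), seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  fr <- .class_frequencies(spec)
  alphabet <- aa_alphabet()
  make_class <- function(freq, prefix, plant_motif) {
    n <- spec$n_per_class
    seqs <- character(n)
    for (i in seq_len(n)) {
      p <- .rdirichlet1(spec$dirichlet_concentration * freq)
      len <- sample(spec$length_range[1L]:spec$length_range[2L], 1L)
      chars <- sample(alphabet, len, replace = TRUE, prob = p)
      if (plant_motif && !is.null(spec$motif) &&
          stats::runif(1) < spec$motif_prob) {
        mot <- strsplit(spec$motif, "", fixed = TRUE)[[1L]]
        if (length(mot) <= len) {
          at <- sample.int(len - length(mot) + 1L, 1L)
          chars[at:(at + length(mot) - 1L)] <- mot
        }
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    stats::setNames(seqs, sprintf("%s_%03d", prefix, seq_len(n)))
  }
  neg <- make_class(fr$neg, "neg", FALSE)
  pos <- make_class(fr$pos, "pos", TRUE)
  labeled_dataset(c(neg, pos),
                  labels = rep(c(FALSE, TRUE), each = spec$n_per_class))
}

#' Write a labelled dataset as FASTA plus a label TSV
#'
#' @param dataset A `labeled_dataset`.
#' @param fasta,labels Output paths (labels written only when the dataset is
#'   labelled).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, fasta, labels = NULL) {
  write_fasta(dataset$sequences, fasta)
  if (!is.null(labels) && !is.null(dataset$labels)) {
    utils::write.table(
      data.frame(id = dataset$ids, label = as.integer(dataset$labels)),
      labels, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(c(fasta = fasta, labels = labels))
}

#' Two-Gaussian-blob toy descriptor matrix
#'
#' Two 2-feature spherical Gaussian classes (unit standard deviation) whose
#' centres sit `gap` standard deviations apart, bypassing featurization for
#' direct SVM tests.
#'
#' @param n Total instances (even; half per class).
#' @param gap Centre separation in standard deviations.
#' @param seed Integer seed.
#' @return A labelled `descriptor_matrix` with features `F1`, `F2`.
#' @export
make_separable_toy <- function(n = 40L, gap = 10, seed = 1L) {
  stopifnot(n >= 4L, n %% 2L == 0L, gap >= 0)
  set.seed(seed)
  half <- n %/% 2L
  m <- rbind(
    cbind(stats::rnorm(half), stats::rnorm(half)),
    cbind(stats::rnorm(half, mean = gap), stats::rnorm(half)))
  dimnames(m) <- list(sprintf("t%03d", seq_len(n)), c("F1", "F2"))
  descriptor_matrix(m, labels = rep(c(FALSE, TRUE), each = half))
}
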