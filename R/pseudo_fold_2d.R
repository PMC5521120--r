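# Pseudo-fold (2D) descriptors: Nandy lattice embedding of a sequence,
# weighted node/adjacency matrices, spectral-moment series.

#' Default four-class residue partition for the Nandy embedding
#'
#' Maps each residue class to a unit lattice step: aromatic residues step
#' `+x`, nonpolar/aliphatic residues `-x`, charged residues `+y`, polar
#' uncharged residues `-y`. The four classes are disjoint and cover the
#' 20-letter alphabet.
#'
#' @return Named list of four residue-letter vectors (`xplus`, `xminus`,
#'   `yplus`, `yminus`).
#' @export
nandy_partition <- function() {
  list(
    xplus  = c("F", "W", "Y", "H"),
    xminus = c("A", "V", "L", "I", "M", "G", "P", "C"),
    yplus  = c("D", "E", "K", "R"),
    yminus = c("S", "T", "N", "Q")
  )
}

#' Embed a sequence on a 2D lattice (Nandy walk)
#'
#' The walk starts at the origin; each residue advances one unit step in the
#' direction of its partition class. Lattice points visited become graph
#' nodes; revisiting a point merges the residue into the existing node.
#' Consecutive distinct nodes along the walk are connected by an edge.
#'
#' @param sequence Canonical sequence string.
#' @param partition Four disjoint residue classes covering the alphabet, as
#'   returned by [nandy_partition()].
#' @return A `graph2d`: list with `coords` (nodes x 2 integer matrix),
#'   `residues` (per node, integer positions of the residues merged into it;
#'   the origin node may hold none), `edges` (2-column matrix of node index
#'   pairs) and `walk` (node index of each residue).
#' @export
nandy_embed <- function(sequence, partition = nandy_partition()) {
  stopifnot(length(partition) == 4L)
  all_res <- unlist(partition)
  if (anyDuplicated(all_res)) stop("partition classes must be disjoint")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  miss <- setdiff(unique(chars), all_res)
  if (length(miss)) {
    stop("partition does not cover residue(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  steps <- rbind(xplus = c(1L, 0L), xminus = c(-1L, 0L),
                 yplus = c(0L, 1L), yminus = c(0L, -1L))
  cls <- rep(names(partition), lengths(partition))
  names(cls) <- all_res
  dxy <- steps[cls[chars], , drop = FALSE]
  path <- rbind(c(0L, 0L), apply(dxy, 2L, cumsum))
  if (length(chars) == 1L) path <- rbind(c(0L, 0L), dxy)
  key <- paste(path[, 1L], path[, 2L])
  node_of <- match(key, unique(key))      # first-visit order
  n_nodes <- max(node_of)
  coords <- path[!duplicated(node_of), , drop = FALSE]
  residues <- split(seq_along(chars), node_of[-1L])
  res_list <- rep(list(integer()), n_nodes)
  res_list[as.integer(names(residues))] <- residues
  from <- node_of[-length(node_of)]
  to <- node_of[-1L]
  keep <- from != to
  e <- cbind(pmin(from[keep], to[keep]), pmax(from[keep], to[keep]))
  e <- unique(e)
  structure(list(coords = coords, residues = res_list, edges = e,
                 walk = node_of[-1L], sequence = sequence),
            class = "graph2d")
}

#' @export
print.graph2d <- function(x, ...) {
  cat(sprintf("Nandy lattice graph: %d nodes, %d edges (%d residues)\n",
              nrow(x$coords), nrow(x$edges), length(x$walk)))
  invisible(x)
}

#' Build the weighted node/adjacency matrix of a lattice graph
#'
#' Node weight = arithmetic mean of the property values of the residues merged
#' into the node (0 for a residue-less origin node); edge weight = mean of the
#' two incident node weights. The matrix is symmetric; node weights sit on the
#' diagonal unless `diagonal = FALSE`, which gives the pure adjacency form.
#'
#' @param graph A `graph2d` from [nandy_embed()].
#' @param property An `aa_index_table` or index code.
#' @param diagonal Keep node weights on the diagonal (default `TRUE`).
#' @return Symmetric numeric matrix of dimension node count.
#' @export
build_matrix <- function(graph, property, diagonal = TRUE) {
  stopifnot(inherits(graph, "graph2d"))
  if (is.character(property)) property <- get_index(property)
  chars <- strsplit(graph$sequence, "", fixed = TRUE)[[1L]]
  vals <- unname(property$values[chars])
  nw <- vapply(graph$residues,
               function(ix) if (length(ix)) mean(vals[ix]) else 0, 0)
  n <- length(nw)
  m <- matrix(0, n, n)
  if (nrow(graph$edges)) {
    ew <- (nw[graph$edges[, 1L]] + nw[graph$edges[, 2L]]) / 2
    m[graph$edges] <- ew
    m[graph$edges[, c(2L, 1L), drop = FALSE]] <- ew
  }
  if (diagonal) diag(m) <- nw
  m
}

#' Spectral-moment series of a weighted graph matrix
#'
#' `mu_k = trace(M^k)` for `k = 0..kmax`; `mu_0` is the node count and the
#' series equals the power sums of the matrix eigenvalues.
#'
#' @param m Square symmetric numeric matrix.
#' @param kmax Highest order (default 15).
#' @return Named numeric vector `MU0..MU<kmax>`.
#' @export
spectral_moments <- function(m, kmax = 15L) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("matrix must be square")
  mu <- numeric(kmax + 1L)
  mu[1L] <- nrow(m)
  p <- diag(nrow(m))
  for (k in seq_len(kmax)) {
    p <- p %*% m
    mu[k + 1L] <- sum(diag(p))
  }
  stats::setNames(mu, paste0("MU", 0:kmax))
}

signed_log <- function(x) sign(x) * log1p(abs(x))

#' Generate 2D pseudo-fold descriptors for a dataset
#'
#' For every weighting property, the sequence is embedded on the lattice, the
#' weighted node/adjacency matrix is built and the spectral moments
#' `MU0..MU<kmax>` are taken as descriptors, named `MU<k>_2D_<Property>`.
#' High-order raw moments span many orders of magnitude, so the default
#' `transform = "signed_log"` stores `sign(mu) * log(1 + |mu|)`; use
#' `"none"` for raw values.
#'
#' @param dataset A `labeled_dataset`.
#' @param properties Index codes used as weights (default: all bundled).
#' @param partition Residue partition for the walk.
#' @param kmax Highest moment order.
#' @param diagonal Passed to [build_matrix()].
#' @param transform `"signed_log"` (default) or `"none"`.
#' @param drop_constant Drop columns constant across instances.
#' @return A `descriptor_matrix` (constant columns dropped by default).
#' @export
featurize_2d <- function(dataset, properties = list_indices(),
                         partition = nandy_partition(), kmax = 15L,
                         diagonal = TRUE,
                         transform = c("signed_log", "none"),
                         drop_constant = TRUE) {
  stopifnot(inherits(dataset, "labeled_dataset"), length(properties) >= 1L)
  transform <- match.arg(transform)
  tabs <- lapply(properties, get_index)
  feat_names <- as.vector(vapply(
    properties, function(p) paste0("MU", 0:kmax, "_2D_", p),
    character(kmax + 1L)))
  rows <- vapply(dataset$sequences, function(s) {
    g <- nandy_embed(s, partition)
    unlist(lapply(tabs, function(tab) {
      mu <- spectral_moments(build_matrix(g, tab, diagonal = diagonal),
                             kmax = kmax)
      if (transform == "signed_log") signed_log(mu) else mu
    }), use.names = FALSE)
  }, numeric(length(feat_names)))
  m <- t(rows)
  dimnames(m) <- list(dataset$ids, feat_names)
  if (!drop_constant) {
    return(descriptor_matrix(m, labels = dataset$labels))
  }
  rng <- apply(m, 2L, function(col) diff(range(col)))
  keep <- rng > 1e-12 * pmax(1, apply(abs(m), 2L, max))
  if (!any(keep)) stop("all 2D descriptor columns are constant", call. = FALSE)
  descriptor_matrix(m[, keep, drop = FALSE], labels = dataset$labels,
                    dropped = feat_names[!keep])
}
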