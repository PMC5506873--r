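#' Pairwise p-distances from an alignment
#'
#' Proportion of differing residues per pair, with pairwise deletion:
#' columns holding a gap in either sequence of the pair are ignored.
#'
#' @param aln a [protein_alignment].
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance <- function(aln) {
  n <- length(aln$ids)
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- aln$mat[i, ]; b <- aln$mat[j, ]
      ok <- a != "-" & b != "-"
      if (!any(ok)) stop("no shared ungapped columns between ",
                         aln$ids[i], " and ", aln$ids[j])
      D[i, j] <- D[j, i] <- sum(a[ok] != b[ok]) / sum(ok)
    }
  }
  D
}

#' Neighbor-joining fallback tree
#'
#' Builds an unrooted NJ tree from a distance matrix (via [ape::nj()]);
#' used when no externally inferred phylogeny is supplied. Negative branch
#' lengths occasionally produced by NJ are clamped to zero with a warning.
#'
#' @param D symmetric numeric distance matrix with zero diagonal, >= 3 taxa.
#' @return an [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix not symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal must be zero")
  tr <- ape::nj(D)
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to zero")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}
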