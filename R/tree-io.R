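#' Read a phylogenetic tree from a newick file
#'
#' Wraps [ape::read.tree()] with the validation the downstream signal
#' computations rely on: every edge must carry a finite, nonnegative branch
#' length (no silent defaults) and tip labels must be unique. Trees need not
#' be ultrametric.
#'
#' @param path path to a newick file, or use `text=` for a literal string.
#' @param text newick string (alternative to `path`).
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop("file not found: ", path)
    tr <- ape::read.tree(path)
  } else {
    tr <- ape::read.tree(text = text)
  }
  if (is.null(tr)) stop("could not parse newick input")
  validate_tree(tr)
  tr
}

validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip label: ", tr$tip.label[duplicated(tr$tip.label)][1L])
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge))
    stop("tree has missing branch lengths; lengths are required on every edge")
  if (any(!is.finite(tr$edge.length)))
    stop("tree has non-finite branch lengths")
  if (any(tr$edge.length < 0))
    stop("tree has negative branch lengths")
  invisible(tr)
}

#' Write a tree to newick
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
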