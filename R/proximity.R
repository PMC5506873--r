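#' Minimum residue-to-cluster distance
#'
#' Smallest Euclidean distance between any heavy atom of a residue and any
#' atom of a cofactor cluster group, in Angstrom.
#'
#' @param res_atoms numeric matrix (n x 3) of residue heavy-atom coordinates.
#' @param cluster_atoms numeric matrix (m x 3) of cluster atom coordinates.
#' @return nonnegative numeric scalar.
#' @export
min_cluster_distance <- function(res_atoms, cluster_atoms) {
  res_atoms <- as.matrix(res_atoms); cluster_atoms <- as.matrix(cluster_atoms)
  if (nrow(res_atoms) == 0L) stop("residue has no atoms")
  if (nrow(cluster_atoms) == 0L) stop("empty cluster group")
  d2 <- outer(rowSums(res_atoms^2), rowSums(cluster_atoms^2), "+") -
    2 * res_atoms %*% t(cluster_atoms)
  sqrt(max(min(d2), 0))
}

#' Select differing residues near the FeS clusters
#'
#' For every column of a focal-pair conservation profile (i.e. every
#' position where the two enzymes differ), computes the minimum distance
#' from the corresponding reference-structure residue (and, optionally, the
#' model-structure residue) to each cofactor cluster group, and flags the
#' residues whose smallest cluster distance is within `cutoff`. This is the
#' filter that nominates second-coordination-sphere candidates.
#'
#' @param profile a `conservation_profile` data frame.
#' @param reference a [structure_model] with non-empty `cluster_groups`.
#' @param site_map data frame mapping profile columns to structure residues:
#'   columns `column`, `ref_chain`, `ref_resno` and optionally `model_chain`,
#'   `model_resno`. Profile columns absent from the map are skipped with a
#'   warning. See [map_profile_residues()].
#' @param model optional [structure_model] of the second enzyme, already
#'   superposed onto the reference frame.
#' @param cutoff distance threshold in Angstrom (default 5).
#' @param use which structure the cutoff tests: `"either"` (union, default),
#'   `"ref"`, or `"model"`.
#' @param region_map optional named character vector collapsing cluster
#'   labels into region names (e.g. mapping the 2Fe subsite and its cubane
#'   to one "H-cluster" region); unmapped labels keep their own name.
#' @param keep_all return all mapped profile columns with a `within_cutoff`
#'   flag instead of only those within the cutoff (default `FALSE`).
#' @return data frame of class `candidate_sites`, sorted by reference
#'   residue number: profile columns plus `ref_resno`, `model_resno`,
#'   `dist_<cluster>` columns, `min_dist`, `region`, `within_cutoff`.
#' @export
candidate_sites <- function(profile, reference, site_map, model = NULL,
                            cutoff = 5.0, use = c("either", "ref", "model"),
                            region_map = NULL, keep_all = FALSE) {
  use <- match.arg(use)
  if (length(reference$cluster_groups) == 0L)
    stop("reference structure has no cluster groups")
  if (use %in% c("model", "either") && is.null(model) && use == "model")
    stop("use = 'model' requires a model structure")
  labels <- names(reference$cluster_groups)
  cl_ref <- lapply(labels, function(l) cluster_coords(reference, l))
  cl_model <- if (!is.null(model)) {
    if (!setequal(names(model$cluster_groups), labels) &&
        length(model$cluster_groups))
      warning("model cluster groups differ from reference; using reference labels present in model")
    lapply(labels, function(l)
      if (l %in% names(model$cluster_groups)) cluster_coords(model, l) else NULL)
  }
  rows <- list()
  for (k in seq_len(nrow(profile))) {
    col <- profile$column[k]
    mrow <- site_map[site_map$column == col, , drop = FALSE]
    if (nrow(mrow) == 0L) {
      warning("profile column ", col, " has no structure mapping; skipped")
      next
    }
    mrow <- mrow[1L, ]
    ratoms <- residue_atoms(reference, mrow$ref_chain, mrow$ref_resno)
    if (is.null(ratoms)) {
      warning("reference residue ", mrow$ref_resno, " not in structure; column ",
              col, " skipped")
      next
    }
    dref <- vapply(cl_ref, function(cc) min_cluster_distance(ratoms, cc),
                   numeric(1))
    dmod <- rep(NA_real_, length(labels))
    if (!is.null(model) && !is.null(mrow$model_resno) &&
        !is.na(mrow$model_resno)) {
      matoms <- residue_atoms(model, mrow$model_chain, mrow$model_resno)
      if (!is.null(matoms))
        dmod <- vapply(seq_along(labels), function(i)
          if (is.null(cl_model[[i]])) NA_real_
          else min_cluster_distance(matoms, cl_model[[i]]), numeric(1))
    }
    dd <- switch(use,
                 ref = dref,
                 model = dmod,
                 either = pmin(dref, dmod, na.rm = TRUE))
    region_label <- labels[which.min(dd)]
    if (!is.null(region_map) && region_label %in% names(region_map))
      region_label <- unname(region_map[region_label])
    row <- data.frame(column = col,
                      res_a = profile$res_a[k], res_b = profile$res_b[k],
                      ref_resno = mrow$ref_resno,
                      model_resno = if ("model_resno" %in% names(mrow))
                        mrow$model_resno else NA_integer_,
                      stringsAsFactors = FALSE)
    for (i in seq_along(labels)) row[[paste0("dist_", labels[i])]] <- dd[i]
    row$min_dist <- min(dd, na.rm = TRUE)
    row$region <- region_label
    row$within_cutoff <- row$min_dist <= cutoff
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L)
    stop("no profile column could be mapped onto the structure")
  out <- do.call(rbind, rows)
  out <- out[order(out$ref_resno), , drop = FALSE]
  if (!keep_all) out <- out[out$within_cutoff, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  class(out) <- c("candidate_sites", "data.frame")
  out
}

#' Map profile columns to structure residue numbers via the alignment
#'
#' Uses the alignment column maps of the two focal records to translate
#' profile columns into (1-based) residue numbers, plus a constant offset
#' per record when structure numbering does not start at the first residue
#' of the sequence.
#'
#' @param profile a `conservation_profile`.
#' @param aln the [protein_alignment] the profile came from.
#' @param focal_a,focal_b focal record ids.
#' @param chain_a,chain_b chain ids in the two structures.
#' @param offset_a,offset_b number added to the ungapped residue index to
#'   obtain the structure residue number.
#' @return a `site_map` data frame for [candidate_sites()].
#' @export
map_profile_residues <- function(profile, aln, focal_a, focal_b,
                                 chain_a = "A", chain_b = "A",
                                 offset_a = 0L, offset_b = 0L) {
  ra <- column_to_residue(aln, focal_a, profile$column)
  rb <- column_to_residue(aln, focal_b, profile$column)
  data.frame(column = profile$column,
             ref_chain = chain_a, ref_resno = ra + offset_a,
             model_chain = chain_b, model_resno = rb + offset_b,
             stringsAsFactors = FALSE)
}
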