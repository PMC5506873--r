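#' Locate the conserved (H-cluster) block of an alignment
#'
#' The catalytic domain of an [FeFe]-hydrogenase is bracketed by the L1 and
#' L3 signature motifs. This finds the first L1 match and the last L3 match
#' in the ungapped reference record and returns the closed column range from
#' the column of the L1 start to the column of the last residue of L3.
#'
#' @param aln a [protein_alignment].
#' @param ref_id id of the reference record carrying the motifs.
#' @param l1,l3 anchor motif patterns (wildcard `x` = any residue).
#' @return integer length-2: first and last column of the block.
#' @export
conserved_region <- function(aln, ref_id, l1 = "TSCCPxW",
                             l3 = "ExMxCxxGCxxG") {
  refseq <- ungapped(aln, ref_id)
  h1 <- scan_motifs(refseq, data.frame(name = "L1", pattern = l1))
  h3 <- scan_motifs(refseq, data.frame(name = "L3", pattern = l3))
  if (nrow(h1) == 0L) stop("anchor motif L1 (", l1, ") not found in ", ref_id)
  if (nrow(h3) == 0L) stop("anchor motif L3 (", l3, ") not found in ", ref_id)
  start_res <- min(h1$start)
  end_res <- max(h3$start) + nchar(l3) - 1L
  c(residue_to_column(aln, ref_id, start_res),
    residue_to_column(aln, ref_id, end_res))
}

#' Per-column conservation profile of a focal pair against homologs
#'
#' Keeps only alignment columns where the two focal records differ (columns
#' identical in both are removed) and, for each kept column, reports the
#' focal residues and the percentage of homologs (all records except the
#' two focal ones) carrying the focal-A residue, the focal-B residue, or
#' anything else. Homolog gaps count as "other". The three percentages sum
#' to 100 per column.
#'
#' @param aln a [protein_alignment] containing the focal pair and at least
#'   one homolog.
#' @param focal_a,focal_b record ids of the focal pair.
#' @param columns optional integer vector restricting the profile to a
#'   column subset (e.g. the conserved region from [conserved_region()]).
#' @return data frame of class `conservation_profile` with columns `column`,
#'   `res_a`, `res_b`, `pct_a`, `pct_b`, `pct_other`; attributes `focal_a`,
#'   `focal_b`, `n_homologs`.
#' @export
conservation_profile <- function(aln, focal_a, focal_b, columns = NULL) {
  for (id in c(focal_a, focal_b))
    if (!id %in% aln$ids) stop("focal id not in alignment: ", id)
  hom <- setdiff(aln$ids, c(focal_a, focal_b))
  if (length(hom) < 1L) stop("need at least one homolog besides the focal pair")
  cols <- if (is.null(columns)) seq_len(aln$n_columns) else as.integer(columns)
  ra <- aln$mat[focal_a, cols]
  rb <- aln$mat[focal_b, cols]
  keep <- ra != rb
  cols <- cols[keep]; ra <- ra[keep]; rb <- rb[keep]
  H <- aln$mat[hom, cols, drop = FALSE]
  n <- length(hom)
  pct_a <- pct_b <- numeric(length(cols))
  for (k in seq_along(cols)) {
    # gaps never count toward a focal residue class
    pct_a[k] <- if (ra[k] == "-") 0 else 100 * sum(H[, k] == ra[k]) / n
    pct_b[k] <- if (rb[k] == "-") 0 else 100 * sum(H[, k] == rb[k]) / n
  }
  out <- data.frame(column = cols, res_a = ra, res_b = rb, pct_a = pct_a,
                    pct_b = pct_b, pct_other = 100 - pct_a - pct_b,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "focal_a") <- focal_a
  attr(out, "focal_b") <- focal_b
  attr(out, "n_homologs") <- n
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Write / read a conservation profile as TSV
#' @param profile a `conservation_profile` data frame.
#' @param path file path.
#' @export
write_profile <- function(profile, path) {
  write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("column", "res_a", "res_b", "pct_a", "pct_b", "pct_other")
  if (!all(need %in% names(d))) stop("not a conservation profile TSV")
  class(d) <- c("conservation_profile", "data.frame")
  d
}
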