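#' Accessory-cluster cysteine ligand inventory
#'
#' Each accessory FeS cluster of the reference enzyme (FS2, a [2Fe-2S]
#' cluster, and the [4Fe-4S] cubanes FS4A/FS4B/FS4C) is ligated by a known
#' set of cysteines. Given a pairwise alignment of a query to the reference,
#' this counts, per cluster, how many of those ligand positions carry a
#' cysteine in the query. A position aligned to a gap contributes 0.
#'
#' @param aln a [protein_alignment] containing both sequences (e.g. built
#'   from [global_align()] via [as_alignment()]).
#' @param query_id,ref_id record ids of the query and reference.
#' @param ref_positions named list: cluster label -> integer vector of
#'   1-based ungapped residue indices of ligand cysteines in the reference.
#'   A non-cysteine at any such reference position is an error (corrupt
#'   annotation).
#' @return named integer vector of per-cluster cysteine counts.
#' @export
ligand_inventory <- function(aln, query_id, ref_id, ref_positions) {
  refseq <- strsplit(ungapped(aln, ref_id), "")[[1L]]
  out <- integer(length(ref_positions))
  names(out) <- names(ref_positions)
  for (cl in names(ref_positions)) {
    pos <- ref_positions[[cl]]
    if (any(pos < 1L | pos > length(refseq)))
      stop("ligand position out of range for cluster ", cl)
    if (any(refseq[pos] != "C"))
      stop("annotation error: reference residue at position ",
           pos[refseq[pos] != "C"][1L], " (cluster ", cl, ") is not cysteine")
    cols <- residue_to_column(aln, ref_id, pos)
    out[cl] <- sum(aln$mat[query_id, cols] == "C")
  }
  out
}

#' Read a cluster-ligand annotation table (TSV: cluster, position)
#' @param path path to a tab-separated annotation table.
#' @return named list of integer vectors, one per cluster.
#' @export
read_ligand_annotation <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cluster", "position") %in% names(d)))
    stop("annotation table needs columns 'cluster' and 'position'")
  lapply(split(as.integer(d$position), d$cluster), sort)
}

#' Classify a hydrogenase sequence
#'
#' Applies the motif rules: a sequence is typed [FeFe] when the H-cluster
#' motifs L1, L2 and L3 are all present in that order; [NiFe] when a CxxC
#' pair occurs within `terminus_window` residues of both termini. Among
#' [FeFe] sequences, group B2 requires the P1 variant motif (TSCCCPxW);
#' otherwise, when a reference ligand annotation is available, a full
#' accessory-cluster inventory gives A2 and loss of FS2 + FS4C with intact
#' FS4A/FS4B gives A3. Anything else is left unclassified with the reasons
#' recorded. Only the groups relevant to the focal comparison (A2, A3, B2)
#' are assigned; the full published A1-A5/B1-B3 scheme is out of scope.
#'
#' @param seq residue string or single-row [seq_records].
#' @param id sequence id used in the report.
#' @param motifs motif definitions, see [default_motifs()].
#' @param reference optional reference residue string (for the ligand
#'   inventory); when `NULL`, group assignment beyond B2 is skipped.
#' @param ref_positions named list of reference ligand cysteine indices per
#'   cluster (required with `reference`).
#' @param ... alignment parameters passed to [global_align()].
#' @return object of class `hydrogenase_classification`: list with `id`,
#'   `type`, `hits`, `inventory`, `group`, `reasons`.
#' @export
classify_hydrogenase <- function(seq, id = "query", motifs = default_motifs(),
                                 reference = NULL, ref_positions = NULL,
                                 terminus_window = 80L, ...) {
  if (inherits(seq, "seq_records")) {
    stopifnot(nrow(seq) == 1L)
    id <- seq$id
    seq <- seq$seq
  }
  hits <- scan_motifs(seq, motifs)
  reasons <- character()
  # the B2 variant of the P1 motif (extra Cys) stands in for L1: a sequence
  # carrying TSCCCPxW has the L1 cysteines even though strict L1 won't match
  h1 <- hits$start[hits$motif %in% c("L1", "P1B")]
  h2 <- hits$start[hits$motif == "L2"]
  h3 <- hits$start[hits$motif == "L3"]
  m1 <- if (length(h1)) min(h1) else Inf
  m2 <- min(h2[h2 > m1], Inf)
  fefe <- is.finite(m1) && is.finite(m2) && any(h3 > m2)
  type <- "none"
  if (fefe) {
    type <- "[FeFe]"
  } else {
    n <- nchar(seq)
    cx <- hits$start[hits$motif == "NIFE_CXXC"]
    near_n <- any(cx <= terminus_window)
    near_c <- any(cx + 3L >= n - terminus_window + 1L)
    if (near_n && near_c) type <- "[NiFe]"
    if (length(h1) || length(h2) || length(h3))
      reasons <- c(reasons, "incomplete or out-of-order L1/L2/L3 motif set")
  }
  group <- "unclassified"
  inventory <- NULL
  if (type == "[FeFe]") {
    if (any(hits$motif == "P1B")) {
      group <- "B2"
    } else if (!is.null(reference)) {
      if (is.null(ref_positions))
        stop("ref_positions required when a reference is supplied")
      pa <- global_align(seq, reference, ...)
      aln <- as_alignment(pa, ids = c(id, ".ref"))
      inventory <- ligand_inventory(aln, id, ".ref", ref_positions)
      full <- vapply(names(ref_positions),
                     function(cl) length(ref_positions[[cl]]), integer(1))
      have <- c("FS2", "FS4C", "FS4B", "FS4A") %in% names(ref_positions)
      if (!all(have)) {
        reasons <- c(reasons, "annotation lacks FS2/FS4C/FS4B/FS4A clusters")
      } else if (all(inventory == full)) {
        group <- "A2"
      } else if (inventory["FS2"] == 0L && inventory["FS4C"] == 0L &&
                 inventory["FS4B"] == full["FS4B"] &&
                 inventory["FS4A"] == full["FS4A"]) {
        group <- "A3"
      } else {
        reasons <- c(reasons, "ligand inventory matches neither the full A2-like nor the FS2/FS4C-less A3-like pattern")
      }
    } else {
      reasons <- c(reasons, "no reference annotation: accessory-cluster groups not assessed")
    }
  }
  structure(list(id = id, type = type, hits = hits, inventory = inventory,
                 group = group, reasons = reasons),
            class = "hydrogenase_classification")
}

#' @export
print.hydrogenase_classification <- function(x, ...) {
  cat(sprintf("<hydrogenase_classification> %s: type %s, group %s\n",
              x$id, x$type, x$group))
  if (nrow(x$hits))
    cat("  motifs:", paste(sprintf("%s@%d", x$hits$motif, x$hits$start),
                           collapse = " "), "\n")
  if (!is.null(x$inventory))
    cat("  ligands:", paste(sprintf("%s=%d", names(x$inventory), x$inventory),
                            collapse = " "), "\n")
  if (length(x$reasons)) cat("  note:", paste(x$reasons, collapse = "; "), "\n")
  invisible(x)
}
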