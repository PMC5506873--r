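#' @title Multiple sequence alignments
#' @name protein_alignment
#' @description
#' A `protein_alignment` stores an aligned set of protein sequences as a
#' character matrix (rows = records, columns = alignment columns, gap `"-"`)
#' together with, for each record, a column map: an integer vector whose
#' k-th entry is the alignment column holding the record's k-th (ungapped)
#' residue. Columns and residue indices are 1-based throughout.
NULL

#' Construct a protein alignment from gapped sequence strings
#'
#' @param seqs named character vector of equal-length gapped sequences.
#'   `"."` is normalized to `"-"` on input.
#' @param desc optional descriptions.
#' @return an object of class `protein_alignment` with elements `ids`,
#'   `desc`, `mat` (character matrix), `column_map` (list of integer
#'   vectors), `n_columns`, and `gap_only` (logical flag per column).
#' @export
protein_alignment <- function(seqs, desc = "") {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("aligned sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate id in alignment: ", names(seqs)[duplicated(names(seqs))][1L])
  seqs <- gsub(".", "-", toupper(seqs), fixed = TRUE)
  len <- nchar(seqs)
  if (length(unique(len)) != 1L) {
    off <- names(seqs)[len != len[1L]][1L]
    stop("ragged alignment: record '", off, "' has length ", nchar(seqs[off]),
         " but '", names(seqs)[1L], "' has length ", len[1L])
  }
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(mat) <- names(seqs)
  bad <- !(mat %in% c(AA_LETTERS, "-"))
  if (any(bad)) stop("invalid characters in alignment: ",
                     paste(unique(mat[bad]), collapse = " "))
  cmap <- lapply(seq_len(nrow(mat)), function(i) which(mat[i, ] != "-"))
  names(cmap) <- names(seqs)
  structure(list(ids = names(seqs), desc = rep_len(desc, length(seqs)),
                 mat = mat, column_map = cmap, n_columns = ncol(mat),
                 gap_only = apply(mat == "-", 2L, all)),
            class = "protein_alignment")
}

#' Read an aligned FASTA file
#'
#' All records must have equal (gapped) length; ragged input is rejected
#' naming the offending record.
#'
#' @param path path to an aligned FASTA file.
#' @return a [protein_alignment].
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty alignment file: ", path)
  hdr <- names(ss)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  protein_alignment(setNames(as.character(ss), id), desc)
}

#' Write a protein alignment as aligned FASTA
#' @param aln a [protein_alignment].
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln$mat, 1L, paste, collapse = "")
  hdr <- ifelse(nzchar(aln$desc), paste(aln$ids, aln$desc), aln$ids)
  ss <- Biostrings::BStringSet(setNames(seqs, hdr))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Map between residue indices and alignment columns
#'
#' `residue_to_column()` returns the alignment column holding residue number
#' `res` of record `id`; `column_to_residue()` inverts it (NA at gaps).
#'
#' @param aln a [protein_alignment].
#' @param id record id.
#' @param res,column 1-based residue index / alignment column.
#' @return integer vector.
#' @export
residue_to_column <- function(aln, id, res) {
  cm <- aln$column_map[[id]]
  if (is.null(cm)) stop("record not in alignment: ", id)
  if (any(res < 1L | res > length(cm)))
    stop("residue index out of range for ", id)
  cm[res]
}

#' @rdname residue_to_column
#' @export
column_to_residue <- function(aln, id, column) {
  cm <- aln$column_map[[id]]
  if (is.null(cm)) stop("record not in alignment: ", id)
  out <- match(column, cm)
  out
}

#' Ungapped sequence of one alignment record
#' @param aln a [protein_alignment].
#' @param id record id.
#' @return character scalar without gaps.
#' @export
ungapped <- function(aln, id) {
  row <- aln$mat[id, ]
  paste(row[row != "-"], collapse = "")
}

#' Extract a column range as a new alignment
#'
#' Used to trim a homolog alignment to the catalytic (H-cluster) block;
#' bounds are closed and 1-based.
#'
#' @param aln a [protein_alignment].
#' @param bounds integer length-2, first and last column to keep.
#' @return a [protein_alignment] over the restricted columns.
#' @export
trim_alignment <- function(aln, bounds) {
  stopifnot(length(bounds) == 2L)
  if (bounds[1L] < 1L || bounds[2L] > aln$n_columns || bounds[1L] > bounds[2L])
    stop("bounds out of range: ", bounds[1L], "..", bounds[2L])
  sub <- aln$mat[, bounds[1L]:bounds[2L], drop = FALSE]
  protein_alignment(setNames(apply(sub, 1L, paste, collapse = ""), aln$ids),
                    aln$desc)
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("<protein_alignment> %d record(s) x %d column(s)",
              length(x$ids), x$n_columns))
  if (any(x$gap_only)) cat(sprintf(" [%d gap-only column(s)]", sum(x$gap_only)))
  cat("\n")
  invisible(x)
}
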