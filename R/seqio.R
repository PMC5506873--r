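#' @title Protein sequence records
#' @name seq_records
#' @description
#' Collections of protein sequences are held as a plain data frame with
#' class `"seq_records"` and columns `id`, `desc`, `seq`. Residues are
#' uppercase letters over the 20 standard amino acids plus `X`; ids are
#' unique within a collection.
NULL

AA_LETTERS <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                "P","S","T","W","Y","V","X")

new_seq_records <- function(id, desc, seq) {
  out <- data.frame(id = as.character(id), desc = as.character(desc),
                    seq = as.character(seq), stringsAsFactors = FALSE)
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Build a sequence record collection from character vectors
#'
#' @param seqs named character vector of residue strings; names are the ids.
#'   Lowercase letters are uppercased with a warning.
#' @param desc optional descriptions, recycled.
#' @return a `seq_records` data frame with columns `id`, `desc`, `seq`.
#' @export
seq_records <- function(seqs, desc = "") {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named (non-empty ids)")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence id: ",
         names(seqs)[duplicated(names(seqs))][1L])
  up <- toupper(seqs)
  if (any(up != seqs))
    warning("lowercase residues uppercased in: ",
            paste(names(seqs)[up != seqs], collapse = ", "))
  bad <- vapply(strsplit(up, ""), function(ch) any(!ch %in% AA_LETTERS),
                logical(1))
  if (any(bad))
    stop("invalid residue letters in: ", paste(names(seqs)[bad], collapse = ", "))
  new_seq_records(names(seqs), rep_len(desc, length(seqs)), unname(up))
}

#' Read protein sequences from a FASTA file
#'
#' The id is the first whitespace-delimited token of the header; the rest is
#' kept as the description. Lowercase residues are uppercased with a warning;
#' letters outside the 20 amino acids plus X are an error.
#'
#' @param path path to a FASTA file.
#' @return a [seq_records] data frame.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) {
    warning("empty FASTA file: ", path)
    return(new_seq_records(character(), character(), character()))
  }
  hdr <- names(ss)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (anyDuplicated(id))
    stop("duplicate sequence id in ", path, ": ", id[duplicated(id)][1L])
  recs <- seq_records(setNames(as.character(ss), id), desc)
  recs
}

#' Write sequence records to FASTA
#'
#' @param records a [seq_records] data frame (or anything with `id`, `desc`,
#'   `seq` columns).
#' @param path output path.
#' @param width line-wrap width for residues.
#' @export
write_fasta <- function(records, path, width = 60L) {
  hdr <- ifelse(nzchar(records$desc),
                paste(records$id, records$desc), records$id)
  ss <- Biostrings::BStringSet(setNames(records$seq, hdr))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' @export
print.seq_records <- function(x, ...) {
  cat(sprintf("<seq_records> %d sequence(s)\n", nrow(x)))
  if (nrow(x) > 0) {
    show <- utils::head(x, 6L)
    cat(sprintf("  %-20s %6s  %s\n", show$id, nchar(show$seq),
                substr(show$seq, 1, 30)), sep = "")
    if (nrow(x) > 6L) cat("  ...\n")
  }
  invisible(x)
}

seq_of <- function(records, id) {
  i <- match(id, records$id)
  if (is.na(i)) stop("sequence id not found: ", id)
  records$seq[i]
}
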