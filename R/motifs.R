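#' Signature motif definitions
#'
#' Built-in signature motifs used to recognize hydrogenase sequences.
#' Patterns are strings over amino-acid letters where `x` matches any
#' residue. The three H-cluster motifs (L1, L2, L3) jointly diagnose an
#' [FeFe]-hydrogenase catalytic domain; `P1B` is the L1 variant carrying an
#' extra cysteine that marks the B2 group; `NIFE_CXXC` is the cysteine pair
#' ligating a [NiFe] center near each terminus of the large subunit.
#'
#' @param names optional subset of motif names to return.
#' @return data frame with columns `name`, `pattern`.
#' @export
default_motifs <- function(names = NULL) {
  m <- data.frame(
    name = c("L1", "L2", "L3", "P1B", "NIFE_CXXC"),
    pattern = c("TSCCPxW", "MPCxxKxxE", "ExMxCxxGCxxG", "TSCCCPxW", "CxxC"),
    stringsAsFactors = FALSE
  )
  if (!is.null(names)) {
    i <- match(names, m$name)
    if (anyNA(i)) stop("unknown motif: ", paste(names[is.na(i)], collapse = ", "))
    m <- m[i, , drop = FALSE]
  }
  m
}

#' Read a motif table (TSV with columns name, pattern)
#' @param path path to a tab-separated motif table.
#' @return data frame with columns `name`, `pattern`.
#' @export
read_motifs <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "pattern") %in% names(m)))
    stop("motif table needs columns 'name' and 'pattern'")
  validate_motifs(m)
  m[, c("name", "pattern")]
}

validate_motifs <- function(m) {
  if (any(!nzchar(m$pattern))) stop("empty motif pattern")
  ch <- strsplit(toupper(gsub("x", "", m$pattern)), "")
  bad <- vapply(ch, function(s) any(!s %in% AA_LETTERS), logical(1))
  if (any(bad)) stop("invalid letters in motif pattern: ",
                     paste(m$name[bad], collapse = ", "))
  invisible(m)
}

#' Scan a sequence for signature motifs
#'
#' Exact matching: every non-`x` position of the pattern must equal the
#' sequence residue, up to `max_mismatch` tolerated mismatches. All match
#' positions are reported, including overlapping ones, sorted by start.
#'
#' @param seq residue string (or a single-row [seq_records]).
#' @param motifs data frame of motif definitions, see [default_motifs()].
#' @param max_mismatch mismatches tolerated at non-wildcard positions
#'   (default 0, exact).
#' @return data frame with columns `motif`, `start` (1-based), `match`.
#' @export
scan_motifs <- function(seq, motifs = default_motifs(), max_mismatch = 0L) {
  if (inherits(seq, "seq_records")) {
    stopifnot(nrow(seq) == 1L)
    seq <- seq$seq
  }
  validate_motifs(motifs)
  s <- strsplit(toupper(seq), "")[[1L]]
  n <- length(s)
  hits <- list()
  for (k in seq_len(nrow(motifs))) {
    pat <- strsplit(motifs$pattern[k], "")[[1L]]
    L <- length(pat)
    if (L > n) next
    fixed <- which(pat != "x" & pat != "X")
    mm <- numeric(n - L + 1L)
    for (f in fixed) mm <- mm + (s[f:(f + n - L)] != pat[f])
    starts <- which(mm <= max_mismatch)
    if (length(starts))
      hits[[length(hits) + 1L]] <- data.frame(
        motif = motifs$name[k], start = starts,
        match = vapply(starts, function(i) paste(s[i:(i + L - 1L)],
                                                 collapse = ""), ""),
        stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L)
    return(data.frame(motif = character(), start = integer(),
                      match = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}
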