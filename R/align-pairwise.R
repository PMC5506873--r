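#' Substitution matrix lookup
#'
#' Fetches one of the Biostrings substitution matrices by name, or passes a
#' user matrix through (must be square with identical row/column names).
#'
#' @param matrix matrix name (e.g. "BLOSUM62") or a numeric matrix.
#' @return numeric substitution matrix.
#' @export
substitution_matrix <- function(matrix = "BLOSUM62") {
  if (is.matrix(matrix)) {
    stopifnot(identical(rownames(matrix), colnames(matrix)))
    return(matrix)
  }
  e <- new.env()
  data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch/Gotoh alignment maximizing the summed substitution
#' score minus affine gap costs; a gap of length L costs
#' `gap_open + gap_extend * (L - 1)`. The optimum is exact; ties are broken
#' deterministically (diagonal moves preferred).
#'
#' @param a,b residue strings (non-empty).
#' @param matrix substitution matrix or its Biostrings name; default
#'   BLOSUM62.
#' @param gap_open,gap_extend gap penalties (positive costs).
#' @return object of class `pairwise_alignment`: list with `score`,
#'   `a_aligned`, `b_aligned` (gapped strings), `matrix` (the substitution
#'   matrix used).
#' @export
global_align <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  sub <- substitution_matrix(matrix)
  av <- strsplit(toupper(a), "")[[1L]]
  bv <- strsplit(toupper(b), "")[[1L]]
  ai <- match(av, rownames(sub))
  bi <- match(bv, rownames(sub))
  if (anyNA(ai) || anyNA(bi))
    stop("residue letter not in substitution matrix: ",
         paste(unique(c(av[is.na(ai)], bv[is.na(bi)])), collapse = " "))
  res <- .gotoh_align(ai - 1L, bi - 1L, sub, gap_open, gap_extend)
  ga <- ifelse(res$a_pos == 0L, "-", av[pmax(res$a_pos, 1L)])
  gb <- ifelse(res$b_pos == 0L, "-", bv[pmax(res$b_pos, 1L)])
  structure(list(score = res$score,
                 a_aligned = paste(ga, collapse = ""),
                 b_aligned = paste(gb, collapse = ""),
                 matrix = sub,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "pairwise_alignment")
}

#' Convert a pairwise alignment into a two-record protein_alignment
#' @param pa a `pairwise_alignment` from [global_align()].
#' @param ids length-2 ids for the two records.
#' @return a [protein_alignment].
#' @export
as_alignment <- function(pa, ids = c("a", "b")) {
  stopifnot(inherits(pa, "pairwise_alignment"), length(ids) == 2L)
  protein_alignment(setNames(c(pa$a_aligned, pa$b_aligned), ids))
}

#' Identity and similarity of an aligned pair
#'
#' Percent identity over the full alignment (matches / alignment length,
#' gap columns included in the denominator) and, within an optional
#' conserved-region column range, percent identity and percent similarity.
#' Similarity counts aligned residue pairs with a strictly positive
#' substitution score (identities included; BLOSUM62 diagonal is positive).
#'
#' @param pa a `pairwise_alignment` from [global_align()].
#' @param region optional length-2 column bounds of the conserved region
#'   (closed, 1-based); defaults to the full alignment.
#' @return object of class `pairwise_result`: list with `identity_full`,
#'   `identity_region`, `similarity_region`, `region` (all percentages in
#'   `[0, 100]`).
#' @export
pairwise_result <- function(pa, region = NULL) {
  av <- strsplit(pa$a_aligned, "")[[1L]]
  bv <- strsplit(pa$b_aligned, "")[[1L]]
  L <- length(av)
  if (is.null(region)) region <- c(1L, L)
  if (region[1L] < 1L || region[2L] > L || region[1L] > region[2L])
    stop("region bounds outside alignment")
  idx <- region[1L]:region[2L]
  match_full <- sum(av == bv & av != "-")
  m <- av[idx] == bv[idx] & av[idx] != "-"
  both <- av[idx] != "-" & bv[idx] != "-"
  pos <- both
  pos[both] <- pa$matrix[cbind(av[idx][both], bv[idx][both])] > 0
  pos <- pos | m  # identities always count as similar (X~X scores <= 0)
  structure(list(identity_full = 100 * match_full / L,
                 identity_region = 100 * sum(m) / length(idx),
                 similarity_region = 100 * sum(pos) / length(idx),
                 region = region),
            class = "pairwise_result")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> score %.1f, length %d\n", x$score,
              nchar(x$a_aligned)))
  invisible(x)
}

#' @export
print.pairwise_result <- function(x, ...) {
  cat(sprintf(
    "<pairwise_result> identity %.1f%% (full); %.1f%% identity, %.1f%% similarity over columns %d..%d\n",
    x$identity_full, x$identity_region, x$similarity_region,
    x$region[1L], x$region[2L]))
  invisible(x)
}
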