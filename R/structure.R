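#' @title Structure models
#' @name structure_model
#' @description
#' A `structure_model` holds atomic coordinates read from a PDB-format
#' subset (ATOM/HETATM/TER records, v3.3 fixed-width columns) plus named
#' cluster groups: sets of cofactor atoms (e.g. the H-cluster 2Fe subsite,
#' or accessory [4Fe-4S] cubanes) selected from HETATM records via a
#' user-supplied mapping. Residue numbers follow the source file (1-based).
NULL

#' Read a PDB-subset structure file
#'
#' Only ATOM, HETATM and TER records are honored. Insertion codes are
#' rejected with an error rather than silently dropped. HETATM atoms are
#' assigned to cluster groups through `cluster_map`; HETATM residues not
#' covered by the mapping are ignored with a warning.
#'
#' @param path path to a PDB-format file.
#' @param cluster_map data frame with columns `resname`, `chain`, `resno`,
#'   `cluster` assigning HETATM residues to named cofactor groups. May be
#'   `NULL` if the file has no HETATM records of interest.
#' @return a `structure_model`: list with `atoms` (data frame: record,
#'   serial, name, altloc, resname, chain, resno, x, y, z, element) and
#'   `cluster_groups` (named list of row indices into `atoms`).
#' @export
read_structure <- function(path, cluster_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  keep <- trimws(rec) %in% c("ATOM", "HETATM")
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no ATOM/HETATM records in ", path)
  f <- function(a, b) trimws(substr(lines, a, b))
  icode <- f(27, 27)
  if (any(nzchar(icode)))
    stop("insertion codes are not supported (found '", icode[nzchar(icode)][1L],
         "'); renumber the file first")
  atoms <- data.frame(
    record = f(1, 6),
    serial = as.integer(f(7, 11)),
    name = f(13, 16),
    altloc = f(17, 17),
    resname = f(18, 20),
    chain = substr(lines, 22, 22),
    resno = as.integer(f(23, 26)),
    x = as.numeric(f(31, 38)),
    y = as.numeric(f(39, 46)),
    z = as.numeric(f(47, 54)),
    element = f(77, 78),
    stringsAsFactors = FALSE
  )
  alt <- !(atoms$altloc %in% c("", "A"))
  if (any(alt)) {
    warning(sum(alt), " alternate-location atom(s) dropped")
    atoms <- atoms[!alt, , drop = FALSE]
  }
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in ", path)
  # fall back to first letter of the atom name when the element field is blank
  blank <- !nzchar(atoms$element)
  atoms$element[blank] <- substr(gsub("[0-9]", "", atoms$name[blank]), 1, 1)
  rownames(atoms) <- NULL
  groups <- list()
  het <- which(atoms$record == "HETATM")
  if (length(het)) {
    if (is.null(cluster_map)) {
      warning(length(het), " HETATM atom(s) ignored (no cluster mapping supplied)")
    } else {
      stopifnot(all(c("resname", "chain", "resno", "cluster") %in%
                      names(cluster_map)))
      key <- paste(atoms$resname[het], atoms$chain[het], atoms$resno[het])
      mkey <- paste(cluster_map$resname, cluster_map$chain, cluster_map$resno)
      hit <- match(key, mkey)
      if (any(is.na(hit)))
        warning(sum(is.na(hit)), " HETATM atom(s) not covered by the cluster ",
                "mapping; ignored")
      ok <- !is.na(hit)
      groups <- split(het[ok], cluster_map$cluster[hit[ok]])
    }
  }
  if (length(groups) && any(lengths(groups) == 0L))
    stop("empty cluster group after mapping")
  structure(list(atoms = atoms, cluster_groups = groups),
            class = "structure_model")
}

#' Write a structure model as PDB-subset text
#' @param model a `structure_model`.
#' @param path output path.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  nm <- ifelse(nchar(a$name) >= 4L, substr(a$name, 1, 4),
               sprintf(" %-3s", a$name))
  lines <- sprintf("%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                   a$record, a$serial, nm, a$altloc, a$resname, a$chain,
                   a$resno, a$x, a$y, a$z, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Heavy atoms of one residue
#'
#' @param model a `structure_model`.
#' @param chain chain id.
#' @param resno residue number (per the source file).
#' @return numeric matrix (atoms x 3) of coordinates; hydrogens excluded.
#' @export
residue_atoms <- function(model, chain, resno) {
  a <- model$atoms
  i <- which(a$record == "ATOM" & a$chain == chain & a$resno == resno &
               toupper(a$element) != "H")
  if (length(i) == 0L) return(NULL)
  as.matrix(a[i, c("x", "y", "z")])
}

cluster_coords <- function(model, label) {
  i <- model$cluster_groups[[label]]
  if (is.null(i) || length(i) == 0L) stop("unknown or empty cluster group: ", label)
  as.matrix(model$atoms[i, c("x", "y", "z")])
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, %d chain(s), %d cluster group(s)\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              length(x$cluster_groups)))
  if (length(x$cluster_groups))
    cat("  clusters:", paste(sprintf("%s[%d]", names(x$cluster_groups),
                                     lengths(x$cluster_groups)),
                             collapse = " "), "\n")
  invisible(x)
}
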