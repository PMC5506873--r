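#' @title Seeded synthetic-data generators
#' @name synthetic_data
#' @description
#' Every stage of the pipeline has a generator emitting inputs with known
#' ground truth: Yule trees with Brownian or binary tip traits, homolog
#' alignments with planted signature motifs and exact per-column residue
#' frequencies, toy metalloprotein structures with residues at controlled
#' distances from planted cofactor clusters, and Ct tables with planted
#' expression ratios. All randomness flows from an explicit seed; sub-seeds
#' are derived with [split_seed()].
NULL

#' Derive reproducible sub-seeds from a master seed
#'
#' Seeds the RNG with `seed` and draws `n` integers below 2^31; this is the
#' single documented splitting scheme used by all generators.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`.
#' @export
split_seed <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a Yule (pure-birth) tree
#'
#' @param n_tips number of tips (>= 4).
#' @param birth birth rate (default 1; affects depth scaling only).
#' @param seed RNG seed (required).
#' @return rooted [ape::phylo] tree with tips `t1..tn`.
#' @export
gen_tree <- function(n_tips, birth = 1, seed) {
  if (missing(seed)) stop("seed is required")
  if (n_tips < 4L) stop("need at least 4 tips")
  set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth, death = 0)
  tr$tip.label <- paste0("t", seq_len(n_tips))
  validate_tree(tr)
  tr
}

#' Simulate a Brownian-motion trait on a tree
#'
#' Recurses from the root (value 0), adding independent normal increments
#' with variance `sigma^2 * branch length` along each edge. The tip values
#' therefore have covariance `sigma^2 * phylo_covariance(tree)`. This walk
#' is deliberately independent of the covariance-matrix code it is used to
#' calibrate.
#'
#' @param tree rooted [ape::phylo] tree with branch lengths.
#' @param sigma BM standard deviation per unit branch length (> 0).
#' @param seed RNG seed (required).
#' @return named numeric vector over the tips.
#' @export
gen_bm_trait <- function(tree, sigma = 1, seed) {
  if (missing(seed)) stop("seed is required")
  if (sigma <= 0) stop("sigma must be positive")
  validate_tree(tree)
  set.seed(seed)
  n <- length(tree$tip.label)
  nnode <- tree$Nnode
  val <- numeric(n + nnode)
  # edges in preorder so parents are set before children
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1L]; child <- ord$edge[k, 2L]
    val[child] <- val[par] + rnorm(1L, 0, sigma * sqrt(ord$edge.length[k]))
  }
  setNames(val[seq_len(n)], tree$tip.label)
}

#' Simulate a binary trait on a tree
#'
#' Two mechanisms: `"threshold"` dichotomizes a BM realization at its median
#' (binary traits that retain BM-like signal); `"mk"` runs a symmetric
#' two-state Markov process with transition rate `rate` along the branches
#' (rate-controlled signal).
#'
#' @param tree rooted [ape::phylo] tree.
#' @param model `"threshold"` or `"mk"`.
#' @param rate Mk transition rate (ignored for threshold).
#' @param seed RNG seed (required).
#' @return named 0/1 vector over the tips.
#' @export
gen_binary_trait <- function(tree, model = c("threshold", "mk"), rate = 0.5,
                             seed) {
  if (missing(seed)) stop("seed is required")
  model <- match.arg(model)
  if (model == "threshold") {
    y <- gen_bm_trait(tree, sigma = 1, seed = seed)
    return(setNames(as.numeric(y > stats::median(y)), names(y)))
  }
  set.seed(seed)
  n <- length(tree$tip.label)
  val <- integer(n + tree$Nnode)
  root <- n + 1L
  val[root] <- sample(0:1, 1L)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1L]; child <- ord$edge[k, 2L]
    # flip probability of a 2-state symmetric chain over time t
    pflip <- 0.5 * (1 - exp(-2 * rate * ord$edge.length[k]))
    val[child] <- if (runif(1L) < pflip) 1L - val[par] else val[par]
  }
  setNames(as.numeric(val[seq_len(n)]), tree$tip.label)
}

#' Generate a random synthetic proteome
#'
#' @param n number of sequences.
#' @param length_range min/max sequence length.
#' @param seed RNG seed (required).
#' @return a [seq_records] collection with unique ids `p1..pn`.
#' @export
gen_proteome <- function(n = 50L, length_range = c(120L, 400L), seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  aa <- setdiff(AA_LETTERS, "X")
  lens <- sample(length_range[1L]:length_range[2L], n, replace = TRUE)
  seqs <- vapply(lens, function(L) paste(sample(aa, L, replace = TRUE),
                                         collapse = ""), "")
  seq_records(setNames(seqs, paste0("p", seq_len(n))))
}

#' Generate a homolog alignment with planted truth
#'
#' Builds a gapless background where every homolog equals the focal-A
#' sequence, then plants: (i) the signature motifs at fixed offsets in both
#' focal sequences (and hence in all homologs), (ii) "profiled" columns
#' where focal A and focal B differ and homolog residues follow exact
#' planted counts of the A residue, the B residue and a third residue, and
#' (iii) optional gap columns in chosen records. The truth table records the
#' planted motif offsets and realized per-column percentages; with
#' homolog counts that divide evenly these equal the requested frequencies
#' exactly.
#'
#' @param n_homologs number of homolog records (besides the two focal).
#' @param n_columns alignment length.
#' @param profile_spec data frame: `column`, `res_a`, `res_b`, `p_a`, `p_b`
#'   (per-column focal residues and homolog frequencies; `p_other` is the
#'   complement). Frequencies must lie in `[0,1]` with `p_a + p_b <= 1`.
#' @param motif_offsets named integer vector of 1-based residue offsets at
#'   which to plant motifs in the focal-A background (default plants L1, L2,
#'   L3 in order); patterns come from [default_motifs()]. Wildcard positions
#'   are filled with `"G"`.
#' @param gap_columns optional named list: record id -> columns replaced by
#'   gaps in that record (must avoid motif and profiled columns for focal
#'   records).
#' @param focal_ids ids of the two focal records.
#' @param seed RNG seed (required).
#' @return list with `aln` (a [protein_alignment]) and `truth` (list:
#'   `motifs` data frame of name/start/pattern, `profile` data frame with
#'   realized `pct_a`, `pct_b`, `pct_other`).
#' @export
gen_msa <- function(n_homologs = 30L, n_columns = 400L,
                    profile_spec = NULL,
                    motif_offsets = c(L1 = 20L, L2 = 120L, L3 = 260L),
                    gap_columns = NULL,
                    focal_ids = c("focalA", "focalB"), seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  aa <- setdiff(AA_LETTERS, "X")
  bg <- sample(aa, n_columns, replace = TRUE)
  motif_truth <- NULL
  occupied <- integer(0)
  if (length(motif_offsets)) {
    defs <- default_motifs(names(motif_offsets))
    inst <- gsub("x", "G", defs$pattern)
    for (i in seq_along(motif_offsets)) {
      off <- motif_offsets[i]
      span <- off:(off + nchar(inst[i]) - 1L)
      if (max(span) > n_columns) stop("motif ", defs$name[i], " exceeds length")
      if (any(span %in% occupied)) stop("planted motifs overlap")
      bg[span] <- strsplit(inst[i], "")[[1L]]
      occupied <- c(occupied, span)
    }
    motif_truth <- data.frame(name = defs$name,
                              start = as.integer(motif_offsets),
                              pattern = defs$pattern, stringsAsFactors = FALSE)
  }
  fa <- bg
  fb <- bg
  profile_truth <- NULL
  mat_hom <- matrix(rep(bg, n_homologs), nrow = n_homologs, byrow = TRUE)
  if (!is.null(profile_spec)) {
    ps <- profile_spec
    stopifnot(all(c("column", "res_a", "res_b", "p_a", "p_b") %in% names(ps)))
    if (any(ps$p_a < 0 | ps$p_b < 0 | ps$p_a + ps$p_b > 1 + 1e-12))
      stop("invalid planted frequencies (need p_a, p_b >= 0, p_a + p_b <= 1)")
    if (any(ps$res_a == ps$res_b)) stop("profiled columns must differ")
    if (any(ps$column %in% occupied)) stop("profiled column inside a motif")
    n <- n_homologs
    pct <- matrix(0, nrow(ps), 3L)
    for (k in seq_len(nrow(ps))) {
      ca <- round(ps$p_a[k] * n)
      cb <- round(ps$p_b[k] * n)
      if (ca + cb > n) stop("planted counts exceed homolog number")
      other <- setdiff(aa, c(ps$res_a[k], ps$res_b[k]))[1L]
      states <- sample(c(rep(ps$res_a[k], ca), rep(ps$res_b[k], cb),
                         rep(other, n - ca - cb)))
      mat_hom[, ps$column[k]] <- states
      fa[ps$column[k]] <- ps$res_a[k]
      fb[ps$column[k]] <- ps$res_b[k]
      pct[k, ] <- 100 * c(ca, cb, n - ca - cb) / n
    }
    profile_truth <- data.frame(column = ps$column, res_a = ps$res_a,
                                res_b = ps$res_b, pct_a = pct[, 1L],
                                pct_b = pct[, 2L], pct_other = pct[, 3L],
                                stringsAsFactors = FALSE)
  }
  seqs <- c(setNames(list(fa, fb), focal_ids),
            setNames(split(mat_hom, row(mat_hom)), paste0("h", seq_len(n_homologs))))
  seqs <- vapply(seqs, paste, "", collapse = "")
  if (!is.null(gap_columns)) {
    for (id in names(gap_columns)) {
      cols <- gap_columns[[id]]
      if (id %in% focal_ids &&
          any(cols %in% c(occupied, profile_truth$column)))
        stop("gap columns may not hit motif or profiled columns of a focal record")
      s <- strsplit(seqs[[id]], "")[[1L]]
      s[cols] <- "-"
      seqs[[id]] <- paste(s, collapse = "")
    }
  }
  aln <- protein_alignment(seqs)
  list(aln = aln,
       truth = list(motifs = motif_truth, profile = profile_truth,
                    ungapped_lengths = lengths(aln$column_map)))
}

#' Generate a toy metalloprotein structure with planted distances
#'
#' Builds one 4-atom cofactor cluster per requested label (a small
#' tetrahedron of Fe/S atoms, cluster centers spaced 40 Angstrom apart) and
#' places each requested residue as a single CA atom at an exact planted
#' minimum distance from its assigned cluster, on the ray pointing away
#' from the cluster centroid through the nearest cluster atom (so the
#' planted atom is provably the nearest one).
#'
#' @param residues data frame: `resno`, `resname`, `cluster`, `distance`
#'   (Angstrom, >= 0).
#' @param clusters character vector of cluster labels (default the cofactor
#'   layout of the reference enzyme: 2Fe subsite plus accessory clusters).
#' @param chain chain id for the residues.
#' @param seed RNG seed (required; randomizes placement directions).
#' @return list with `model` (a [structure_model]), `cluster_map` (the
#'   HETATM mapping used by [read_structure()]) and `truth` (the residues
#'   table with the realized minimum distance per cluster).
#' @export
gen_structure <- function(residues,
                          clusters = c("H2Fe", "FS4A", "FS4B", "FS4C", "FS2"),
                          chain = "A", seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(all(c("resno", "resname", "cluster", "distance") %in%
                  names(residues)))
  if (any(residues$distance < 0)) stop("distances must be >= 0")
  if (any(!residues$cluster %in% clusters)) stop("unknown cluster in residues")
  if (anyDuplicated(residues$resno)) stop("duplicate residue numbers")
  set.seed(seed)
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3) * 1.7
  atoms <- list(); cmap <- list()
  serial <- 0L
  for (i in seq_along(clusters)) {
    center <- c(40 * (i - 1L), 0, 0)
    for (j in 1:4) {
      serial <- serial + 1L
      atoms[[length(atoms) + 1L]] <- data.frame(
        record = "HETATM", serial = serial,
        name = if (j <= 2) paste0("FE", j) else paste0("S", j - 2L),
        altloc = "", resname = "SF4", chain = "X", resno = 900L + i,
        x = center[1L] + tet[j, 1L], y = center[2L] + tet[j, 2L],
        z = center[3L] + tet[j, 3L],
        element = if (j <= 2) "FE" else "S", stringsAsFactors = FALSE)
    }
    cmap[[i]] <- data.frame(resname = "SF4", chain = "X", resno = 900L + i,
                            cluster = clusters[i], stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(residues))) {
    i <- match(residues$cluster[k], clusters)
    center <- c(40 * (i - 1L), 0, 0)
    anchor <- center + tet[sample(4L, 1L), ]
    u <- anchor - center
    u <- u / sqrt(sum(u^2))
    pos <- anchor + residues$distance[k] * u
    serial <- serial + 1L
    atoms[[length(atoms) + 1L]] <- data.frame(
      record = "ATOM", serial = serial, name = "CA", altloc = "",
      resname = residues$resname[k], chain = chain,
      resno = as.integer(residues$resno[k]),
      x = pos[1L], y = pos[2L], z = pos[3L], element = "C",
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, atoms)
  groups <- lapply(clusters, function(cl)
    which(atoms$record == "HETATM" &
            atoms$resno == 900L + match(cl, clusters)))
  names(groups) <- clusters
  model <- structure(list(atoms = atoms, cluster_groups = groups),
                     class = "structure_model")
  truth <- residues
  truth$min_dist <- vapply(seq_len(nrow(residues)), function(k)
    min_cluster_distance(residue_atoms(model, chain, residues$resno[k]),
                         cluster_coords(model, residues$cluster[k])),
    numeric(1))
  list(model = model, cluster_map = do.call(rbind, cmap), truth = truth)
}

#' Generate a Ct table with planted expression ratios
#'
#' The reference genes are constructed with zero Ct shift between
#' conditions; each target gene's Ct under `Nminus` is displaced by
#' `-log(ratio)/log(1 + E)` cycles so that the efficiency-corrected ratio
#' recovers the planted value exactly in the noise-free case.
#'
#' @param genes data frame: `gene`, `efficiency`, `true_ratio` (reference
#'   genes have `true_ratio = 1`).
#' @param replicates replicates per (gene, condition).
#' @param noise_sd Gaussian Ct noise standard deviation (cycles).
#' @param base_ct mean Ct under `Nplus`.
#' @param seed RNG seed (required).
#' @return list with `table` (a `ct_table`), `efficiencies` (named vector)
#'   and `truth` (the genes table).
#' @export
gen_ct <- function(genes, replicates = 3L, noise_sd = 0, base_ct = 20,
                   seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(all(c("gene", "efficiency", "true_ratio") %in% names(genes)))
  if (any(genes$efficiency <= 0 | genes$efficiency > 1))
    stop("efficiencies must lie in (0, 1]")
  if (any(genes$true_ratio <= 0)) stop("true ratios must be positive")
  set.seed(seed)
  rows <- list()
  for (k in seq_len(nrow(genes))) {
    shift <- log(genes$true_ratio[k]) / log(1 + genes$efficiency[k])
    for (cond in c("Nplus", "Nminus")) {
      mu <- if (cond == "Nplus") base_ct else base_ct - shift
      rows[[length(rows) + 1L]] <- data.frame(
        gene = genes$gene[k], condition = cond,
        replicate = seq_len(replicates),
        ct = mu + rnorm(replicates, 0, noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  tab <- validate_ct_table(do.call(rbind, rows))
  list(table = tab,
       efficiencies = setNames(genes$efficiency, genes$gene),
       truth = genes)
}

#' Generate a synthetic hydrogenase sequence of a chosen group
#'
#' Random background with the three H-cluster motifs planted in order and
#' four cysteine-ligand positions per accessory cluster in the N-terminal
#' region. Group variants: `"A2"` keeps all ligands; `"A3"` mutates the FS2
#' and FS4C ligand cysteines to alanine; `"B2"` swaps the L1 motif for its
#' extra-cysteine P1 variant. The ligand annotation refers to the A2
#' reference's residue numbering, so classify A3/B2 variants against the A2
#' sequence generated with the same seed.
#'
#' @param group one of "A2", "A3", "B2".
#' @param length total sequence length.
#' @param seed RNG seed (required).
#' @return list with `seq` (residue string) and `ligands` (named list of
#'   cysteine positions per cluster, as in the A2 reference).
#' @export
gen_hydrogenase <- function(group = c("A2", "A3", "B2"), length = 520L,
                            seed) {
  group <- match.arg(group)
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  aa <- setdiff(AA_LETTERS, c("X", "C"))  # background without cysteines
  s <- sample(aa, length, replace = TRUE)
  ligands <- list(FS2 = c(12L, 17L, 22L, 27L), FS4C = c(40L, 45L, 50L, 55L),
                  FS4B = c(70L, 75L, 80L, 85L), FS4A = c(100L, 105L, 110L, 115L))
  for (pos in unlist(ligands)) s[pos] <- "C"
  defs <- default_motifs(c("L1", "L2", "L3"))
  inst <- gsub("x", "G", defs$pattern)
  offs <- c(L1 = 160L, L2 = 280L, L3 = 420L)
  for (i in 1:3) s[offs[i]:(offs[i] + nchar(inst[i]) - 1L)] <-
      strsplit(inst[i], "")[[1L]]
  if (group == "A3")
    for (pos in c(ligands$FS2, ligands$FS4C)) s[pos] <- "A"
  if (group == "B2") {
    p1 <- gsub("x", "G", default_motifs("P1B")$pattern)
    s[offs["L1"]:(offs["L1"] + nchar(p1) - 1L)] <- strsplit(p1, "")[[1L]]
  }
  list(seq = paste(s, collapse = ""), ligands = ligands, motif_offsets = offs)
}
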