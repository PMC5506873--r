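#' Brownian-motion covariance matrix of a tree
#'
#' Under Brownian motion a trait's covariance between two tips is
#' proportional to the length of their shared root-to-MRCA path; the
#' diagonal holds root-to-tip distances. Requires a rooted tree with branch
#' lengths on every edge.
#'
#' @param tree an [ape::phylo] tree (rooted, with branch lengths).
#' @return symmetric positive semi-definite matrix, rows/cols in
#'   `tree$tip.label` order.
#' @export
phylo_covariance <- function(tree) {
  validate_tree(tree)
  # a star tree (single internal node) is a valid rooted shape for BM even
  # though ape flags the basal polytomy as unrooted
  if (!ape::is.rooted(tree) && tree$Nnode > 1L)
    stop("tree must be rooted (root it with an outgroup before computing signal)")
  ape::vcv(tree)
}

#' Blomberg's K phylogenetic signal
#'
#' K compares the observed partitioning of trait variance on a phylogeny to
#' the partitioning expected under Brownian motion. With C the BM covariance
#' matrix, the phylogenetically corrected mean is
#' \deqn{\hat a = (1' C^{-1} 1)^{-1} 1' C^{-1} y,}
#' and K is the ratio of the observed \eqn{MSE_0/MSE} to its BM expectation:
#' \deqn{MSE_0 = (y-\hat a)'(y-\hat a)/(n-1), \quad
#'       MSE = (y-\hat a)' C^{-1} (y-\hat a)/(n-1),}
#' \deqn{K = \frac{MSE_0/MSE}{[\mathrm{tr}(C) - n/(1'C^{-1}1)]/(n-1)}.}
#' K = 1 on a star tree for any trait; values near 1 are consistent with
#' Brownian motion, values well above 1 indicate stronger-than-BM signal,
#' values near 0 a pattern random with respect to the tree. K is invariant
#' to affine transforms of the trait.
#'
#' Linear solves use a Cholesky factorization of C; if C is numerically
#' singular it is ridged by `1e-10 * I` with a warning.
#'
#' @param tree rooted [ape::phylo] tree with branch lengths, >= 4 tips.
#' @param trait named numeric vector; names must match the tip labels.
#' @return K (nonnegative scalar), or `NA` with a warning for a constant
#'   trait (K is undefined there, not zero).
#' @export
blomberg_k <- function(tree, trait) {
  prep <- signal_prep(tree, trait)
  if (is.null(prep)) return(NA_real_)
  signal_stats(prep)$K
}

signal_prep <- function(tree, trait) {
  C <- phylo_covariance(tree)
  n <- nrow(C)
  if (n < 4L) stop("need at least 4 tips")
  if (is.null(names(trait))) stop("trait must be named by tip label")
  if (!setequal(names(trait), rownames(C)))
    stop("trait names do not match tree tips")
  y <- trait[rownames(C)]
  if (anyNA(y)) stop("missing trait values")
  if (sd(y) == 0) {
    warning("constant trait: K undefined")
    return(NULL)
  }
  L <- tryCatch(chol(C), error = function(e) {
    warning("covariance numerically singular; ridging with 1e-10 * I")
    chol(C + diag(1e-10, n))
  })
  ones <- rep(1, n)
  Cinv_1 <- backsolve(L, forwardsolve(t(L), ones))
  denom_1 <- sum(ones * Cinv_1)              # 1' C^-1 1
  expected <- (sum(diag(C)) - n / denom_1) / (n - 1)
  list(y = as.numeric(y), L = L, Cinv_1 = Cinv_1, denom_1 = denom_1,
       expected = expected, n = n)
}

# observed MSE0/MSE ratio (and the pieces) for a trait vector y
signal_stats <- function(prep, y = prep$y) {
  a_hat <- sum(y * prep$Cinv_1) / prep$denom_1
  r <- y - a_hat
  mse0 <- sum(r^2) / (prep$n - 1)
  Cinv_r <- backsolve(prep$L, forwardsolve(t(prep$L), r))
  mse <- sum(r * Cinv_r) / (prep$n - 1)
  list(K = (mse0 / mse) / prep$expected, mse = mse, mse0 = mse0)
}

#' Permutation test for phylogenetic signal
#'
#' Shuffles trait values across tips; the p-value is the fraction of
#' permutations (plus the observed arrangement) whose phylogenetic mean
#' squared error is at most the observed one — low MSE means the trait
#' fits the tree at least as well as observed.
#'
#' @param tree rooted [ape::phylo] tree.
#' @param trait named numeric vector over the tips.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed (required, for reproducibility).
#' @return object of class `signal_result`: list with `K`, `p`, `n_perm`.
#' @export
k_pvalue <- function(tree, trait, n_perm = 999L, seed) {
  if (missing(seed)) stop("seed is required")
  if (n_perm < 99L) stop("n_perm must be >= 99")
  prep <- signal_prep(tree, trait)
  if (is.null(prep))
    return(structure(list(K = NA_real_, p = NA_real_, n_perm = n_perm),
                     class = "signal_result"))
  obs <- signal_stats(prep)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- signal_stats(prep, sample(prep$y))
    if (perm$mse <= obs$mse) hits <- hits + 1L
  }
  structure(list(K = obs$K, p = (1 + hits) / (n_perm + 1), n_perm = n_perm),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("<signal_result> K = %.4f, p = %.4g (%d permutations)\n",
              x$K, x$p, x$n_perm))
  invisible(x)
}

#' Per-column phylogenetic signal for a conservation profile
#'
#' For each profiled column, encodes residue usage as a binary indicator
#' over the homolog tips (1 = the tip carries the chosen focal residue at
#' that column) and computes Blomberg's K with a permutation p-value. Tips
#' absent from the alignment, and tips gapped at a column, are pruned from
#' the tree for that column (logged via message).
#'
#' @param profile a `conservation_profile`.
#' @param aln the [protein_alignment] behind the profile.
#' @param tree rooted [ape::phylo] tree whose tip labels are alignment ids.
#' @param residue which focal residue defines the indicator: `"a"` or `"b"`.
#' @param n_perm,seed permutation settings, see [k_pvalue()].
#' @return the profile with columns `K` and `p` appended (NA where the
#'   indicator is constant or fewer than 4 usable tips remain).
#' @export
profile_signal <- function(profile, aln, tree, residue = c("a", "b"),
                           n_perm = 999L, seed) {
  residue <- match.arg(residue)
  if (missing(seed)) stop("seed is required")
  common <- intersect(tree$tip.label, aln$ids)
  drop <- setdiff(tree$tip.label, common)
  if (length(drop)) {
    message(length(drop), " tree tip(s) absent from the alignment; pruned")
    tree <- ape::drop.tip(tree, drop)
  }
  if (is.null(tree) || length(tree$tip.label) < 4L)
    stop("fewer than 4 tree tips overlap the alignment")
  K <- p <- rep(NA_real_, nrow(profile))
  for (k in seq_len(nrow(profile))) {
    col <- profile$column[k]
    focal <- if (residue == "a") profile$res_a[k] else profile$res_b[k]
    states <- aln$mat[tree$tip.label, col]
    gapped <- states == "-"
    tr <- tree
    if (any(gapped)) {
      tr <- ape::drop.tip(tree, tree$tip.label[gapped])
      if (is.null(tr) || length(tr$tip.label) < 4L) next
      states <- states[!gapped]
    }
    trait <- setNames(as.numeric(states == focal), names(states))
    if (sd(trait) == 0) next
    res <- k_pvalue(tr, trait, n_perm = n_perm, seed = seed + k)
    K[k] <- res$K
    p[k] <- res$p
  }
  profile$K <- K
  profile$p <- p
  profile
}
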