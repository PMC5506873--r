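test_that("phylo_covariance matches path arithmetic and the MRCA oracle", {
  # identity on a unit star tree
  star <- read_newick(text = "(A:1,B:1,C:1,D:1);")
  expect_equal(unname(phylo_covariance(star)), diag(4))
  # shared-path arithmetic on a 3-tip tree
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  C <- phylo_covariance(tr)
  expect_equal(C["A", "B"], 1)
  expect_equal(unname(diag(C)), rep(2, 3))
  # brute-force MRCA oracle on a 16-tip Yule tree
  y <- gen_tree(16L, seed = 6)
  Cy <- phylo_covariance(y)
  expect_equal(Cy, oracle_vcv(y)[rownames(Cy), colnames(Cy)],
               tolerance = 1e-12)
  # unrooted trees are refused
  unr <- ape::unroot(ape::rtree(6))
  expect_error(phylo_covariance(unr), "rooted")
})

test_that("blomberg_k equals the explicit-inverse oracle on all fixture trees", {
  set.seed(14)
  for (tr in fixture_trees()) {
    n <- length(tr$tip.label)
    for (rep in 1:3) {
      y <- setNames(rnorm(n), tr$tip.label)
      expect_equal(blomberg_k(tr, y), oracle_k(tr, y), tolerance = 1e-10)
    }
    yb <- setNames(sample(c(0, 1), n, replace = TRUE), tr$tip.label)
    if (sd(yb) > 0)
      expect_equal(blomberg_k(tr, yb), oracle_k(tr, yb), tolerance = 1e-10)
  }
})

test_that("K is exactly 1 on star trees and affine-invariant", {
  star <- read_newick(text = "(A:1,B:1,C:1,D:1,E:1,F:1);")
  set.seed(8)
  for (rep in 1:5) {
    y <- setNames(rnorm(6), star$tip.label)
    expect_equal(blomberg_k(star, y), 1, tolerance = 1e-12)
  }
  trees <- fixture_trees()
  for (rep in 1:10) {
    tr <- trees[[sample(length(trees), 1L)]]
    y <- setNames(rnorm(length(tr$tip.label)), tr$tip.label)
    k0 <- blomberg_k(tr, y)
    a <- runif(1, 0.1, 5) * sample(c(-1, 1), 1L)
    b <- rnorm(1, 0, 10)
    expect_equal(blomberg_k(tr, a * y + b), k0, tolerance = 1e-8)
  }
  # constant trait: NA with warning, not zero
  tr <- trees[[1L]]
  expect_warning(k <- blomberg_k(tr, setNames(rep(1, 4), tr$tip.label)),
                 "constant")
  expect_true(is.na(k))
})

test_that("K calibrates against Brownian motion and detects shuffled traits", {
  tree <- gen_tree(64L, seed = 42)
  seeds <- split_seed(1001, 200L)
  ks <- vapply(seeds, function(s) blomberg_k(tree, gen_bm_trait(tree, 1, seed = s)),
               numeric(1))
  expect_gt(mean(ks), 0.9)
  expect_lt(mean(ks), 1.1)
  # tip-shuffled traits lose signal: mean K drops below the BM mean
  set.seed(77)
  ks_shuf <- vapply(seeds[1:100], function(s) {
    y <- gen_bm_trait(tree, 1, seed = s)
    blomberg_k(tree, setNames(sample(y), names(y)))
  }, numeric(1))
  expect_lt(mean(ks_shuf), mean(ks))
})

test_that("permutation p-values behave and are reproducible", {
  # non-ultrametric tree: root-to-tip depth varies and carries strong signal
  set.seed(9)
  tree <- ape::rtree(32L)
  depth <- setNames(diag(phylo_covariance(tree)), tree$tip.label)
  r1 <- k_pvalue(tree, depth, n_perm = 199L, seed = 5)
  expect_lte(r1$p, 0.05)
  expect_gte(r1$p, 1 / 200)
  r2 <- k_pvalue(tree, depth, n_perm = 199L, seed = 5)
  expect_identical(r1$p, r2$p)
  expect_error(k_pvalue(tree, depth, n_perm = 50L, seed = 5), ">= 99")
  expect_error(k_pvalue(tree, depth, n_perm = 199L), "seed")
})

test_that("profile_signal appends per-column K and p over homolog tips", {
  spec <- data.frame(column = c(10L, 25L), res_a = c("M", "A"),
                     res_b = c("T", "S"), p_a = c(0.5, 0.5), p_b = c(0.5, 0.25))
  g <- gen_msa(n_homologs = 8L, n_columns = 40L, profile_spec = spec,
               motif_offsets = integer(0), seed = 44)
  tree <- gen_tree(8L, seed = 45)
  tree$tip.label <- paste0("h", 1:8)
  prof <- conservation_profile(g$aln, "focalA", "focalB")
  out <- profile_signal(prof, g$aln, tree, n_perm = 99L, seed = 10)
  expect_true(all(c("K", "p") %in% names(out)))
  expect_true(all(out$K[!is.na(out$K)] >= 0))
  expect_true(all(out$p[!is.na(out$p)] >= 1 / 100))
  # tree tips absent from the alignment are pruned, leaving the same answer
  # as running on the pre-pruned tree
  tree2 <- gen_tree(10L, seed = 46)
  tree2$tip.label <- c(paste0("h", 1:8), "extra1", "extra2")
  pre <- ape::drop.tip(tree2, c("extra1", "extra2"))
  expect_message(out2 <- profile_signal(prof, g$aln, tree2, n_perm = 99L,
                                        seed = 10), "pruned")
  out_pre <- profile_signal(prof, g$aln, pre, n_perm = 99L, seed = 10)
  expect_equal(out2$K, out_pre$K, tolerance = 1e-9)
})

test_that("p_distance and nj_tree recover additive structure", {
  aln <- protein_alignment(c(a = "MKTA-Y", b = "MKTA-Y", c = "MQTA-F"))
  D <- p_distance(aln)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 2 / 5)  # gap column ignored pairwise
  expect_equal(D, t(D))

  true_tree <- read_newick(text = "((A:1,B:2):1,(C:3,D:4):2);")
  Dt <- ape::cophenetic.phylo(true_tree)
  nj <- nj_tree(Dt)
  expect_equal(ape::cophenetic.phylo(nj)[rownames(Dt), colnames(Dt)], Dt,
               tolerance = 1e-10)
  expect_error(nj_tree(Dt[1:2, 1:2]), "at least 3")
  bad <- Dt; bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
})

test_that("BM and binary trait generators are seed-stable with the right moments", {
  tree <- gen_tree(16L, seed = 20)
  y1 <- gen_bm_trait(tree, sigma = 1, seed = 100)
  expect_identical(y1, gen_bm_trait(tree, sigma = 1, seed = 100))
  expect_error(gen_bm_trait(tree, sigma = 0, seed = 1), "positive")
  # Monte-Carlo: empirical tip covariance approaches sigma^2 * C
  C <- phylo_covariance(tree)
  reps <- vapply(split_seed(500, 400L),
                 function(s) gen_bm_trait(tree, 1, seed = s), numeric(16L))
  Cemp <- tcrossprod(reps - rowMeans(reps)) / (ncol(reps) - 1)
  expect_lt(max(abs(Cemp - C)) / max(diag(C)), 0.35)
  expect_gt(stats::cor(Cemp[upper.tri(C)], C[upper.tri(C)]), 0.8)
  # binary generators: 0/1 support, both mechanisms, reproducible
  b1 <- gen_binary_trait(tree, "threshold", seed = 7)
  expect_setequal(unique(b1), c(0, 1))
  b2 <- gen_binary_trait(tree, "mk", rate = 0.5, seed = 7)
  expect_true(all(b2 %in% c(0, 1)))
  expect_identical(b2, gen_binary_trait(tree, "mk", rate = 0.5, seed = 7))
})
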