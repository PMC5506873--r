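random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1-2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y)),
        c(2*(x*y+w*z), 1-2*(x^2+z^2), 2*(y*z-w*x)),
        c(2*(x*z-w*y), 2*(y*z+w*x), 1-2*(x^2+y^2)))
}

test_that("kabsch_superpose recovers identity, translation and rotation", {
  set.seed(4)
  X <- matrix(rnorm(45), ncol = 3)
  fit0 <- kabsch_superpose(X, X)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-8)

  fit1 <- kabsch_superpose(sweep(X, 2, c(5, 0, 0), "+"), X)
  expect_equal(fit1$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit1$translation, c(-5, 0, 0), tolerance = 1e-8)

  R <- random_rotation()
  Xl <- matrix(rnorm(900), ncol = 3)
  noise <- matrix(rnorm(900, 0, 0.05), ncol = 3)
  mobile <- (Xl + noise) %*% R  # noise applied in the mobile frame
  fit2 <- kabsch_superpose(mobile, Xl)
  expect_lt(max(abs(fit2$rotation - t(R))), 0.02)
  # the fitted RMSD cannot exceed that of the generating transform itself
  resid <- sqrt(mean(rowSums((sweep(noise, 2, colMeans(noise)))^2)))
  expect_lte(fit2$rmsd, resid + 1e-10)
  expect_gte(fit2$rmsd, 0.5 * resid)

  expect_error(kabsch_superpose(X[1:2, ], X[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("min_cluster_distance is a plain Euclidean minimum", {
  expect_equal(min_cluster_distance(rbind(c(0, 0, 0)), rbind(c(0, 0, 0))), 0)
  expect_equal(min_cluster_distance(rbind(c(3, 4, 0)), rbind(c(0, 0, 0))), 5)
  g <- gen_structure(data.frame(resno = 1L, resname = "GLY",
                                cluster = "FS4B", distance = 4.2),
                     clusters = "FS4B", seed = 2)
  expect_equal(min_cluster_distance(residue_atoms(g$model, "A", 1L),
                                    cluster_coords_for_test(g$model, "FS4B")),
               4.2, tolerance = 1e-12)
})

test_that("candidate_sites selects exactly the planted within-cutoff set", {
  res <- data.frame(resno = c(10L, 20L, 30L, 40L, 50L, 60L),
                    resname = "ALA",
                    cluster = c("H2Fe", "FS4B", "FS4A", "H2Fe", "FS4B", "FS4A"),
                    distance = c(3.0, 4.99, 5.01, 8.0, 2.5, 12.0))
  g <- gen_structure(res, seed = 19)
  prof <- data.frame(column = 1:6, res_a = "M", res_b = "T",
                     pct_a = 50, pct_b = 30, pct_other = 20)
  class(prof) <- c("conservation_profile", "data.frame")
  smap <- data.frame(column = 1:6, ref_chain = "A", ref_resno = res$resno)
  sites <- candidate_sites(prof, g$model, smap, cutoff = 5.0,
                           region_map = c(H2Fe = "H-cluster"))
  expect_identical(sites$ref_resno, c(10L, 20L, 50L))
  expect_identical(sites$region, c("H-cluster", "FS4B", "FS4B"))
  expect_equal(sites$min_dist, c(3.0, 4.99, 2.5), tolerance = 1e-9)

  # cutoff 0 keeps only residues touching a cluster atom: empty here
  expect_identical(nrow(candidate_sites(prof, g$model, smap, cutoff = 0)), 0L)

  # monotonicity: sites at cutoff 4 are a subset of sites at cutoff 5
  s4 <- candidate_sites(prof, g$model, smap, cutoff = 4.0)
  expect_true(all(s4$ref_resno %in% sites$ref_resno))

  # unmapped profile column -> warning + skip
  expect_warning(candidate_sites(prof, g$model, smap[-2L, ], cutoff = 5),
                 "no structure mapping")
})

test_that("distances are invariant under joint rigid transforms", {
  res <- data.frame(resno = c(1L, 2L), resname = "ALA",
                    cluster = c("H2Fe", "FS4A"), distance = c(4.0, 6.5))
  g <- gen_structure(res, clusters = c("H2Fe", "FS4A"), seed = 3)
  set.seed(12)
  for (r in 1:5) {
    R <- random_rotation()
    shift <- rnorm(3, 0, 20)
    m2 <- g$model
    xyz <- as.matrix(m2$atoms[, c("x", "y", "z")]) %*% R
    m2$atoms[, c("x", "y", "z")] <- sweep(xyz, 2, shift, "+")
    for (k in 1:2) {
      d1 <- min_cluster_distance(residue_atoms(g$model, "A", res$resno[k]),
                                 cluster_coords_for_test(g$model, res$cluster[k]))
      d2 <- min_cluster_distance(residue_atoms(m2, "A", res$resno[k]),
                                 cluster_coords_for_test(m2, res$cluster[k]))
      expect_equal(d1, d2, tolerance = 1e-9)
    }
  }
})

test_that("the model structure participates via the union rule", {
  res_ref <- data.frame(resno = 1L, resname = "ALA", cluster = "H2Fe",
                        distance = 7.0)
  res_mod <- data.frame(resno = 1L, resname = "ALA", cluster = "H2Fe",
                        distance = 3.0)
  gr <- gen_structure(res_ref, clusters = "H2Fe", seed = 41)
  gm <- gen_structure(res_mod, clusters = "H2Fe", seed = 41)
  prof <- data.frame(column = 1L, res_a = "A", res_b = "S",
                     pct_a = 60, pct_b = 30, pct_other = 10)
  class(prof) <- c("conservation_profile", "data.frame")
  smap <- data.frame(column = 1L, ref_chain = "A", ref_resno = 1L,
                     model_chain = "A", model_resno = 1L)
  # reference alone: outside the cutoff
  expect_identical(nrow(candidate_sites(prof, gr$model, smap, cutoff = 5)), 0L)
  # union with the model: within
  both <- candidate_sites(prof, gr$model, smap, model = gm$model, cutoff = 5)
  expect_identical(nrow(both), 1L)
  expect_equal(both$min_dist, 3.0, tolerance = 1e-9)
  # restricted to the reference only
  expect_identical(nrow(candidate_sites(prof, gr$model, smap,
                                        model = gm$model, cutoff = 5,
                                        use = "ref")), 0L)
})
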