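test_that("generators demand seeds and are reproducible from them", {
  expect_error(gen_tree(8L), "seed")
  expect_error(gen_msa(), "seed")
  expect_error(gen_ct(data.frame(gene = "g", efficiency = 0.9,
                                 true_ratio = 1)), "seed")
  t1 <- gen_tree(12L, seed = 2)
  t2 <- gen_tree(12L, seed = 2)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_identical(split_seed(9, 5L), split_seed(9, 5L))
  expect_true(all(split_seed(9, 1000L) < 2^31))
})

test_that("invalid generator specs fail before generation", {
  expect_error(gen_msa(profile_spec = data.frame(
    column = 5L, res_a = "M", res_b = "T", p_a = 0.8, p_b = 0.4), seed = 1),
    "frequencies")
  expect_error(gen_msa(profile_spec = data.frame(
    column = 5L, res_a = "M", res_b = "M", p_a = 0.5, p_b = 0.2), seed = 1),
    "differ")
  expect_error(gen_structure(data.frame(resno = 1L, resname = "ALA",
                                        cluster = "H2Fe", distance = -1),
                             seed = 1), ">= 0")
  expect_error(gen_ct(data.frame(gene = "g", efficiency = 1.4,
                                 true_ratio = 2), seed = 1), "\\(0, 1\\]")
})

test_that("every generated artifact round-trips through its reader", {
  dir <- withr::local_tempdir()
  g <- gen_msa(n_homologs = 12L, n_columns = 150L,
               profile_spec = data.frame(column = 60L, res_a = "M",
                                         res_b = "T", p_a = 0.5, p_b = 0.25),
               motif_offsets = c(L1 = 10L), seed = 10)
  write_alignment(g$aln, file.path(dir, "aln.fasta"))
  expect_identical(read_alignment(file.path(dir, "aln.fasta"))$mat, g$aln$mat)

  tr <- gen_tree(10L, seed = 11)
  write_newick(tr, file.path(dir, "t.nwk"))
  expect_setequal(read_newick(file.path(dir, "t.nwk"))$tip.label,
                  tr$tip.label)

  st <- gen_structure(data.frame(resno = 5L, resname = "MET",
                                 cluster = "H2Fe", distance = 4.0),
                      clusters = c("H2Fe", "FS4B"), seed = 12)
  write_structure(st$model, file.path(dir, "s.pdb"))
  back <- read_structure(file.path(dir, "s.pdb"), st$cluster_map)
  expect_equal(back$atoms$x, st$model$atoms$x, tolerance = 1e-3)
  expect_identical(lengths(back$cluster_groups)[names(st$model$cluster_groups)],
                   lengths(st$model$cluster_groups))
})

test_that("the sigma -> 0 limit of BM traits is constant", {
  tree <- gen_tree(8L, seed = 30)
  y <- gen_bm_trait(tree, sigma = 1e-12, seed = 3)
  expect_lt(diff(range(y)), 1e-9)
})

test_that("the end-to-end synthetic bundle recovers all planted truths", {
  seeds <- split_seed(2024, 4L)
  spec <- data.frame(column = c(40L, 80L, 150L, 220L),
                     res_a = c("M", "A", "I", "V"),
                     res_b = c("T", "S", "T", "L"),
                     p_a = c(0.6, 0.5, 0.4, 0.9),
                     p_b = c(0.3, 0.4, 0.4, 0.1))
  g <- gen_msa(n_homologs = 20L, n_columns = 300L, profile_spec = spec,
               motif_offsets = c(L1 = 10L, L2 = 100L, L3 = 250L),
               seed = seeds[1L])
  # motifs
  hits <- scan_motifs(ungapped(g$aln, "focalA"),
                      default_motifs(c("L1", "L2", "L3")))
  expect_identical(setNames(hits$start, hits$motif),
                   c(L1 = 10L, L2 = 100L, L3 = 250L))
  # conservation
  prof <- conservation_profile(g$aln, "focalA", "focalB")
  expect_equal(prof$pct_a, g$truth$profile$pct_a)
  expect_equal(prof$pct_b, g$truth$profile$pct_b)
  # proximity, with the 4.99 / 5.01 boundary pair
  res <- data.frame(resno = c(40L, 80L, 150L, 220L), resname = "ALA",
                    cluster = c("H2Fe", "FS4B", "FS4A", "FS2"),
                    distance = c(4.99, 5.01, 3.0, 10.0))
  st <- gen_structure(res, seed = seeds[2L])
  smap <- data.frame(column = prof$column, ref_chain = "A",
                     ref_resno = res$resno)
  sites <- candidate_sites(prof, st$model, smap, cutoff = 5.0)
  expect_identical(sites$ref_resno, c(40L, 150L))
  # qPCR
  ct <- gen_ct(data.frame(gene = c("target", "ref"),
                          efficiency = c(0.92, 0.98), true_ratio = c(7.5, 1)),
               noise_sd = 0, seed = seeds[3L])
  expect_equal(relative_ratio(ct$table, "target", "ref",
                              ct$efficiencies)$ratio, 7.5, tolerance = 1e-12)
})

test_that("the command-line interface drives the pipeline end to end", {
  dir <- withr::local_tempdir()
  biaslens_cli(c("simulate", "--out", dir, "--seed", "3"))
  expect_true(file.exists(file.path(dir, "msa.fasta")))
  prof_path <- file.path(dir, "profile.tsv")
  biaslens_cli(c("conserve", "--msa", file.path(dir, "msa.fasta"),
                 "--focal-a", "focalA", "--focal-b", "focalB",
                 "--out", prof_path))
  prof <- read_profile(prof_path)
  truth <- read.delim(file.path(dir, "truth_profile.tsv"))
  expect_equal(prof$pct_a[match(truth$column, prof$column)], truth$pct_a)
  fc <- biaslens_cli(c("qpcr", "--ct", file.path(dir, "ct.tsv"),
                       "--eff", file.path(dir, "eff.tsv"),
                       "--target", "target", "--controls", "ref16S"))
  expect_equal(fc$ratio, 7.5, tolerance = 1e-12)
  cls <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seq_records(c(q = gen_hydrogenase("B2", seed = 1)$seq)), cls)
  rep <- biaslens_cli(c("classify", "--fasta", cls))
  expect_identical(rep$group, "B2")
})
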