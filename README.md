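# biaslens

Comparative sequence, structure and phylogenetic-signal analysis of paired
[FeFe]-hydrogenases.

## The problem

Some organisms encode two closely related [FeFe]-hydrogenases with opposite
*catalytic bias*: one is a fast H₂ producer, the other is tuned toward H₂
oxidation (e.g. recycling the H₂ that nitrogenase releases during nitrogen
fixation). The catalytic H-cluster motifs are conserved in both, so the bias
must come from elsewhere — accessory FeS cluster complements and residues in
the *second coordination sphere* of the cofactors. `biaslens` implements a
pipeline that nominates such residues from a focal enzyme pair, its homologs,
and structures, for people doing metalloenzyme comparative analysis who want
a reproducible, testable version of this workflow:

1. **Classify** hydrogenase sequences by signature motifs
   (L1 `TSCCPxW`, L2 `MPCxxKxxE`, L3 `ExMxCxxGCxxG`; the extra-cysteine P1
   variant marking group B2; `CxxC` pairs near both termini for [NiFe]) and
   by an accessory-cluster cysteine ligand inventory (FS2, FS4C, FS4B,
   FS4A), assigning the A2 / A3 / B2 groups the focal comparison needs.
2. **Profile conservation**: align the focal pair (Needleman–Wunsch/Gotoh,
   affine gaps, BLOSUM62), drop every alignment column where the two focal
   enzymes agree, and score the remaining columns by the percentage of
   homologs carrying the A-type residue, the B-type residue, or anything
   else.
3. **Filter by structure**: superimpose the second enzyme's model onto the
   reference crystal structure (Kabsch least squares) and keep differing
   residues whose minimum heavy-atom distance to any FeS cluster is within
   5 Å.
4. **Quantify phylogenetic signal** per candidate column with Blomberg's K
   on a homolog phylogeny (supplied as newick, or a neighbor-joining
   fallback from p-distances), with permutation p-values:

   K = (MSE₀/MSE)ₒᵦₛ / (MSE₀/MSE)ₑₓₚ, with â = (1ᵀC⁻¹1)⁻¹1ᵀC⁻¹y,
   MSE₀ = (y−â1)ᵀ(y−â1)/(n−1), MSE = (y−â1)ᵀC⁻¹(y−â1)/(n−1),
   (MSE₀/MSE)ₑₓₚ = [tr(C) − n/(1ᵀC⁻¹1)]/(n−1),

   where C is the Brownian-motion covariance of the tree. K ≈ 1 is
   consistent with Brownian motion; K ≫ 1 flags columns under strong
   phylogenetic conservation.
5. **Supporting qPCR**: efficiency-corrected expression ratios
   R = (1+E_t)^ΔCt_t / (1+E_r)^ΔCt_r between nitrogen-replete and
   nitrogen-fixing conditions, normalized to one or more control genes.

Every stage has a seeded synthetic-data generator (`gen_msa()`,
`gen_structure()`, `gen_tree()`, `gen_bm_trait()`, `gen_ct()`,
`gen_hydrogenase()`) that plants known truth, so the whole pipeline is
testable end to end without external downloads.

## Worked example

A fully synthetic run — 20 homologs, 3 planted differing columns, a toy
structure with clusters at known distances:

```r
library(biaslens)
seeds <- split_seed(2024, 4L)

spec <- data.frame(column = c(40L, 80L, 150L),
                   res_a = c("M", "A", "I"), res_b = c("T", "S", "T"),
                   p_a = c(0.6, 0.5, 0.4), p_b = c(0.3, 0.4, 0.4))
g <- gen_msa(n_homologs = 20L, n_columns = 300L, profile_spec = spec,
             motif_offsets = c(L1 = 10L, L2 = 100L, L3 = 250L), seed = seeds[1])

scan_motifs(ungapped(g$aln, "focalA"), default_motifs(c("L1", "L2", "L3")))
#>   motif start        match
#> 1    L1    10      TSCCPGW
#> 2    L2   100    MPCGGKGGE
#> 3    L3   250 EGMGCGGGCGGG

prof <- conservation_profile(g$aln, "focalA", "focalB")
prof
#>   column res_a res_b pct_a pct_b pct_other
#> 1     40     M     T    60    30        10
#> 2     80     A     S    50    40        10
#> 3    150     I     T    40    40        20
```

The three columns are exactly the planted differing sites; `pct_a` is the
percentage of homologs carrying the focal-A residue. Now the structural
filter (planted distances 4.2, 5.6, 3.1 Å):

```r
res <- data.frame(resno = c(40L, 80L, 150L), resname = "ALA",
                  cluster = c("H2Fe", "FS4B", "FS4A"),
                  distance = c(4.2, 5.6, 3.1))
st <- gen_structure(res, seed = seeds[2])
smap <- data.frame(column = prof$column, ref_chain = "A", ref_resno = res$resno)
candidate_sites(prof, st$model, smap, cutoff = 5,
                region_map = c(H2Fe = "H-cluster"))[,
  c("column", "res_a", "res_b", "ref_resno", "min_dist", "region")]
#>   column res_a res_b ref_resno min_dist    region
#> 1     40     M     T        40      4.2 H-cluster
#> 2    150     I     T       150      3.1      FS4A
```

Only the two residues within 5 Å survive, labeled by their nearest cluster.
Phylogenetic signal per column (the homolog residues here were planted
independently of the tree, so K is near 0 — a random pattern):

```r
tree <- gen_tree(20L, seed = seeds[3]); tree$tip.label <- paste0("h", 1:20)
profile_signal(prof, g$aln, tree, n_perm = 199L, seed = 17)[,
  c("column", "pct_a", "pct_b", "K", "p")]
#>   column pct_a pct_b          K    p
#> 1     40    60    30 0.02971061 0.95
#> 2     80    50    40 0.03656089 0.46
#> 3    150    40    40 0.33052016 0.13

ct <- gen_ct(data.frame(gene = c("CpII", "s16"), efficiency = c(0.92, 0.98),
                        true_ratio = c(7.5, 1)), noise_sd = 0.1, seed = seeds[4])
relative_ratio(ct$table, "CpII", "s16", ct$efficiencies)
#> <fold_change> CpII: ratio 6.93 (increase, 6.9-fold) [5.63, 8.53]
```

The planted 7.5-fold induction is recovered as 6.9-fold under 0.1-cycle Ct
noise, with a replicate-noise interval.

## Command line

```sh
Rscript inst/cli/biaslens.R simulate --out demo --seed 3
Rscript inst/cli/biaslens.R conserve --msa demo/msa.fasta \
    --focal-a focalA --focal-b focalB --out demo/profile.tsv
Rscript inst/cli/biaslens.R signal --tree demo/tree.nwk --msa demo/msa.fasta \
    --profile demo/profile.tsv --n-perm 999 --seed 17 --out demo/signal.tsv
Rscript inst/cli/biaslens.R qpcr --ct demo/ct.tsv --eff demo/eff.tsv \
    --target target --controls ref16S
```

Subcommands: `classify`, `conserve`, `sites`, `signal`, `qpcr`, `simulate`.

## Documentation

See the methods vignette (`vignettes/catalytic-bias.Rmd`) for the model,
parameter defaults, what the synthetic generators do and do not emulate,
and the package's design decisions.
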