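---
title: "Locating structural determinants of catalytic bias in paired [FeFe]-hydrogenases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating structural determinants of catalytic bias in paired [FeFe]-hydrogenases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biaslens)
```

## The analysis in one paragraph

Two related [FeFe]-hydrogenases in one organism can run the same reaction in
opposite preferred directions: one evolves H₂ to dispose of excess reducing
equivalents during fermentation, the other oxidizes H₂ to recapture
electrons released during nitrogen fixation. Because both carry the same
conserved H-cluster machinery, the determinants of this catalytic bias are
expected among residues that (i) differ between the two enzymes, (ii) sit
close to the catalytic or accessory FeS clusters, and (iii) are
phylogenetically conserved within each enzyme's lineage. `biaslens`
operationalizes that triage: motif-based classification, focal-pair
conservation profiling over a homolog alignment, a 5 Å structural proximity
filter, and per-column Blomberg's K on a homolog phylogeny, plus
efficiency-corrected qPCR ratios for the accompanying expression story.

## Classification model

A sequence is typed **[FeFe]** when the three H-cluster motifs occur in
order: L1 `TSCCPxW`, L2 `MPCxxKxxE`, L3 `ExMxCxxGCxxG` (`x` = any residue;
matching is exact at non-wildcard positions, with an optional
`max_mismatch` tolerance that defaults to 0 because these are diagnostic
signatures, not statistical profiles). The B-group P1 variant `TSCCCPxW`
carries one extra cysteine inside the L1 region; since a literal L1 match
cannot co-occur with it, a P1B hit satisfies the L1 requirement during
typing. A sequence is typed **[NiFe]** when a `CxxC` pair occurs within 80
residues of both termini; "near each terminus" has no published numeric
definition, so 80 is a documented package constant, chosen to cover the
ligand positions in canonical large-subunit sequences while excluding
mid-sequence pairs.

Group assignment covers only the groups the focal comparison involves:

* **B2** — P1B present;
* **A2** — full cysteine ligand inventory at all four accessory clusters
  (FS2, FS4C, FS4B, FS4A), counted at reference-aligned positions;
* **A3** — FS2 and FS4C inventories empty with FS4A/FS4B full (the
  truncated N-terminus phenotype);
* anything else is `unclassified`, with reasons recorded rather than
  guessed.

The reference ligand positions are a user-editable annotation table (the
shipped `cluster_ligands_synthetic.tsv` matches the package's synthetic
reference generator, and is labeled synthetic for that reason): the true
positions are structure-specific and should come from the user's reference
annotation, not from hard-coded constants.

## Pairwise alignment and the conserved region

The focal pair is aligned by global Needleman–Wunsch with affine gaps
(Gotoh three-state recursion, implemented in C++; a gap of length L costs
`open + extend*(L-1)`, defaults open = 10, extend = 0.5, BLOSUM62). The
substitution matrix matches the one used for the homolog tree work; the gap
defaults are conventional EMBOSS-style values and are CLI-overridable —
they are documented defaults, not published ones. Three figures are
reported: percent identity over the full alignment (gap columns in the
denominator), and percent identity and percent similarity over the
*conserved region*. "Similarity" is defined as aligned pairs with a
strictly positive substitution score (identities always count); this is one
of several possible conventions and is recorded as such. The conserved
region itself is operationalized as the H-cluster block bracketed by the
first L1 match and the end of the last L3 match in the reference — the
region both enzymes share once accessory N-terminal domains are set aside.
The same bounds are used to trim a homolog alignment before tree work.
Ties in the alignment DP are broken deterministically (diagonal, then
vertical, then horizontal), so outputs are reproducible.

## Conservation profiling

Columns where the two focal sequences agree carry no information about the
bias and are removed. For each remaining column the homolog set (all
records minus the two focal ones) is partitioned into A-type (equal to the
focal-A residue), B-type (equal to focal-B), and other; gaps always count
as other, including when a focal residue is itself a gap, so the three
percentages sum to 100 exactly. Whether the profile is computed over the
full alignment or only the trimmed H-cluster block is a flag (`columns =`),
because the published description does not pin the denominator context;
both routes give identical percentages at any column they share (verified
by test).

## Structural proximity filter

The second enzyme's model is superposed onto the reference by Kabsch least
squares (SVD with determinant correction; degenerate/collinear inputs are
an error, not a silent fit). Distances are minimum heavy-atom distances —
all backbone and side-chain atoms, hydrogens excluded — from a residue to
any atom of a named cofactor cluster group. A differing residue becomes a
candidate site when that minimum is ≤ 5 Å, the cutoff used for
second-coordination-sphere reasoning. By default the test passes if either
the reference residue or the model residue is within the cutoff (the union
is the conservative screen given model coordinates are approximate); a
flag restricts it to one structure. The region label is the argmin cluster,
with an optional collapse map so the 2Fe subsite and its cubane report as a
single "H-cluster" region; argmin ties are broken by the fixed cluster
label order of the reference structure.

## Blomberg's K and its permutation test

For a rooted tree with branch lengths, the Brownian-motion covariance C has
entries equal to shared root-to-MRCA path lengths. With the GLS mean
`â = (1ᵀC⁻¹1)⁻¹1ᵀC⁻¹y`,

* MSE₀ = (y−â1)ᵀ(y−â1)/(n−1),
* MSE = (y−â1)ᵀC⁻¹(y−â1)/(n−1),
* K = (MSE₀/MSE) / ([tr(C) − n/(1ᵀC⁻¹1)]/(n−1)).

K = 1 exactly on star trees (C = I makes the observed ratio equal its
expectation), ≈ 1 under Brownian motion on any tree, → 0 for patterns
random with respect to the tree, and > 1 for stronger-than-BM clustering.
K is invariant to affine transforms of the trait. Numerical choices: solves
use a Cholesky factorization of C (never an explicit inverse — the
explicit-inverse route lives in the test oracle); a numerically singular C
is ridged by `1e-10·I` with a warning; a constant trait returns `NA` with a
warning because K is undefined there, not zero. Unrooted trees are refused
with instructions to root (the published workflow roots with outgroups);
the one exception is a pure star topology, which ape flags as unrooted but
which is a legitimate rooted BM shape.

Residue usage at a column is encoded as a binary indicator — 1 when the
tip carries the chosen focal residue, 0 otherwise — which is the recorded
interpretation of "amino acid usage at a position" as a trait; the
`residue = "a"`/`"b"` switch selects which focal residue defines the
indicator. Tips missing from the alignment, or gapped at a column, are
pruned for that column (logged). The permutation p-value shuffles trait
values across tips and counts arrangements whose phylogenetic MSE is at
most the observed (low MSE = at least as tree-like), with the +1
correction, so p ≥ 1/(n_perm+1); the default n_perm = 999 and mandatory
seed make results reproducible. The permutation null is standard
infrastructure added for interpretability — the published analysis reports
K values only, and this package likewise flags K ≥ 1 without making
evolutionary claims.

When no externally inferred phylogeny is available, `p_distance()` (pairwise
deletion) plus `nj_tree()` provide a neighbor-joining fallback; maximum
likelihood inference is deliberately out of scope, as trees are consumed,
not inferred.

## qPCR model

Each gene amplifies by (1+E) per cycle with E its fractional primer
efficiency in (0, 1] — the convention matching published efficiencies in
the 0.84–0.98 range. The efficiency-corrected ratio on replicate-mean Cts
is `R = (1+E_t)^ΔCt_t / (1+E_r)^ΔCt_r` with `ΔCt = mean Ct(N+) − mean
Ct(N−)`, so R > 1 means induction under nitrogen fixation. Multiple control
genes combine by the geometric mean of their normalization factors; a
`simple_ddct` switch degrades gracefully to the classic 2^(−ΔΔCt) method.
Replicate scatter propagates to the ratio on the log scale (normal
approximation), giving an interval rather than a bare point estimate —
the published description is silent on error handling, so this is a
package choice. The exact published fold changes are not recomputable
without the raw Ct values, which is why the test suite substitutes
round-trip (planted ratio recovered to 1e-12 noise-free) and antisymmetry
(swapping condition labels inverts the ratio exactly) properties.

## What the synthetic generators emulate — and what they do not

`gen_tree()` draws pure-birth (Yule) trees; `gen_bm_trait()` simulates BM
by recursing increments down the edges, deliberately independent of the
covariance-matrix code it calibrates; `gen_binary_trait()` offers both a
BM-threshold mechanism (signal-bearing) and a symmetric two-state Markov
process (rate-controlled), since the real trait process is unknown.
`gen_msa()` plants motifs at fixed offsets and exact per-column residue
counts; `gen_structure()` places single-atom residues at exact minimum
distances from 4-atom cofactor clusters spaced 40 Å apart;
`gen_ct()` plants expression ratios through the (1+E) model. All randomness
flows from one seed via `split_seed()` (seed the RNG, draw sub-seeds below
2³¹).

A green test on these inputs establishes that the pipeline's arithmetic is
correct on data obeying its own assumptions. It does not establish
performance on real data: real homolog sets have phylogenetically
correlated residue columns (the generator plants frequencies independently
of the tree, which is why planted-profile K values sit near 0), real
alignments have alignment error and indel structure, real structures have
full side chains and alternate conformations, and real Ct tables have
between-run effects the noise model ignores. Defaults encode the stated
world of the analysis: 5 Å cutoff, BLOSUM62, 999 permutations, BM sigma 1,
triplicate qPCR reactions, and a 64-tip / 200-replicate K calibration whose
mean is expected in [0.9, 1.1].

## Degenerate inputs and tie-breaks

Ragged alignments, missing branch lengths, negative lengths, insertion
codes, non-cysteine "ligand" annotations, empty cluster groups, constant
traits, sub-3-taxon distance matrices and out-of-range efficiencies are all
hard errors or explicit NA-with-warning cases — never silent defaults.
Lowercase residues are uppercased with a warning; `.` gaps normalize to
`-`; HETATM atoms not covered by the user's cluster mapping are ignored
with a warning, since the mapping — not the file — defines the cofactor
inventory. Alignment columns and structure residue numbers are 1-based
with closed intervals throughout, matching how sites are reported in the
field (e.g. "M353").

## Known limitations

* Group assignment covers A2/A3/B2 only; the full A1–A5/B1–B3 scheme and
  genomic-context classification are out of scope.
* The conserved-region definition (L1 start to L3 end) is an
  operationalization; published identity/similarity figures depend on the
  original's unstated alignment parameters and region bounds, so exact
  reproduction is alignment-parameter-sensitive and requires external
  sequence downloads in any case.
* `candidate_sites()` requires a user-supplied cluster mapping and
  column-to-residue site map; the package does not guess cofactor
  identities from HETATM names.
* The NJ fallback is a fallback: for publication-grade trees, infer
  externally and pass newick.
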