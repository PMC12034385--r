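# conpatch

Detection of spatially clustered, evolutionarily conserved amino-acid
patches in protein tertiary structures.

Purifying selection leaves a per-site signature in orthologous sequence
alignments: functionally or structurally critical residues accumulate
substitutions slowly. Per-site conservation scores alone, however, say
nothing about *where* those residues sit in the folded protein. Active
sites, binding pockets and folding cores are spatial objects — their
residues may be scattered along the sequence yet packed together in 3D.
`conpatch` combines a multiple sequence alignment with a tertiary
structure (experimental or predicted) to test formally whether the most
conserved sites form a spatial patch, and where that patch is.

It is aimed at molecular evolutionary biologists and structural
bioinformaticians who have an alignment of orthologs and a PDB file and
want a statistically calibrated answer, not just a colored surface.

## The method

1. **Site-specific substitution rates.** A neighbor-joining guide tree is
   built from Poisson-corrected distances; the shape `alpha` of a mean-one
   gamma distribution of among-site rate variation is fitted by maximum
   likelihood (discretized into k = 16 equal-probability categories,
   JTT exchangeabilities with empirical frequencies); each column's rate is
   its empirical-Bayes posterior mean
   `E[r | column] = sum_c r_c L(col | r_c) / sum_c L(col | r_c)`,
   z-normalized so that lower = more conserved. Precomputed Rate4Site
   output files are accepted as a drop-in alternative.
2. **Mapping.** The alignment's reference row is globally aligned
   (Needleman–Wunsch, BLOSUM62) to the structure's sequence; rates are
   transferred to residues. Either Cα positions or residue centers of mass
   (mass-weighted over heavy atoms; a proxy for side-chain orientation)
   define residue coordinates.
3. **Spatial weighting.** For each residue A and window size w, the
   spatially correlated rate is the distance-discounted average over the
   neighborhood `N(A) = { i : d_Ai <= w }`:

   `S̄(A) = (1/N) * Σ_{i in N(A)} [ S_i  if d_Ai = 0 ;  S_i / d_Ai  otherwise ]`

   (the focal site contributes its own rate unweighted; the divisor is the
   neighborhood size N, not the weight sum).
4. **Anchored patch test.** The centroid of the sites with the lowest
   spatially weighted rates (default: 10%) is the *anchor point*. The
   Euclidean distances to the anchor of the most conserved 10% of sites
   are compared with the distances of the remaining sites by a one-sided
   two-sample t-test (Welch). The score is `log P = -ln(p)`; windows are
   scanned from 1 to 20 Å in 1 Å steps and the window maximizing log P is
   reported. `log P >= 8` declares a conserved patch.
5. **Controls.** A permutation null (shuffling the raw rates across
   residues and rerunning the whole scan) calibrates the threshold, and a
   simulation benchmark with planted conserved clusters measures power.

## Worked example

On real data you would pass file paths
(`conpatch("orthologs.fasta", "structure.pdb", chain = "A")`). The same
pipeline on a self-contained synthetic dataset with a planted conserved
cluster:

```r
library(conpatch)

bd  <- simulate_benchmark(n_seq = 60, n_sites = 200, gamma_shape = 0.7,
                          seed = 11)
fit <- conpatch(bd$alignment, bd$structure, coords = "ca",
                n_perm = 50, seed = 1)
fit
#> Conserved-patch analysis
#>   200 alignment columns, 200 structure residues, 200 mapped (CA coordinates)
#>   rates: internal
#> Window scan (1-20 A, fraction 0.10): optimal 1 A, log P = 39.65 (significant at threshold 8)
#>   permutation null: 100.0% of 50 replicates below threshold

summary(fit)
#> Optimal window: 1 A  (log P = 39.65, t = -10.94)
#> Patch DETECTED at threshold 8
#> Anchor point: (4.36, -24.11, 38.44) A
#> Conserved sites (20): GLN67 SER69 ASN70 LEU83 GLU91 ASN92 LEU95 LEU96 ...
```

The printed numbers mean: across the 20 candidate window sizes the
strongest spatial clustering of conserved sites was found at a 1 Å window
(i.e. already in the unsmoothed rates), with a Welch t of -10.9 — the 20
most conserved residues sit far closer to the anchor than the remaining
180 (p = e^-39.7). None of 50 rate permutations reached the threshold, so
the patch is not an artifact of the scan. `plot(fit)` draws log P against
window size; `write_site_table()`, `write_run_summary()` and
`write_annotated_pdb()` export a per-site TSV, a JSON run summary, and a
PDB with the weighted rates in the B-factor column for coloring in a
molecular viewer.

A command-line interface wraps the same functions:

```sh
inst/scripts/conpatch run --alignment orthologs.fasta --structure protein.pdb \
    --chain A --coords com --nperm 100 --seed 1 --out results/
inst/scripts/conpatch simulate --nseq 60 --nsites 200 --shape 0.7 --out sim/
inst/scripts/conpatch benchmark --ndatasets 100 --nperm 20 --seed 1 --out bench/
```

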