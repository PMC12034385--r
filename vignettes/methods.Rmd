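---
title: "Detecting conserved amino-acid patches: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved amino-acid patches: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`conpatch` asks one question of an alignment/structure pair: do the most
conserved sites cluster in space? This vignette documents the statistical
model behind each stage, the tunable parameters, the design decisions that
were genuinely open and how they were resolved, and what the simulation
benchmark does and does not demonstrate.

## 1. Site-specific substitution rates

Rates are estimated per alignment column under a standard
phylogenetic model:

* **Guide tree.** Pairwise Poisson-corrected distances
  `d = -ln(1 - p)` (mismatch fraction `p` over gap-free column pairs,
  saturated to `d = 3` at `p >= 0.95`) feed neighbor joining. Negative
  branch lengths are clamped to zero with the slack moved to the sibling
  branch so adjacent distances are preserved. Branch lengths are *not*
  re-optimized by maximum likelihood afterwards — a deliberate speed/
  accuracy trade-off; downstream only the *ranking* of site rates matters,
  which is robust to modest branch-length error.
* **Rate prior.** A mean-one gamma distribution with shape `alpha`
  discretized into `k = 16` equal-probability categories, each represented
  by its conditional mean (so the representatives average exactly to 1).
  `alpha` is fitted by a log-spaced grid search (default 40 points in
  [0.05, 5]) over the summed column log-likelihoods, computed by
  Felsenstein pruning (C++, with per-site rescaling against underflow on
  large trees) under JTT exchangeabilities and empirical amino-acid
  frequencies. LG is available.
* **Per-site scores.** The empirical-Bayes posterior mean
  `E[r | column] = sum_c r_c L(col | r_c) / sum_c L(col | r_c)` with a
  uniform prior over categories; gaps and `X` are missing data (all-ones
  partial likelihoods). Scores are z-normalized over columns; lower =
  more conserved. Columns with no observed residues score 0 with a
  warning; if the score standard deviation is zero (e.g. identical
  sequences) all scores are 0. Per-site uncertainty is intentionally not
  propagated: the patch statistic consumes only the scores.

Imported Rate4Site result files travel through the identical downstream
path (`provenance = "imported"`); the test suite checks the two sources
are interchangeable.

## 2. Spatial weighting

Given residue coordinates (Cα, or the mass-weighted center of mass of all
heavy atoms — the default `com` mode tracks side-chain orientation) and a
window `w` in Å, the spatially correlated rate of residue `A` is

S̄(A) = (1/N) Σ_{i ∈ N(A)} { S_i if d_Ai = 0; S_i / d_Ai otherwise },

where `N(A) = {i : d_Ai <= w}` *includes the focal residue* (its own rate
enters unweighted via the `d = 0` branch) and `N` is the neighborhood
count. Two properties deserve emphasis:

* The divisor is `N`, **not** the sum of weights. This is not a
  conventional weighted mean: residues with many distant neighbors are
  shrunk toward zero. The scan is robust to this because it only ranks
  sites within one window size.
* The case split is on distance, not identity, so residues at coincident
  coordinates contribute each other's raw rate — no division by zero is
  possible. The neighborhood boundary is closed (`d <= w`) for
  determinism.

## 3. The anchored patch test

Per window size the method computes:

1. an **anchor point** — the unweighted centroid of the sites with the
   lowest spatially weighted rates (default fraction 0.10 of mapped
   residues, minimum 2; ties at the cutoff go to the lower index);
2. a **tested group** — the most conserved fraction by the **raw**
   (unsmoothed) scores;
3. a one-sided two-sample t-test comparing the anchor distances of the
   tested group against those of the remaining sites, scored as
   `log P = -ln(p)` with `p` floored at 1e-320.

Windows run from 1 to 20 Å in 1 Å steps; the maximal log P wins, with
ties resolved toward the smallest window (least smoothing). The default
significance threshold is `log P >= 8`, i.e. `p <= e^-8 ≈ 3.4e-4`.

Three design points here were genuinely open, and each was resolved by
requiring the permutation null to be calibrated and the positive controls
to retain power:

* **Separate selections for anchor and group.** If the tested group were
  also selected by the *smoothed* rates, the test would be strongly
  anticonservative: the lowest values of any spatially smoothed field form
  a contiguous spatial blob even for i.i.d. random rates, so the group
  would cluster around its own anchor under the null. Measured on
  permuted rates, that variant exceeds the threshold in a third or more
  of replicates. Selecting the group by the raw scores (whose minima are
  spatially diffuse under the null) while letting the anchor track the
  smoothed field keeps the null clean and loses no power: under a true
  patch both selections coincide.
* **Natural-log scale.** With `log P = -log10(p)` a threshold of 8 means
  `p <= 1e-8`, which a group of 5–10 sites (10% of a 50–100-residue
  protein) cannot reach even under perfect geometric separation — the
  t statistic is bounded by the group size. On the natural scale the
  threshold corresponds to `t ≈ 3.5`, attainable across the whole size
  range while remaining conservative under permutation, as the test suite
  verifies.
* **Welch rather than pooled variance.** A genuine patch makes the tested
  group's distances tight (small variance) while the remainder spans the
  whole structure (large variance) — the textbook unequal-variance
  situation. The pooled statistic dilutes exactly the datasets where the
  signal is clearest (small proteins); Welch recovers them and is
  near-identical to the pooled test under permutation, where both groups
  have comparable variance. The pooled variant stays available
  (`var_equal = TRUE`) and is what the closed-form checks in the test
  suite exercise.

The permutation null shuffles the **raw** rate vector across residues and
reruns the entire cascade — re-weighting included — so spatial
correlation is destroyed at its source; each replicate's optimal log P is
recorded and compared against the threshold.

## 4. The simulation benchmark

`run_benchmark()` emulates the conditions the method is intended for:

| parameter | default | meaning |
|---|---|---|
| `n_datasets` | 100 | datasets, round-robin over five size strata |
| strata | 50–100 … 400–500 | alignment columns = chain length |
| `n_seq_range` | 20–200 | sequences per alignment |
| `shape_range` | 0.5–0.9 | gamma shape of rate heterogeneity |
| `clustered_fraction` | 0.30 | planted conserved fraction |
| `ca_spacing_mean` | 3.8 Å | consecutive Cα spacing |
| `n_perm` | 20 | permutation replicates per dataset |

Each dataset is built in the order an empirical study would: a random
Yule-style tree (exponential branch lengths, mean 0.1 substitutions/site),
an alignment evolved column-by-column under LG with gamma rates (rates are
estimated back with JTT — a deliberate model mismatch, mimicking practice),
conservation estimated, and only then a synthetic structure in which the
30% most conserved *estimated* sites are spatially clustered. Planting
follows estimation because the benchmark probes the spatial statistic, not
the rate estimator (whose accuracy is tested separately by rank-recovery
against the true simulated rates).

The chain generator is a self-avoiding random walk: steps
`~ N(3.8, 0.2)` Å truncated above the 3.0 Å exclusion radius, proposals
closer than 3.0 Å to any earlier point rejected, with restart caps. The
planted cluster is enforced *constructively*: a contiguous block of
`m = round(0.3 n)` steps, starting at a random chain position, is confined
to a sphere of globular packing radius `(3 m · 134 Å³ / 4π)^{1/3}` around
its entry point, forming a compact sub-domain; alignment columns are then
assigned to chain positions so that the `m` most conserved columns occupy
the block (columns of an i.i.d.-sites simulation are exchangeable, so this
is a relabeling, not a distortion). This keeps the emitted file in walk
order — consecutive-residue spacing stays ~3.8 Å — and makes the
alignment-to-structure mapping the identity, which the sequence-based
mapper must and does recover.

**What the generator does *not* emulate**, and hence what passing
benchmarks cannot certify about real data: indels and alignment error
(inputs are assumed clean and gap-handling is only tested as missing
data); heterotachy (rates are constant along the tree); structural
ensembles or coordinate error (a single exact chain, with center of mass
equal to Cα); multi-domain and oligomeric architecture (one chain, at most
one planted patch); and non-globular cluster geometry. Real structures are
handled through bio3d with altloc/occupancy rules, but the benchmark never
exercises crystallographic pathologies.

## 5. Numerical choices and degenerate inputs

* p-values floored at 1e-320, so `log P` is finite and `<= 736.8`.
* Zero variance in both distance groups (all sites equidistant from the
  anchor, e.g. coincident coordinates): `p = 1`, `log P = 0`, warning.
* `round(fraction × n) < 2` selected sites: a configuration error
  ("protein too small for fraction"), reported per-entry inside
  `fraction_sweep()` without aborting the sweep.
* Identical alignment rows: z-score denominator zero → all scores 0; the
  scan then reports a degenerate, non-significant result rather than
  failing.
* Pruning likelihood underflow on deep trees: per-site rescaling inside
  the C++ kernel; a column with zero likelihood in every category scores
  0 with a warning.
* Mapping: global Needleman–Wunsch with BLOSUM62, gap open 10, extension
  0.5; below 30% identity over aligned positions the run aborts — in
  practice that means the wrong structure or the wrong alignment.
* All randomness flows from explicit seeds; campaign tables are
  bitwise-reproducible under the master seed, and every JSON summary
  echoes the full configuration including the seed.

## 6. Problem sizes used by the test suite

The shipped tests run the full campaign at 100 datasets × 20 permutations
with a 10-point shape grid for the per-dataset rate estimation (the
40-point default grid is used where a single estimate is examined in
depth). These sizes are the package's desk-scale defaults: one hundred
datasets bound the detection-rate estimate's standard error below ~3
percentage points, and posterior-mean *rankings* — all the scan consumes —
are insensitive to shape-grid resolution well before 10 points.

## 7. Known limitations

* One anchor, hence one patch per run; proteins with several conserved
  regions (or several domains) should be split and analyzed per domain.
* Not designed for oligomers: interfaces contributed by other chains are
  invisible.
* Isolated conserved sites (no spatial neighborhood) are outside the
  method's scope by construction.
* The internal rate estimator trades exactness for self-containment
  (fixed NJ branch lengths, grid-fitted shape); users wanting
  publication-grade rates can import Rate4Site output directly.
* The spatial weighting is not a proper weighted mean (see §2); its
  values should be read as rankings, not calibrated rates.
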