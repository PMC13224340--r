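---
title: "Delineating seasonal microbial ecotypes with three dimensionality reductions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating seasonal microbial ecotypes with three dimensionality reductions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecotyper)
```

## The problem

Dense 16S amplicon time series resolve thousands of amplicon sequence
variants (ASVs) across hundreds of samples, far more dimensions than any
seasonal interpretation needs. `ecotyper` implements and compares three
routes from such a table to a small set of recurrent, functionally coherent
community states — *ecotypes*:

1. **PCoA + k-means** — classical metric ordination of samples, clustered in
   the reduced space;
2. **SOM + k-means** — a self-organizing map on a toroidal hexagonal grid, a
   non-linear prototype-based reduction, with k-means super-clustering of
   the map;
3. **Co-abundance network modules** — a signed weighted correlation network
   over ASVs, transformed to a topological overlap matrix (TOM) and
   segmented into modules by k-means on the TOM dissimilarity (a hybrid
   variant of the usual hierarchical module detection).

Downstream statistics (PERMANOVA, Kruskal–Wallis with post hoc rank-sum
tests, NMDS with permutation-tested environmental vectors) validate the
segmentations, and a rule-based integration step decides which clusters
and modules qualify as ecotypes.

## Preprocessing

Raw counts go through a fixed chain: singleton removal (total count exactly
1 across the study — a read-count concept, so it precedes any
normalization), division by the per-ASV 16S copy number, relative
abundance, and the Hellinger transformation
$y_{sa} = \sqrt{x_{sa} / \sum_a x_{sa}}$. Euclidean distance between
Hellinger rows equals the Hellinger distance between compositions, which
is what makes Euclidean-assumption methods (PCoA, SOM prototypes, k-means)
defensible on community data.

The network arm additionally applies a QC tailored to correlation methods:
zero-variance ASVs are dropped, samples with more than 50% zeros among the
surviving ASVs are dropped, and the most abundant half of the ASVs (by
mean relative abundance — a Hellinger table is squared back to abundance
scale before ranking) is retained. Both thresholds are configurable; the
50%-abundance default keeps the table dense enough for stable Pearson
correlations at these sample sizes.

## The three reductions

**PCoA.** Gower double-centering of the squared distance matrix followed by
an eigendecomposition; coordinates are eigenvectors scaled by
$\sqrt{\lambda}$. Negative eigenvalues are dropped without correction —
the pipeline feeds Euclidean-on-Hellinger distances, whose Gower matrix is
positive semi-definite, so nothing is lost. k-means runs on the first
**three** axes: $k$ well-separated groups need up to $k-1$ dimensions, and
with the four seasonal states typical of a polar year, two axes can
project two cluster centers on top of each other. Each axis is oriented so
its largest-magnitude coordinate is positive, making output reproducible
across platforms.

**SOM.** A from-scratch online competitive learner. The grid is hexagonal
(offset rows, spacing $\sqrt{3}/2$) and toroidal, so every unit has an
identical neighborhood structure and the map has no edge effects; the
toroidal distance is the minimum over the nine shifted copies of the
plane. Defaults follow common practice where the study design leaves them
open: codebooks initialized from data rows (robust for compositional
data, deterministic under seed), bubble neighborhood, 100 passes over the
data, learning rate decaying linearly 0.05 → 0.01, radius decaying
linearly from the 2/3 quantile of grid distances to just below the
smallest positive distance (so training ends with BMU-only refinement).
The per-pass mean distance of presented samples to their best-matching
unit is recorded as a training trace.

Samples are clustered by running k-means on their BMU codebook vectors.
One subtlety: the silhouette used for choosing $k$ is computed on the
*original* Hellinger profiles, not on the BMU representation. Samples
sharing a unit are identical points in BMU space, so any clustering that
keeps units intact has within-cluster distance 0 and silhouette exactly 1
— the scan would always pick the largest $k$. Judging separation in data
space removes this degeneracy while leaving the clustering itself in the
map's smoothed space.

**Network modules.** Signed adjacency $a_{ij} = ((1+r_{ij})/2)^\beta$ with
$\beta = 8$ (chosen in the usual way via the scale-free topology fit
index, `pick_soft_power()`), topological overlap
$\mathrm{TOM}_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$,
and k-means on the rows of $1 - \mathrm{TOM}$ as Euclidean feature
vectors, with $k$ chosen by the same elbow/silhouette scan (2–10).
Modules are summarized by eigengenes (first principal component of the
standardized member profiles, unit variance, sign-oriented to correlate
positively with its members); modules whose eigengenes correlate above
0.7 are merged iteratively, recomputing eigengenes after every merge so
the result does not depend on the initial pair order. Module membership
(kME) is the correlation of each ASV with each eigengene; module–trait
relationships are Pearson correlations of eigengenes with trait and
environmental covariates, with two-sided $t$-based p-values reported raw
(tagged `p_adjust_method = "none"`).

## Choosing k

All three arms share one rule (`choose_k()`): the elbow $k$ maximizes the
perpendicular distance of the (k, WSS) curve to its endpoint chord, with
both axes rescaled to [0, 1] so the rule is unit-free ("inflection" is
not computable verbatim; distance-to-chord is its standard parameter-free
operationalization). The silhouette $k$ maximizes mean silhouette width.
When they disagree the silhouette wins — it is the criterion that also
sees between-cluster separation — and the conflict is recorded in the
returned rule trace. k-means itself is Lloyd iteration from k-means++
seeding, best of 25 restarts, with empty clusters repaired by re-seeding
at the farthest point of the largest cluster; on instances small enough
to enumerate every partition, the restarts recover the global WSS optimum
(this is asserted in the test suite).

## Statistics

PERMANOVA partitions the squared distance matrix in the one-factor form
(pseudo-$F$ with $k-1$ and $n-k$ degrees of freedom) and permutes raw
labels; all permutation p-values use the add-one estimator
$(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + B)$, which cannot return 0.
Group trait comparisons use Kruskal–Wallis and pairwise two-sample
Wilcoxon rank-sum tests (exact null for small tie-free groups, normal
approximation with continuity correction otherwise) with Holm adjustment.
The rank-sum form is the applicable Wilcoxon variant for independent
clusters of unequal size; a signed-rank test would require paired
observations. NMDS minimizes Kruskal stress-1 by alternating
pooled-adjacent-violators monotone regression with Guttman majorization
updates, best of 20 random starts plus a PCoA start, converged when the
stress decrease falls below 1e-6.

## Ecotype qualification

Every sample cluster (PCoA, SOM) and every module is a candidate. The
module arm enters sample space through *dominance*: the module whose
members' summed relative abundance is largest on a date labels that date.
A candidate qualifies if:

- **functionally distinct** — for sample clusters, at least one of
  {doubling time, genome size} differs significantly (Holm-adjusted
  rank-sum p < 0.05) from *every* other supported cluster of the same
  method; for modules, the eigengene correlates (p < 0.05) with at least
  2 of {copy number, doubling time, genome size, GC content,
  chlorophyll-a}; **and**
- **compositionally distinct** — the Jaccard overlap of its top-25 most
  abundant ASVs with each temporally adjacent dominant cluster is below
  0.5; **and**
- **COG-validated** — at least one COG category whose scaled profile is
  ≥ 0.75 for the candidate while every temporally adjacent cluster is
  ≤ 0.5. Profiles are per-category z-scores across the metagenome dates
  rescaled min–max to [0, 1] (z-scores alone are unbounded, so a "scaled
  0–1 z-score" is implemented as z-score followed by min–max) and averaged
  over the candidate's dates. Candidates with no matching metagenome date
  are flagged and the criterion is skipped with a warning rather than
  failed — sparse metagenome coverage should not veto an otherwise
  well-supported state.

Candidates with fewer than 3 samples are rejected outright with reason
`"insufficient support"`, and are also excluded from the pairwise trait
comparisons (a 2-sample noise cluster should not be able to veto the
significance of a 50-sample cluster). Qualified candidates whose sample
sets overlap at Jaccard ≥ 0.5 are grouped into one cross-method ecotype;
Jaccard (not the overlap coefficient) is used so a small
boundary-straddling cluster cannot chain two adjacent windows together.
Each ecotype's sample set is the majority vote of its member candidates,
which keeps one over-extended cluster from stretching the reported window.

## The synthetic study

`generate_dataset()` emulates a near-daily polar surface-ocean year at
desk scale: 200 samples over ~11 months starting 2019-10-29 with two
excised field gaps (25 and 12 days), 800 ASVs with log-normal loadings
(sdlog 1.2, heavy-tailed, including 20 planted singletons and a 30%
background fraction), four seasonal modules, and four sample-level
ecotype windows driven by those modules.

Design choices worth recording, because the obvious alternative fails:

- **Seasonal latents are flat-topped bumps with logistic shoulders**
  (plateau per window, transitions of about two days), parameterized by
  sample index so the excised gaps cannot skew the crossings.
  Equal-amplitude bumps then cross exactly at the window boundaries and
  the argmax ground truth coincides with the boundary a sample-space
  clustering can recover. Pure Gaussian bumps were tried first and
  produce a compositional *continuum*: with no plateau structure the
  silhouette criterion has no preferred k and recovered boundaries drift
  by a week or more. The quasi-discrete regime is also the ecological
  claim being modeled — alternating community states, not a smooth blend.
- **The pulse module** is a two-day rectangular burst of ~6 comparably
  loaded taxa (year-round low baseline, high GC, unremarkable copy
  number) strong enough to dominate its two samples — an advected
  different-water-mass pair, planted so the pipeline must *reject* it:
  it surfaces as a 2-sample candidate and fails the minimum-support rule.
- **Metagenome dates** sit on a stride-12 grid offset into the windows
  (16 dates), so the sparse functional table samples states, not the few
  transition days; each ecotype has one planted COG category enriched by
  a factor of 5 on its dates, with ~8% log-normal tpm noise.
- **Traits** are abundance-weighted mixtures of per-module trait means
  (fast-growing large-genome bloom taxa through slow streamlined winter
  taxa) with 3% noise, and environmental covariates are smooth seasonal
  curves plus noise, so trait and envfit statistics have planted sign
  structure to recover.

What the generator does *not* emulate: taxonomic identity, sequencing
error, zero-inflation beyond multinomial sampling, compositional
correlation artifacts, or drift in the underlying gradients. Passing
tests therefore demonstrate method correctness and recoverability under
the planted model, not performance guarantees on real surveys.

## Problem sizes and numerical choices

The shipped tests run the full pipeline at 200 × 800 (about half a
minute including the NMDS comparison), module
recovery at 600 ASVs over 10 seeds, and ecotype recovery at low noise
(noise_sd 0.1) over 10 seeds; permutation calibrations use 199
permutations with 200–500 replicates. Key tolerances: PCoA/PCA agreement
1e-8; TOM against brute force 1e-12; k-means against exhaustive
enumeration on n ≤ 9; silhouette of single-member clusters defined as 0;
k-means ties broken toward the first center; BMU ties toward the lowest
unit index; eigengene sign toward positive mean member correlation.

## Limitations

The hybrid module detection fixes k globally, so very small genuine
modules can be absorbed when the silhouette scan favors fewer clusters.
The COG validation rule needs at least one metagenome date per candidate
to bind. PERMANOVA is one-factor with free permutation — no strata or
repeated-measures structure. The SOM uses a single fixed grid size; grid
selection is left to the caller (the occupancy histogram in
`map_samples()` is the intended diagnostic).
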