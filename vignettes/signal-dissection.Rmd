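---
title: "Dissecting gene-wise phylogenetic signal for competing topologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting gene-wise phylogenetic signal for competing topologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Phylogenomic datasets routinely produce conflicting, strongly supported
resolutions of the same clade depending on the inference method:
coalescent-aware summary methods, concatenation under site-homogeneous
partitioned models, and site-heterogeneous mixture models can each prefer a
different attachment point for a single rogue clade while agreeing on
everything else. When that happens, the informative question is no longer
"which tree is best" but "which loci prefer which resolution, how strongly,
and does anything about those loci explain their preference".

`topodissect` answers this question locus by locus. It takes per-locus
amino-acid alignments, per-locus gene trees, and a small set of candidate
species-tree topologies (typically three, differing only in one clade's
position), and computes:

1. **Gene-wise log-likelihood scores (GLS)** — for each locus and each
   candidate topology, branch lengths are re-optimized on the fixed
   topology (pruned to the locus' taxa) and per-site log-likelihoods are
   summed.
2. **deltaGLS** — differences of GLS between topology pairs. With three
   candidates the three deltas satisfy the identity
   `delta(1,2) = delta(1,3) - delta(2,3)`, so the delta space has rank 2
   and a PCA of it captures 100% of the variance on two axes.
3. **Categorization** — each locus is called uninformative (A), supporting
   (B), or rejecting (C) a focal topology using a +-2 log-likelihood-unit
   threshold on the focal-involving comparisons.
4. **Treespace disparity** — quartet dissimilarities between gene trees,
   ordinated by PCoA; conflict is measured as the mean distance to the
   centroid, compared against nulls built from random subsamples.
5. **Gene properties and determinants** — a fifteen-metric panel per locus,
   a usefulness ranking, permutation-tested vector fitting of each metric
   onto the deltaGLS ordination, and a conditional-inference-style
   classification tree on the A/B/C factor.

A synthetic-data generator emulates the whole data-generating process so
every stage can be exercised and calibrated without any external data.

## The likelihood engine

Likelihoods use time-reversible empirical amino-acid models. A model is an
exchangeability matrix `S` and stationary frequencies `pi`; the generator
is `Q_ij = s_ij pi_j` with the diagonal set so rows sum to zero, rescaled
so `-sum_i pi_i Q_ii = 1` (branch lengths in expected substitutions per
site). Transition probabilities come from the symmetric eigendecomposition
of `diag(sqrt(pi)) Q diag(1/sqrt(pi))`, which is numerically stable for any
branch length. Rate heterogeneity across sites is the usual discrete gamma
with four equiprobable categories whose rates are category **means**
(the common default of maximum-likelihood engines). LG, WAG and JTT are
available (via the matrices shipped with `phangorn`), plus the Poisson
model, whose transition probabilities have the closed form
`P_ii(t) = 1/20 + (19/20) exp(-20 t / 19)` used as an exact oracle in the
test suite.

Per-site likelihoods are computed by Felsenstein pruning in post-order with
per-node rescaling against underflow. Missing residues, gaps, and ambiguity
codes (`X ? - . B Z J *`) all contribute all-ones partial vectors — they
are marginalized, not treated as extra states — so an entirely missing
column has log-likelihood exactly zero.

**Branch-length optimization** on a fixed topology is coordinate-wise: each
branch in turn is optimized by bounded scalar search on `[1e-8, 10]` with
the partial likelihoods on either side of the branch held fixed. Writing
the flank partials in the eigenbasis reduces each candidate evaluation to a
20-vector contraction per site, so a full sweep over branches costs little
more than two tree traversals. Sweeps repeat until the gene log-likelihood
improves by less than `1e-3` units (or 50 sweeps, flagged as
non-converged); the proposal step is simultaneous across branches, so after
each sweep the full likelihood is re-evaluated and a damped
(geometric-mean) step is taken if the joint update ever overshoots — the
best length vector seen is returned, which also guarantees the result is
never worse than the starting tree. The test suite verifies local
optimality by perturbing every branch +-10%.

**Model selection** is per locus: each candidate (by default Poisson, LG,
WAG, JTT, each with and without gamma) is scored by
`BIC = -2 lnL + k log(n_sites)` on a fixed guide tree, with `k` counting
only the gamma shape (matrices and frequencies are fixed empirical, so they
add no parameters); for gamma candidates the shape is optimized by a 1-D
search. Ties go to the fewer-parameter candidate. Selecting per locus —
rather than on merged partitions, a performance device of large concatenated
analyses — matches the per-locus nature of the deltaGLS quantities; branch
lengths are likewise refit per locus and per topology, since linking them
across loci would leak information between the quantities being compared.

## deltaGLS, PCA and categorization

`computeGLS()` prunes every candidate topology to each locus' taxon set
first (a 70%-occupancy matrix guarantees missing taxa). When two candidates
become topologically identical after pruning — e.g. a locus that samples
none of the movable clade — the pair is flagged *indistinguishable* and its
delta is forced to zero by construction (the later topology's score is
replaced by the earlier one's, which keeps the three-delta identity exact).

The PCA of the deltas is on the covariance matrix (no standardization):
all three deltas are in the same log-likelihood units. Sign conventions are
fixed so PC1 is positively associated with support for the focal topology
and PC2's loading on the non-focal pair is non-negative; this makes runs
deterministic without changing any geometry.

Categorization keys on the focal-involving comparisons only: `A` when all
three deltas are within the threshold (inclusive, default 2), `B` when at
least one focal-involving delta exceeds the threshold in favour and none
against, `C` for the reverse. Two edge cases are resolved explicitly and
flagged: loci whose only above-threshold delta is the non-focal pair are
assigned `A` with an `alternative_only` flag (they discriminate between the
alternatives but say nothing about the focal resolution), and loci with
above-threshold evidence in both directions are assigned by the larger
absolute focal-involving delta with ties going to `C`, flagged `conflict`.
These two rules are design choices of this package where published
descriptions of the approach leave the tie-breaking open; the flags make
every such locus auditable.

## Treespace and disparity

The quartet dissimilarity between two gene trees is the fraction of
four-taxon subsets, among those resolved in **both** trees after pruning to
shared tips, that are resolved differently. Quartet topologies are read
from path-length sums with unit branch lengths (the four-point condition);
ties mark unresolved quartets, which drop out of both numerator and
denominator. The implementation is validated against a brute-force oracle
that prunes every quartet and compares the resulting four-tip trees. Pairs
sharing fewer than four tips are median-imputed (and flagged) before
ordination.

PCoA is classical scaling via `ape::pcoa`, with the Cailliez correction
applied when the most negative eigenvalue exceeds `1e-8` in magnitude; all
axes with positive eigenvalues are retained, so the distance-to-centroid
disparity equals the dispersion in the full embedded space (how many axes
entered the published centroid calculations is not stated anywhere we could
find, so using all positive-eigenvalue axes is this package's documented
choice — disparity is then invariant to rotation, which the tests check).
Null distributions draw `k`-subsets uniformly without replacement, 1000
replicates by default; the percentile of an observed disparity is the
proportion of null values at or below it, and a one-tailed "significant
reduction in conflict" is called at the 5th percentile.

Clade recovery asks, for each gene tree and each named clade, whether the
sampled members (at least two, with at least one non-member present) form
one side of a bipartition of the unrooted gene tree; the per-locus summary
is the proportion recovered among testable clades.

## Gene properties, usefulness, determinants

The fifteen per-locus metrics cover information content and rate
(alignment length, % missing cells, proportion variable and
parsimony-informative sites, taxon count, mean site entropy, total tree
length, average patristic distance), phylogenetic signal (average internal
support, Robinson–Foulds similarity to a reference topology on shared taxa,
treeness = internal/total tree length), and systematic-bias proxies
(RCFV compositional heterogeneity, origin-constrained saturation
`1 - slope` of p-distance on patristic distance, root-to-tip variance after
midpoint rooting for clocklikeness, treeness/RCFV). Midpoint rooting is
used because pruned gene trees frequently lack outgroups. The exact
published panel behind this kind of sorting is specified only in
supplementary material we do not reproduce; the panel here follows the
method's published description and is a plain data frame, so adding or
substituting metrics is a data change, not a code change.

The usefulness ranking is a PCA of the z-scored panel. Among the first two
components, each is oriented so the signal metrics (support, RF similarity)
load positively and scored by the contrast `mean(signal loadings) -
mean(bias loadings)`; the axis with the larger positive contrast is the
usefulness axis. An exact sign-pattern match (signal one sign, all bias
metrics the other) would be stricter, but when bias metrics load near zero
on the quality axis their signs are arbitrary and the strict rule fails on
perfectly ordinary panels; the contrast rule degrades gracefully and is
deterministic. If neither axis shows a positive contrast the function stops
and asks for a manual choice rather than guessing.

Determinant testing is two-pronged, mirroring the linear and non-linear
routes. `vectorFit()` regresses a property on the two PCA score columns;
the squared multiple correlation is the effect size and its p-value comes
from permuting the property vector (10 000 permutations by default,
`p = (1 + #{R2_perm >= R2}) / (1 + n_perm)`); results match `vegan::envfit`
to numerical precision, which the tests verify. `fitSignalTree()` is a
conditional-inference-style recursive partitioning: at each node every
predictor's association with the A/B/C factor is measured by a
Kruskal–Wallis rank statistic (asymptotic chi-square p-values by default,
or permutation p-values by option), Bonferroni-corrected across the
predictors; the node splits only when the best adjusted p is at or below
alpha (0.05), at the cutpoint maximizing the chi-square association of the
binary split with the factor, and recursion stops at node size < 20 or
depth 5. This keeps the defining contract of conditional-inference trees —
splits must survive a multiplicity-corrected hypothesis test, so no pruning
is needed — while using a rank statistic that is simple to verify by
permutation. Null calibration (no association: root-only trees in well over
90% of simulations; planted thresholds: recovered within the data's
inter-point gap) is part of the acceptance tests.

## The synthetic-data generator

`generateScenario()` emulates the structure of a phylogenomic study of
about 39 taxa (35 ingroup in five order-level clades plus a movable clade,
and 4 outgroup-like terminals) with short amino-acid loci:

* **Candidate topologies**: a random base tree with labelled clades; the
  three candidates differ only in whether the movable clade attaches as
  sister to one clade, to another, or to their ancestor — so pruning the
  movable clade away collapses all three to the same tree. Contested
  internal branches default to 0.08 substitutions/site.
* **Locus lengths**: lognormal, `meanlog = log(225)`, `sdlog = 0.35`,
  clamped to [100, 650] — mean about 240 columns, the shape of a
  GBLOCKS-trimmed transcriptomic locus set.
* **Rates**: per-locus lognormal multipliers (`sdlog = 0.4`, mean about 1)
  scale all branch lengths.
* **Missing data**: each taxon is dropped from each locus with probability
  0.3 (a 70% occupancy matrix), keeping at least four taxa.
* **Sequences**: simulated under LG (configurable; optional within-locus
  discrete gamma) by drawing root states from `pi` and evolving along each
  branch with the exact transition probabilities.
* **Gene-tree error**: each gene tree is the true tree perturbed by a
  Poisson number of NNI moves with mean `2 x 0.25 x rate multiplier` —
  faster loci get noisier trees, which is what makes support- and
  congruence-based quality metrics covary realistically. Pseudo-bootstrap
  supports are Beta(3, 1.2) draws stretched to [50, 100] on edges whose
  bipartition survives in the true tree and [20, 90] on perturbed edges.
* **Optional compositional bias**: selected taxa have a fraction of
  residues resampled from a tilted frequency vector, raising RCFV.

Everything is driven by one master seed fanned out to named substreams
(`substreamSeed`), so scenarios are exactly replayable and individual
stages can be re-run in isolation. The truth table records every draw; no
analysis stage reads it — it exists so tests and the acceptance script can
compare recovered quantities against the generating process.

What the generator does **not** emulate: coalescent gene-tree discordance
(gene-tree error is topological noise, not deep coalescence — the
dissection itself is agnostic to the source of discordance),
site-heterogeneous (CAT-like) generating processes, alignment error, and
paralogy. Passing tests therefore demonstrate that the pipeline recovers
planted signal mixtures of the stated shape, not that any empirical dataset
meets these assumptions.

## Numerical choices and problem sizes

* Branch-length bounds `[1e-8, 10]`; sweep convergence `1e-3` lnL units;
  scalar searches to `1e-5`; endpoint snapping so zero-length branches are
  representable.
* Per-node likelihood rescaling uses column means (any positive magnitude
  proxy works); a non-positive scale aborts with the offending column
  named.
* Pattern compression collapses duplicate columns before any likelihood
  work.
* PCoA Cailliez correction threshold `1e-8`; axes kept while the
  eigenvalue exceeds `1e-8` of the largest.
* The dependency identity and rank-2 property of the deltas are enforced
  as a validity condition of the `GLSTable` class (tolerance `1e-6`).
* Tests and the acceptance script run the full engine at desk scale —
  e.g. 100 loci x 400 columns x 3 topologies for mixture recovery, and a
  60-locus scenario with study-shaped locus lengths for the end-to-end
  summary — sizes chosen so the whole suite completes comfortably on one
  CPU while leaving every stage's statistics well inside their asymptotic
  regimes.

## Known limitations

* The engine is for amino acids only; no codon or nucleotide models.
* No tree search: topologies are inputs, exactly as the dissection
  requires.
* Branch lengths are refit per locus and topology; linked or proportional
  branch models across partitions are not implemented, and gene-wise scores
  computed that way would differ somewhat from ours.
* The conditional-inference tree handles numeric predictors only (the
  panel is numeric); no surrogate splits, so rows missing the chosen
  split variable fall out of deeper nodes.
* Quartet enumeration is O(n^4) in the shared taxon count; fine for tens
  of taxa, not for hundreds.
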