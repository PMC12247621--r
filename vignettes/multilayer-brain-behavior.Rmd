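---
title: "Multilayer community structure of brain-behavior correlation patterns: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilayer community structure of brain-behavior correlation patterns: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiflex)
```

This vignette documents the model, the numerical choices, and the design
decisions behind `multiflex`, in the spirit of a methods section: what the
package computes, under what assumptions, and what its synthetic benchmark
does and does not establish.

## The model

### From connectivity to edgewise brain-behavior correlations

The pipeline starts from per-subject functional connectivity: node × node
Pearson correlation matrices (computed by `pearson_fc()` from parcellated
time series, or supplied precomputed). Matrices are vectorized by
`vectorize_fc()` using one fixed bijection — the strict upper triangle in
row-major order — shared by every module and documented as part of the
file format, so all outputs are reproducible down to column order. With
482 nodes this gives 115,921 edges per subject.

For each behavioral measure and each edge, `spearman_edge_behavior()`
computes the Spearman rank correlation across subjects (average ranks for
ties; a constant column yields 0 with a warning, since the correlation is
undefined). Spearman is used because behavioral scale scores are ordinal
at heart and the statistic is invariant to any monotone rescaling of
either variable — an invariance the test suite asserts directly.

Significance is assessed by `edge_permutation_test()`: the behavior table
rows are shuffled as whole rows, so the inter-measure correlation
structure is preserved and the null is "no subject-level association
between scores and edges". The two-sided exceedance p-value uses the
add-one convention, p = (1 + #{|ρ_perm| ≥ |ρ_obs|})/(n_perm + 1), which
cannot return zero; the difference from dividing the raw count by n_perm
is at most 1/n_perm. Benjamini-Hochberg FDR is applied at q = 0.05,
pooled across all measure × edge tests by default (a per-measure scope is
available); the realized criterion p_crit — the largest rejected p — is
reported alongside the mask. `system_summary()` attributes an edge to a
subsystem when either endpoint carries the label, so an edge can count
toward two subsystems; proportions of significant edges are reported per
(subsystem, measure) with log10 proportions (missing when zero).

### Similarity layers and the multilayer model

Modularity maximization treats all negatively weighted items as one
community, which would misrepresent correlation-valued layers. Each
measure's node × node correlation pattern is therefore transformed by
`correlation_to_similarity()`: entry (i, j) is the Pearson correlation of
rows i and j after deleting positions i and j from both rows. The
self-pair masking is a convention of this package: the diagonal entries
of a correlation pattern are undefined, and the shared pair entry would
otherwise couple the two rows mechanically.

`build_supra()` assembles the (nL) × (nL) supra-modularity matrix: the
diagonal block of layer r is `W_r − γ(11ᵀ − I)` — a *uniform* null model,
under which γ is directly interpretable as a similarity threshold:
communities at resolution γ are groups whose average pairwise similarity
exceeds γ. Off-diagonal blocks are ω·I for every ordered layer pair
(all-to-all categorical coupling), so layers are unordered and every node
is coupled to each of its copies. Negative residual similarities are kept
as-is; they simply discourage co-assignment. Q is not normalized by total
weight: comparisons only ever happen within one supra matrix, so the
scale is immaterial.

`evaluate_q()` scores a partition as the exact sum of supra entries over
ordered same-community pairs (self-pairs excluded). The all-singletons
partition scores 0, which is the natural baseline: the optimizer can
never do worse.

### Maximizing Q

`multilayer_louvain()` implements a generalized Louvain heuristic for
arbitrary (signed) modularity matrices, in compiled code:

* **Greedy phase.** Nodes are visited in an order randomized from R's RNG
  (so `set.seed()` gives bit-reproducible runs). By default the move rule
  is stochastic: among all strictly improving moves (including isolation
  into an empty community) one is chosen uniformly at random. This is the
  move rule that gives restarts their diversity; a deterministic
  best-move rule with lowest-community-id tie-breaking is available
  (`rand_moves = FALSE`). A move must improve Q by more than
  `tol = 1e-10`.
* **Aggregation** collapses communities into super-nodes (self-loops carry
  the internal weight) and the greedy phase repeats.
* **Chunk refinement.** Plain aggregation can only move *whole* multilayer
  communities, so it can never repair a bad cross-layer matching — e.g.
  layer 3's share of community A stuck with community B's copies. After
  each cycle the partition is therefore re-aggregated at the
  (community × layer) chunk level and a deterministic greedy pass lets
  individual chunks switch multilayer communities.
* **Iteration.** The whole cycle restarts from the current labels at the
  original scale until a full cycle no longer improves Q.

`run_restarts()` derives restart seeds as `seed + restart_index`. The
first restart starts from all singletons; the rest start from random
coarse partitions (2–8 communities, each node's copies initialized
identically across layers — aligned initialization diversifies the search
without scrambling cross-layer correspondence). On random 6-node,
2-layer instances, 50 restarts attain the exhaustive-search maximum of Q
(enumeration over all partitions of the 12 node-layer units) in 100/100
instances in our validation; the acceptance suite re-checks ≥ 19/20.

### Consensus

`consensus_partition()` follows the agreement-matrix procedure: build the
co-assignment frequency matrix over node-layer units; zero entries below
the null threshold — the expected co-assignment frequency when every
partition's label vector is independently permuted, which given the
community sizes equals τ = P⁻¹ Σ_p Σ_c n_c(n_c−1)/(N(N−1)) exactly, so no
Monte-Carlo estimate is needed; recluster the thresholded agreement
matrix with the same Louvain engine, the threshold playing the role of
the uniform-null resolution; iterate until the agreement matrix is
binary, then read communities off its connected components. An
extreme-value null (the maximum permuted co-assignment) was rejected
during design: with few large communities its threshold exceeds the
genuine agreement of imperfect but consistent partitions and severs the
cross-layer correspondence the coupling exists to provide. Per round
the reclustering uses at most 12 Louvain runs — enough for a stable
agreement estimate at these problem sizes. A single input partition is
returned unchanged; non-convergence after 50 rounds raises an error
reporting the agreement entropy.

### Flexibility

With all-to-all coupling the layers are unordered, so `compute_flexibility()`
counts community changes over unordered layer pairs: f_i = a_i / t with
t = L(L−1)/2 (21 for seven layers). The layerwise variant
f_ir = #{s ≠ r : σ_ir ≠ σ_is}/(L−1) makes "flexibility of all nodes in
all layers" well-posed for the parameter-space PCA, and the identity
*overall = mean over layers of layerwise* holds algebraically and is
asserted exactly in the tests. An ordered-sequence variant (t = L−1,
consecutive changes) is available via `mode = "ordered"` for layer sets
with a natural order.

### Parameter space

`default_grids()` fixes the sweep: 19 linearly spaced γ from 0 to 0.9
(step 0.05) and 9 logarithmically spaced ω from 10⁻⁴ to 1 (half-decade
steps). `run_grid()` evaluates every point with deterministic per-point
seeds (`seed + 1009 × point index`). Downstream maps:

* `pca_on_flexibility()` — PCA (centered, unscaled columns: flexibilities
  share the [0, 1] scale, so standardization would only inflate
  near-constant units; a standardized variant is a flag) of the
  grid-point × node-layer consensus-flexibility matrix. Component signs
  are fixed by making the largest-|loading| entry positive. Consensus
  (not restart-averaged) flexibility is the default input — the consensus
  is the object carried forward to interpretation.
* `variability_in_flexibility()` — per point, the population SD of each
  node-layer flexibility across restarts, averaged over units. The mean
  of per-unit SDs (rather than a variance of means) is the documented
  aggregation choice.
* `partition_landscape()` — mean pairwise ARI across restarts and mean
  ARI of restarts to consensus, each computed layer by layer and then
  averaged; layer-averaged ARI (not ARI on concatenated labels) is used
  throughout so that a relabeling of one layer cannot masquerade as
  disagreement in another.
* `seed_similarity()` — layer-averaged ARI of every point's consensus to
  a chosen grid point's consensus, or to a static reference labeling
  (e.g. canonical system assignments) replicated across layers.
* `select_analysis_points()` — emits the |PC1|- and |PC2|-maximizing
  points and the variability argmax as a machine-readable table.

`adjusted_rand_index()` implements the standard contingency-table form
and defines ARI = 1 when the chance-correction denominator vanishes with
identical partitions (e.g. two all-singleton partitions), 0 otherwise;
the tests verify it against brute-force pair counting on a thousand
random instances.

### Layer differentiation

`layer_switch_analysis()` computes, per unordered layer pair, the
fraction of nodes changing community, averaged across the supplied
partitions (all restarts by default — the consensus variant is obtained
by passing the consensus). The null shuffles each node's label vector
across layers independently, per partition, and the p-value is the
standard add-one exceedance probability. Raw p-values are reported
alongside BH-adjusted ones; raw is the default for comparability with
threshold-style reporting. `leave_one_layer_out()` recomputes flexibility
without each layer (t rescaled) and reports the Spearman correlation with
the original profile. `system_pattern_correlation()` correlates each
system's switch-proportion vector with the global one and with every
other system's.

`system_flexibility_tests()` uses `stats::kruskal.test` (tie-corrected H)
across systems and directional pairwise permutation tests with the
difference in group medians as statistic — medians because the summary
reported per system is a median; directional because the scientific
question is "is A more flexible than B". All node flexibilities are
shuffled jointly once per permutation, so the 10,000 permutations are
shared coherently across every pairwise comparison.

## The synthetic-data generator

`synth_config()` defaults define the benchmark conditions: 92 subjects
(200 in the recovery benchmark), 60 nodes, 7 measures/layers, 3 planted
communities, 12 flexible nodes, one deliberately distinct layer,
effect size β = 1, noise SD 0.1, FC baselines 0.35 (within-block) and
0.05 (between-block).

* **Behavior.** Scores are multivariate normal, affinely mapped to the
  T-score scale (mean 50, SD 10). Downstream stages are Spearman-based,
  hence invariant to this monotone choice of marginal. The default
  inter-measure correlation has a 3-measure "support" block and a
  4-measure "distress" block, positively correlated within blocks and
  negatively across (0.15 / −0.075).
* **Planted structure.** Non-flexible nodes keep one home community in
  every layer; flexible nodes move to the next community in the distinct
  layer only. A `"cycle"` pattern (labels advancing each layer) is
  available for maximal-flexibility scenarios.
* **Edges.** FC is generated directly at the edge level:
  w_ij = clip(b_ij + (β/L) Σ_k m_ijk z_k + ε), with m_ijk the co-membership
  indicator in layer k, z_k the standardized score, b_ij interpolating the
  baselines by co-membership fraction, and hard clipping to [−1, 1] (the
  clipped fraction is recorded and warned about above 5%). The per-layer
  slope β/L makes β the *total* slope of an everywhere-co-communal edge,
  which keeps the clipped mass near 1% at β = 1. A helper
  (`simulate_timeseries()`) draws Gaussian time series from a target FC
  for exercising the connectivity module; no hemodynamic model is
  attempted.

### Why the default inter-measure correlations are modest

Two facts shape what the generator can promise. First, a measure's
edgewise correlation matrix inherits every correlated measure's planted
pattern: the pattern of measure l leaks into measure k's layer with
weight ρ_kl. Second, an edge co-communal in many layers aggregates many
score signals, so its weight variance is larger and its Spearman
correlation with any *single* measure is diluted by roughly the square
root of that variance. With strong inter-measure correlations
(e.g. 0.5 within-block) the concentrated leakage of the distinct layer
into a correlated measure's layer *exceeds* the diluted own-layer signal,
and the planted per-layer partitions are provably not the modularity
optimum — no optimizer could recover them. The default magnitudes
(0.15 / −0.075) keep the sign structure of a support/distress battery
while keeping every layer's planted partition identifiable; with them,
the truth partition is the Q-optimum at interior grid points across all
validation seeds. This is a deliberate benchmark design choice: the
generator emulates the *statistical shape* of the problem (correlated
ordinal scores, block-structured edge-behavior correlations, a distinct
layer, flexible nodes), not the empirical effect sizes of any particular
sample, which are unknown at edge level anyway.

What passing the synthetic benchmark shows: the pipeline's statistics are
calibrated (null permutation p-values uniform; BH yields essentially no
false discoveries under the null), its optimizer reaches exhaustive
maxima at small scale, and planted structure of realistic shape is
recovered end to end. What it does not show: recovery at empirical
effect sizes, robustness to motion or scanner artifacts, or anything
about the marginal distribution of real FC — all explicitly out of scope
for the generator.

## Numerical choices and degenerate inputs

* Louvain tolerance 1e-10; ties in the deterministic move rule break
  toward the lowest community id; restart seeds are `seed + index`; all
  randomness flows through R's RNG from a single master seed.
* Permutation p-values use the add-one convention and are therefore in
  (0, 1]; `n_perm < 100` is rejected as too coarse.
* Undefined correlations (constant inputs) are recorded as 0 with a
  warning where a neutral value is defensible (edge-behavior ρ,
  similarity), and as `NA` where it is not (leave-one-out correlation,
  constant switch vectors, log10 of a zero proportion).
* `devectorize_fc()` rejects lengths not of the form n(n−1)/2, naming the
  nearest valid n. Parcellation files with 1-based ids are shifted with a
  message; non-contiguous ids are rejected.
* Systems with fewer than 2 nodes are excluded from system tests with a
  warning; a single surviving group is an error.

## Problem sizes used by the test and acceptance suites

The validation suites run at desk scale, chosen as the package's own
benchmark sizes: the recovery benchmark uses 10 generator seeds at
n = 200 subjects, 60 nodes, a reduced 5 × 3 (γ, ω) grid with 16 restarts
per point; the optimizer oracle uses 20 random 6-node 2-layer instances
against exhaustive search; calibration uses 500 null edges with 1000
permutations; the coupling-trend check spans the full 9-point ω grid with
16 restarts. The full 19 × 9 grid with 100 restarts remains the default
for analyses via `run_grid()` and `run_pipeline()`.

## Known limitations

* The uniform null is the only null model (by design); a degree-based
  Newman-Girvan null and ordinal (temporal) coupling topologies are out
  of scope.
* Dense matrix algebra throughout: fine for hundreds of nodes, not
  intended for voxel-level networks.
* The consensus fixed point and its null threshold follow one published
  family of procedures; other consensus schemes can give different
  fine-scale assignments at degenerate grid points.
* Leave-one-layer-out correlations and switch-pattern correlations are
  undefined for constant profiles and reported as missing rather than
  imputed.
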