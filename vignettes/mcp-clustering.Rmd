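---
title: "Clustering expression profiles with multiple-cumulative probabilities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering expression profiles with multiple-cumulative probabilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcpcluster)
```

## The model

An expression time course `x = (x_1, ..., x_n)` is reduced to the
*distribution of expression mass over time points*: after a translational
shift (applied only when some values are negative, as in log-ratio or
background-subtracted data) the profile is normalized to a probability
vector `y`. Two genes are considered to behave alike when their mass
distributions are alike — regardless of the overall expression level, and
regardless of the incidental curve wiggles that dominate flat profiles.

The multiple-cumulative probability (MCP) vector makes this comparable by
correlation. For each of the `n` cyclic rotations of `y`, take the
*modified* cumulative sum, in which position `j` contributes only half of
its own mass:

$$T^{(s)}_j \;=\; \sum_{l<j} z^{(s)}_l + \tfrac{1}{2} z^{(s)}_j,
\qquad z^{(s)} = (y_s, \ldots, y_n, y_1, \ldots, y_{s-1}),$$

and concatenate the `n` blocks into the `n^2`-length vector `T`. Three
properties motivate the construction:

* **Half-mass modification.** A plain cumulative sum always starts "low"
  and ends at exactly 1, so its entries have very different variances and
  the last one is useless. With the half-mass rule every entry lies
  strictly in `(0, 1)` (block `s` starts at `y_s/2` and ends at
  `1 - y_{s-1}/2`), and each position of `y` enters the vector with the
  same total weight.
* **All rotations.** A single cumulative sum privileges the (arbitrary)
  first time point: early positions get superposed into almost every entry,
  late ones into almost none. Summing over all `n` rotations restores the
  symmetry; rotating the input merely rotates the MCP blocks.
* **Scale invariance.** Normalization removes positive scaling entirely:
  `mcp(c * x) == mcp(x)` for any `c > 0` (tested to `1e-12`).

Pearson correlation of MCP vectors (PCC-MCP, dissimilarity `1 - r`) is the
recommended measure; Euclidean distance of MCPs (ED-MCP), raw-profile
correlation (`pcc`) and Euclidean distance of normalized profiles (`ed-n`)
are provided as comparison baselines. For flat noisy profiles the MCP
vectors become nearly identical (all blocks close to the uniform ramp),
which is exactly the regime where raw correlation behaves worst.

## icc-cluster

`icc_cluster()` is k-medoids with a deterministic farthest-first seeding:

1. the pair of genes at maximal dissimilarity seeds centers 1 and 2;
2. every further center (3..k) is the non-center gene maximizing its
   minimum dissimilarity to the already-chosen centers (maximin);
3. genes are assigned to the nearest center; each center is then replaced
   by the medoid of its cluster (the member minimizing the sum of
   dissimilarities to all members);
4. steps 3–4 repeat until the label vector stops changing.

Every tie — the max-distance pair, the maximin candidate, nearest-center
assignment, medoid sums — breaks toward the lowest gene index, so the
algorithm has no randomness at all and reruns are byte-identical. A center
always self-assigns even when a duplicate gene sits at distance zero. The
objective (total dissimilarity to assigned medoids) is recorded per
iteration and is non-increasing; convergence on all test fixtures occurs
well inside the default `max_iter = 100`, and hitting the cap returns the
current solution with `converged = FALSE` and a warning rather than an
error.

`kmeans_baseline()` is the Lloyd-style comparator. The original description
of this comparison leaves the k-means variant open, so the package pins it
down and records it in the output: features are MCP vectors for the `*-mcp`
measures and normalized profiles otherwise; point-to-centroid distance is
squared Euclidean (`ed-*`) or `1 - r` (`pcc-*`); centroids are member
means; seeding is k-means++-style under the supplied seed; an emptied
cluster is reseeded to the farthest point. Comparisons against it are
reproducible, not canonical.

## Map selection

The centered MCP matrix has rank at most `n - 1` (each block of a row sums
to a value determined by one entry of `y`, so the `n^2` columns carry only
`n - 1` degrees of freedom); `pca_mcp()` enforces `k <= n - 1` and the
tests verify the trailing singular values vanish to relative `1e-8`. For
each candidate `k`, the first `k` PC scores ("KC-data") are embedded in 2D
with t-SNE; `k = 1` is defined as embedding the *raw* MCP vectors — a
1-dimensional score matrix is never embedded, which also keeps the raw-MCP
map available as a candidate. Each candidate map is scored by the average
silhouette of the supplied cluster labels on its 2D Euclidean coordinates,

$$S_k = \frac{1}{m}\sum_i \frac{b_i - a_i}{\max(a_i, b_i)},$$

and `select_tsne_mcp_o()` returns all candidates plus the argmax (ties go
to the smallest `k`, the cheaper map). Members of singleton clusters
contribute `s_i = 0`, the usual convention. `average_silhouette(..., diss =
TRUE)` also scores a clustering directly in its own measure space; that
variant is an interpretation knob — silhouettes reported on 2D maps and in
measure space answer different questions and are not interchangeable.

t-SNE itself is delegated to `Rtsne`. Defaults: perplexity 30 (capped in
the pipeline at `(m - 1) / 3` as the implementation requires), 1000
iterations, Barnes-Hut `theta = 0.5`, and *deterministic initialization*
from the first two PC scores scaled to sd `1e-4`. With that init the
embedding is a pure function of the data and parameters — reruns and
row-permuted inputs reproduce the same map (tested via distance matrices at
`theta = 0`) — while `init = "random"` restores seeded stochastic starts.
Silhouette values of t-SNE maps should still be read as map-specific:
different environments' BLAS/compiler details can nudge coordinates, which
is why the package's tests assert separation properties rather than exact
silhouette values for embeddings.

## The simulated benchmark

`simulate_dataset1()` draws 2000 genes at five time points in four
500-gene groups from independent normals `N(mean, sd)`:

| time | A       | B          | C         | D        |
|------|---------|------------|-----------|----------|
| 1    | N(10,2) | N(10,2)    | N(100,10) | N(10,2)  |
| 2    | N(10,2) | N(0.5,0.1) | N(60,6)   | N(30,3)  |
| 3    | N(10,2) | N(0.5,0.1) | N(60,6)   | N(10,2)  |
| 4    | N(10,2) | N(0.5,0.1) | N(60,6)   | N(60,6)  |
| 5    | N(10,2) | N(30,3)    | N(100,10) | N(10,2)  |

The second parameter
is read as a standard deviation, not a variance: the spreads then scale
linearly with the means (`N(100,10)`, `N(60,6)`, `N(30,3)`, `N(0.5,0.1)`),
i.e. roughly constant coefficient of variation, the natural design for
intensity-like data. Group A is the diagnostic: five i.i.d. draws around a
common level produce statistically equivalent values with arbitrary curve
shapes, the case that defeats raw-correlation clustering. What the
generator does *not* emulate: heavy-tailed intensity noise,
gene–gene correlation, batch structure, or count sampling (SAGE-like data
are Poisson); passing tests on it demonstrate the shape-robustness
mechanism, not performance on any particular platform's noise.

`simulate_blobs()` is the auxiliary fixture generator: `k` groups share a
common positive base profile, group means are `base + separation *
direction_g`, members add `N(0, noise_sd)` noise. `separation = 0` makes
the groups indistinguishable by construction; `separation >> noise_sd`
makes recovery trivial, which is what the exact-recovery clustering tests
use.

## Numerical choices and degeneracies

* Normalization rejects profiles whose shifted total is below `1e-12`,
  naming the offending gene(s).
* Probability-vector preconditions are checked to `1e-9`; MCP block
  identities and silhouette oracles are asserted to the same tolerance.
* Raw-profile correlation of a constant gene is undefined: `pcc()` returns
  0 with a warning (MCP vectors of valid profiles are never constant, so
  this only affects the baseline measure); `pairwise_dissimilarity(...,
  "pcc")` refuses constant genes by name instead, since silently zeroing a
  whole row would distort the matrix.
* Dissimilarity matrices are symmetrized (`(d + t(d))/2`), clamped at 0,
  and given an exact zero diagonal to absorb floating-point asymmetry.
* Gene order is never reordered: dissimilarities, labels, scores and map
  coordinates all follow input row order.
* The candidate sweep for map selection defaults to `1..n-1`, evenly
  thinned to at most 30 candidates for long time courses.

## Problem sizes in the test suite

The full 2000 × 5 benchmark is used for the clustering replication (a few
seconds: the bottleneck is one `2000^2` correlation). Embedding checks run
on a 120-per-group subsample (480 genes, four t-SNE runs) and on 30–100
point fixtures — sizes chosen so the whole suite exercises every stage in
well under a minute while keeping the separation margins far from the
assertion thresholds.

## Known limitations

* MCPs compare distributions of mass over time points; they deliberately
  discard absolute level and positive scale. Analyses where amplitude
  matters should use the Euclidean baselines or a different measure.
* The lowest-index tie rules make results deterministic but arbitrary at
  exact ties; other implementations of the same algorithm may differ at tie
  boundaries.
* t-SNE maps are for visual structure; their silhouette ranks candidate
  maps for the *given* labels and is not a clustering-quality statistic.
* No probe-level preprocessing (present calls, per-chip normalization,
  fold-change filtering) is included: inputs are assumed to be
  already-filtered gene-by-sample matrices.
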