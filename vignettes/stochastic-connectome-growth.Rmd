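---
title: "Stochastic generative growth of brain networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic generative growth of brain networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The generative model

`stochnet` grows binary, undirected brain networks one connection at a time.
Starting from a fixed seed scaffold, at every step the probability of wiring
the unconnected node pair $(i, j)$ is

$$ p_{ij} \;\propto\; d_{ij}^{\,\eta}\,\bigl(m_{ij} + \epsilon\bigr)^{\gamma}, $$

where $d_{ij}$ is the Euclidean distance between the two regions' centroids
(the *cost* of the connection) and $m_{ij}$ is the matching index — the
normalized overlap of the two nodes' neighborhoods, with each node excluded
from the other's neighbor set (the *value* of the connection, a homophily
term). One pair is sampled per step, the matching matrix is updated, and
growth stops at a fixed edge count. Because each step is a random draw, the
model is intrinsically stochastic: identical parameters can yield different
networks (multifinality), and different parameters can yield similar ones
(equifinality). The package quantifies both, along with the downstream
consequences for sensitivity to developmental noise and robustness to attack.

## Parameters and conventions

* **$\eta$ (dimensionless exponent, default sweep $[-4, 0]$).** Negative
  values penalize long connections; $\eta = 0$ disables the distance factor.
  The exponent is applied to distances in whatever unit the geometry uses
  (mm for the packaged atlas).
* **$\gamma$ (dimensionless exponent, default sweep $[0, 1]$).** Positive
  values favor pairs with overlapping neighborhoods; $\gamma = 0$ disables
  the homophily factor.
* **$\epsilon = 10^{-6}$.** Additive offset inside $(m + \epsilon)^\gamma$.
  Without it, any pair with zero matching would be permanently unreachable
  whenever $\gamma > 0$; the offset keeps all pairs reachable while leaving
  the preference ordering intact. This matches common implementations of
  this model family.
* **$0^0 = 1$.** A zero exponent always disables its factor, including at
  zero distance or zero matching.
* **Stop criterion.** The reference protocol grows networks to 400 edges on
  116 nodes. Under the directed-pair denominator $E / (n(n-1))$ this is a 3%
  density; under the standard undirected convention $2E / (n(n-1))$, the
  ~668-edge cohort protocol is a 10% density. Both conventions appear in
  descriptions of the same protocols, so `edgeDensity()` exposes both and
  none is silently preferred.
* **Noise windows.** A window $(a, b)$, in fractions of the final edge count
  (seed included), during which edges are drawn uniformly among eligible
  pairs instead of from $p_{ij}$. The canonical timings are early
  (0.05–0.10), middle (0.475–0.525) and late (0.90–0.95), i.e. a 5%-of-edges
  burst of pure randomness.
* **Seeds.** Every stochastic operation takes an explicit RNG seed; sweep
  archives derive per-run seeds from the master seed and the cell/repetition
  indices and record them in the manifest, so an archive is bit-reproducible.

## The seed network

Simulations start from a fully connected five-node medio-posterior scaffold
(bilateral lingual, left precuneus, left middle occipital, right fusiform; 10
edges = 2.5% of a 400-edge network). `seed_builder` reconstructs such a
scaffold from a cohort: edges present in at least 70% of subjects form the
consensus network; the rich-club coefficient
$\phi(k) = 2E_{>k} / (N_{>k}(N_{>k}-1))$ is calibrated against
degree-preserving rewired nulls (50 swaps per edge, 1000 nulls) giving
$\phi_{norm}(k)$ and a one-sided permutation $p$; the seed is the induced
subgraph of the selected significant level, re-embedded into the target
geometry by node label.

**Level selection.** Among significant levels ($\phi_{norm} > 1$,
$p < \alpha$), the package picks the *highest* $k$ whose induced subgraph has
at most `max_edges` (default 20) edges. A minimal scaffold should be small —
a level with a hundred-plus edges is not a seed but half a network — and the
highest admissible level is the most exclusive hub set. The permutation $p$
is reported both as plain rank/`n_nulls` and with +1 smoothing; the plain
rank form is used for significance, floored at $1/\mathrm{n\_nulls}$.

# Dissimilarity statistics (multifinality)

For every grid cell, `reps` repeated runs are summarized two ways:

* **Topological dissimilarity.** Each run's five-metric profile — mean nodal
  clustering, mean nodal betweenness, total Euclidean edge length, global
  efficiency, Louvain modularity $Q$ — is min–max rescaled per metric, and
  the scalar is the sum of the full pairwise Euclidean distance matrix in
  that 5-D space (off-diagonal entries counted twice; the upper-triangle sum
  is also reported and is exactly half).
* **Embedding dissimilarity.** The mean over run pairs of the fraction of
  non-overlapping connections, $1 - |E_a \cap E_b| / m$.

**Normalization scope.** In a landscape the min–max context is *global* —
all runs of all cells — because per-cell normalization erases between-cell
magnitude differences: every cell's cloud would be stretched to fill the unit
box and the landscape flattens (we verified this empirically; the per-cell
variant has essentially no relation to either exponent). When
`topologicalDissimilarity()` is called on a standalone profile set, that set
is its own context. The choice is recorded in every archive manifest.

Zero-range metric columns (e.g. modularity in an archive of identical
networks) contribute zero and are flagged rather than propagating 0/0.

**Conventions.** "Mean clustering" is the mean of nodal clustering
coefficients (zero for degree < 2 nodes), not transitivity. Betweenness is
unnormalized nodal betweenness on the binary graph. Modularity is the $Q$ of
a Louvain partition run with a fixed, recorded RNG seed; it is the one
profile entry that is deterministic only given that seed, and it may change
under node relabeling (community detection is label-order sensitive), which
is why the permutation-invariance property covers the other four metrics.

## What the reduced protocol shows

The reference protocol is a 25 × 25 grid with 625 repetitions (390,625 runs
per protocol, a cluster-scale computation). The package's reduced protocol —
13 × 13 grid, 30 repetitions, 400 edges, the packaged geometry — reproduces
the dissociation structure at desk scale and is what the acceptance script
and tests run; all problem sizes below are the package's own defaults for
desk use. On this protocol, $\gamma$ explains the large majority of variance
in topological dissimilarity and almost none in embedding dissimilarity,
while $\eta$ does the reverse.

**Direction of the $\gamma$–dissimilarity relation.** In this
implementation, summed topological dissimilarity *increases* with $\gamma$:
strong homophily amplifies early random differences (which cluster seeds the
runaway neighborhood overlap differs from run to run), whereas near-random
growth concentrates the global metrics by averaging. Correspondingly, cells
with higher repeated-run dissimilarity are *more* confusable to the pairwise
classifier here, so the regression of mean misclassification on topological
dissimilarity has a positive slope, with the variance explained in the same
range as the reference analysis. Accounts of this model family differ on the
sign of these relations while agreeing on the variance decomposition; the
package reports the slope alongside $R^2$ so users can see the direction in
their own data rather than trusting a narrative.

# Noise-injection experiment

`noiseExperiment()` runs a baseline sweep and one sweep per timing with the
same grid, repetition counts *and per-run seeds* (common random numbers): a
noise-condition run replays its baseline trajectory edge for edge until the
window opens, so the per-cell change score (noise minus matched baseline)
isolates the effect of the injected randomness instead of being dominated by
re-simulation noise — at desk-scale repetition counts this matters; with
fresh seeds the Monte-Carlo error of the deltas swamps the timing effect.
A degenerate zero-width window is then exactly a no-op. Change scores are
the default because raw full-matrix sums are dominated by between-cell
baseline differences; raw scores are available behind a flag. The one-way
ANOVA across timings uses the per-cell deltas, giving df = (2, 3·cells − 3).
At the reduced scale (5 × 5 grid, 30 reps) the double dissociation is
reproduced: late noise raises topological dissimilarity more than early
noise, early noise raises embedding dissimilarity more than late noise.

# Attack robustness

Communicability $C = \sum_{ij} (e^A)_{ij}$ is the benchmark capacity
measure; it is at least $n$ for any binary network, so $\ln C$ is always
defined. In the targeted regime nodes are ranked once by intact-network
degree (ties broken by ascending index, for determinism) and removed in that
order by zeroing their connectivity; the random regime uses a seeded uniform
permutation (25 repetitions per network by default). Robustness is the OLS
slope $\beta$ of $\ln C$ against the number of removed nodes over the first
25% of nodes (29 of 116), including the intact-network point (step 0; the fit
window is configurable). Removal keeps the matrix full-size; computationally
the exponential is taken over the remaining submatrix and each removed node
contributes $e^0 = 1$ to the diagonal sum, which is exact.

# Equifinality (pairwise SVM)

For every unordered pair of grid cells a soft-margin SVM with linear kernel
and cost 1 is trained to distinguish the two cells' runs, using 10-fold
stratified cross-validation with features standardized by training-fold
statistics only; the misclassification rate pools errors over folds (the
per-fold mean is available behind a flag, and differs only at non-divisible
sample sizes). Kernel, cost and standardization are recorded in the output
manifest since the reference analysis names none of them. Features are
either the five-metric topology profiles or, in embedding mode, the
vectorized upper-triangle edge indicators. Note that in embedding mode the
classifier is close to perfect here: different exponent combinations place
edges in systematically different locations, and a linear SVM separates even
a few dozen samples in that high-dimensional binary space, so embedding
misclassification rates come out near zero rather than near chance.

# Parameter fitting

The fit energy between an observed and a simulated network is the maximum of
the four two-sample Kolmogorov–Smirnov statistics over the distributions of
nodal degree, nodal clustering, nodal betweenness and edge Euclidean length —
the standard fit measure of this model family, isolated in `ksEnergy()` so
alternatives can be swapped in.

Cohort fitting uses shared seeded landscapes: each landscape simulates every
grid cell once up to the largest edge count in the cohort, keeping the full
edge-formation order; a subject is fitted by truncating each cell's order at
the subject's own edge count (subjects are fitted at their empirical edge
counts, not at a common density) and choosing the cell with minimal energy;
the estimate is the mean best $(\eta, \gamma)$ over landscapes (reference
default: 50 landscapes; the desk-scale tests use 5–6 on a 9 × 9 grid, which
already gives Spearman rank recovery of $\eta$ above 0.9 on synthetic
cohorts). This is a deliberately simplified landscape-fitting scheme — one
shared simulation table, truncation by edge count — rather than a
reimplementation of any specific published pipeline.

Group statistics: median split on the deprivation score (ties at the median
go to the high-SES group, i.e. strictly-greater scores are "low SES"),
Student's pooled-variance two-sample t (Welch behind a flag), pooled-SD
Cohen's d signed as mean(high) − mean(low), and a permutation test of the
absolute mean difference under 1000 random relabelings, reported both as
plain rank $p$ and with +1 smoothing.

# Synthetic data

Two generators make the whole pipeline runnable without restricted imaging
data; both are pure functions of their seeds.

* **Neonatal-like cohort.** Plants a five-node core that is fully
  interconnected in 90% of subjects and acts as equal-degree hubs via
  consistent periphery attachments, on top of a population-level background
  graph retained per subject with probability 0.9, plus 1% independent edge
  flips. The hierarchical background is deliberate: fully independent
  per-subject background would be annihilated by a 70% consensus, leaving a
  bare clique whose degree-preserving nulls are fixed points (the rich club
  could never be significant). Equal core degrees make the highest defined
  rich-club level isolate exactly the planted core, which is what the
  recovery test asserts.
* **Child cohort.** Each subject's network is grown by the generative model
  itself with known $(\eta, \gamma)$; $|\eta|$ differs between two groups by
  a configurable effect (default 0.8 pooled SDs), edge counts are drawn at a
  10%-density scale (mean 668, SD 44), and the deprivation score is a noisy
  monotone transform of *group membership* (gap 2.4, SD 1) rather than of
  $\eta$ itself — the pipeline, not the generator, has to detect the planted
  effect, including the label noise a median split introduces. With n = 40
  (20 per group) a 0.8-SD effect puts a two-sided 0.05-level test at roughly
  70% power *before* attenuation from fitting error and split
  misclassification, so individual cohort replicates are expected to miss
  occasionally; the tests use fixed seeds so the outcome is reproducible.

What the generators do **not** emulate: tractography biases and distance-
dependent false positives/negatives, weighted streamline counts (thresholding
is emulated only as binary support), hemispheric asymmetries, subject-level
geometry variation, or any longitudinal structure. Passing tests therefore
demonstrate that the pipeline recovers structure the model family can
express, not that it is robust to real-world acquisition artifacts.

The packaged 116-node geometry is itself synthetic: bilaterally mirrored,
hand-placed approximate centroids at mm scale with conventional region
labels (file `atlas116_centroids_synthetic.csv`). It provides realistic
distance structure without shipping third-party atlas data.

# Numerical and degenerate-input choices

* Matching 0/0 (empty neighborhood union) is defined as 0.
* Empty graphs yield an all-zero topology profile ($Q = 0$) rather than NAs.
* The sampler draws one uniform variate per added edge and walks the
  cumulative weights in column-major upper-triangle order; the C++
  implementation is verified edge-for-edge against a from-scratch R
  reference for several $(\eta, \gamma)$ settings and seeds.
* `rewiredNull()` skips infeasible swaps, so the degree sequence is
  preserved exactly; complete graphs are fixed points.
* Negative $\eta$ with coincident node coordinates (zero distance) is
  rejected rather than producing infinite weights.
* Nodal statistics in the fitting hot path are computed in C++ (Brandes
  betweenness, triangle clustering) and are tested to agree with igraph to
  1e-9; `topologyProfile()` itself uses igraph.

# Limitations

Binary undirected networks only; a single homophily wiring rule (matching
index) with spatially homogeneous exponents; landscape fitting estimates are
quantized to the sweep grid; Louvain modularity depends on its recorded seed;
and the communicability-based robustness analysis assumes degree is the
attack-ranking measure. Weighted growth models, alternative wiring rules and
regionally varying parameters are out of scope.
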