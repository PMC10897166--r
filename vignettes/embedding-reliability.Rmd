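---
title: "Diagnosing and optimizing 2D single-cell embeddings"
author: "scEmbedQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing and optimizing 2D single-cell embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

t-SNE and UMAP are the standard ways to look at single-cell expression
data, but the 2D pictures they draw are not faithful maps. Depending on
the hyperparameters (perplexity for t-SNE; `n.neighbors` and `min.dist`
for UMAP), a visualization can split one cell population into spurious
islands, or place unrelated populations side by side. Users typically
judge such plots by eye. scEmbedQC replaces that judgment with a
per-cell statistic and a permutation null.

# The reliability score

The input is a genes $\times$ cells matrix $X$ (normalized and
log-transformed at the user's discretion -- the package performs no
normalization), or alternatively any cells $\times$ d coordinate matrix
serving as the *pre-embedding space* (top-$K$ principal components in a
typical pipeline; independent components or CyTOF markers work the same
way).

For each cell $i$, with $n$ cells total and similarity percent $x$
(default 50), let $m = \mathrm{round}(x/100 \cdot n)$, clamped to
$[2, n-1]$. Two ordered neighbor lists are formed by Euclidean distance:
the $m$ nearest cells in the pre-embedding space, and the $m$ nearest
cells in the 2D embedding, each ordered closest to farthest in its own
space, ties broken by cell index. **Both** distance vectors are then
measured in the 2D-embedding space: $v_{\mathrm{pre}}$ holds cell $i$'s
2D distances to its pre-embedding-ordered neighbors, and
$v_{\mathrm{emb}}$ its 2D distances to its 2D-ordered neighbors (a
non-decreasing vector by construction). The reliability score is

$$ r_i = \mathrm{cor}(v_{\mathrm{pre}}, v_{\mathrm{emb}}) $$

(Pearson, so the actual 2D distances matter, not just ranks). $r_i = 1$
when the embedding preserves cell $i$'s neighbor order out to its
mid-range neighborhood; low or negative $r_i$ means the 2D picture puts
the wrong cells near $i$. If either vector has zero variance (perfectly
equidistant neighbors), $r_i$ is undefined and the cell is labeled
`undefined` rather than silently scored -- scoring it 0 would bias the
dubious count.

# The permutation null

To decide what a "low" score is, every gene's values are permuted
independently across cells (`permuteGenes()`). This keeps each gene's
marginal distribution but destroys all cell--cell relationships, so
cells become exchangeable and their neighbors random. The identical
pipeline is then re-run on the permuted matrix -- including an
independent PCA fit when the pre-embedding is PCA; original loadings are
never reused -- with the same embedding method, setting and seed. The
$n$ resulting scores form the null distribution. A cell's embedding is

* **dubious** if its score $\le$ the 5th percentile of the null,
* **trustworthy** if its score $\ge$ the 95th percentile,
* **intermediate** otherwise.

Percentiles use linear interpolation between order statistics (the
common default in both major ecosystems; a nearest-rank option is
provided -- the difference vanishes at realistic $n$). The fractions
flagged are *not* pinned at 5%: on well-structured data far more than 5%
of cells are trustworthy and far fewer than 5% dubious, because the
cutoffs come from the null, not from the observed scores.

# Hyperparameter optimization

`gridSearch()` evaluates a candidate grid and picks the setting
minimizing the number of dubious embeddings. Default candidates follow
common practice for the two methods: perplexity
$\{20, 50, \ldots, 380, 410, 450, 500, \ldots, 750, 800\}$ (filtered to
the feasible $\mathrm{perplexity} < (n-1)/3$); `n.neighbors`
$\{5, 6, \ldots, 30, 35, 40, 45, 50\}$ and `min.dist`
$\{0.0125, 0.05, 0.1, 0.2, \ldots, 0.8\}$. UMAP's two hyperparameters
can be swept jointly (Cartesian product) or marginally (one varied, the
other anchored at the user's original value, falling back to the backend
defaults). Ties at the minimum are broken toward the *smallest*
hyperparameter value -- loss-based selectors are known to drift toward
the largest candidate perplexity, and the tie rule avoids building that
bias in; all minimizers are reported. The permutation is drawn once per
search (it does not depend on the setting) and the permuted data are
re-embedded per candidate setting.

`kneedleElbow()` offers the elbow-point alternative for 1D sweeps: both
axes min--max normalized, the elbow is the value maximizing the vertical
gap between the chord and the curve. A flat or linear curve has no knee
and returns `NA` with a warning; the procedure is intentionally applied
only to one-dimensional sweeps.

# Evaluation metrics

`knnPreservation()` (local structure): the mean fraction of each cell's
$K = 10$ pre-embedding nearest neighbors retained among its $K = 10$ 2D
nearest neighbors; expectation $K/(n-1)$ for an unrelated embedding.
`kncPreservation()` (global structure): the same overlap computed on the
$K = 4$ nearest *cluster centers*, with centers defined as per-dimension
medians for robustness to outliers, and the proportion averaged over
cells. The cell's own cluster counts as a candidate center by default
(its center is a legitimate nearest center; an exclusion flag is
provided). Note that per-dimension medians commute with translations and
axis reflections but not with arbitrary rotations, so KNC is exactly
invariant under the former and only approximately invariant (to ~1% in
our checks) under the latter; KNN is exactly invariant under all rigid
motions. `jaccardIndex()` compares dubious-cell sets, with
$J(\emptyset, \emptyset) = 1$ by convention.

# Choices that matter

**Embedding backends and determinism.** t-SNE is delegated to
Barnes--Hut `Rtsne` (PCA pre-reduction disabled: the supplied
pre-embedding is embedded as-is) and UMAP to `uwot`, both pinned to one
thread under a fixed seed (default 100), which makes every pipeline
stage bit-reproducible. Coordinates are used exactly as produced:
reliability scores are invariant to rotation, translation and
reflection of the 2D space, but not to anisotropic rescaling, so the
package never rescales. A `passthrough` embedder returns the first two
pre-embedding dimensions, giving the exact identity case ($r_i \equiv
1$ on a 2D pre-embedding) used throughout the tests.

**The pre-embedding dimension must exceed 2 for a meaningful null.**
This is easy to miss: with $K = 2$ principal components the permuted
data's pre-embedding is itself 2D, a modern embedder reproduces it
nearly isometrically, and the null scores pile up near 1 -- the null
degenerates and flags genuinely good embeddings. We therefore analyze
the simulation fixtures at $K = 12$, a typical pipeline choice that
gives the permuted data room to be scrambled by the 2D projection. With
user-supplied pre-embeddings the same advice applies.

**PCA conventions.** Genes are centered, not scaled, by default (most
pipelines scale upstream if at all); both flags are exposed.
Zero-variance genes are dropped with a warning when scaling. Component
signs are fixed (largest-magnitude loading positive) for
reproducibility; scores depend only on distances and are unaffected.

**Rounding and ties.** $m$ uses half-up rounding (documented because
R's `round()` is half-to-even: at $n = 7, x = 50$, $m = 4$). All
nearest-neighbor ties break by ascending cell index, and nearest-center
ties by cluster identifier, so results are machine-independent.

# The synthetic fixture

`simulateClusters()` generates the ground-truth data used by the test
suite: $k$ cluster mean vectors placed along random orthonormal
directions in gene space so that every pair of means is exactly
`separation` $\times$ `noiseSd` apart, plus i.i.d. Gaussian noise per
gene. `separation` is thus interpretable in within-cluster standard
deviations: 0 gives indistinguishable clusters (PC-space silhouette
$\approx$ 0), 8 gives cleanly separable ones (silhouette $> 0.7$ on the
top two PCs). A `model = "nb"` variant draws log1p negative-binomial
counts for a more count-like marginal, but the Gaussian model is the
tested surface: the reliability statistic consumes only distances, and
Gaussian noise keeps `separation` interpretable.

What the fixture does *not* emulate: library-size variation, dropout,
gene--gene correlation within clusters, continuous trajectories, batch
effects. Passing tests on it show the statistic, null and optimizer
behave as designed on separable cluster structure; they do not certify
behavior on trajectory-shaped or batch-confounded real data.

**Study conditions used in the deep tests** (chosen once, at a scale a
single CPU handles comfortably): $n = 600$ cells, 1000 genes, 3 equal
clusters, `separation` 8, $K = 12$, default grids (6 feasible
perplexities at this $n$; UMAP swept marginally in `n.neighbors` with
`min.dist` anchored at 0.1, matching how such simulations are usually
optimized). At these conditions the optimizer drives the dubious count
to 0 for both methods. The similarity-percent sensitivity check uses an
*overlapping* fixture (`separation` 3) at a suboptimal perplexity so
dubious sets are non-empty: dubious sets at $x = 40, 50, 60$ agree
pairwise (Jaccard $> 0.5$) while $x = 5$ disagrees with $x = 50$,
reproducing the known instability of very small similarity percents.

# Known limitations

* The score examines mid-range neighborhoods; at very small $x$ it
  degenerates toward "everything is trustworthy", at $x$ near 100 it
  penalizes any global compression. The default $x = 50$ is the
  recommended operating point.
* One permutation per run (exposed seed): the null is an $n$-point
  sample, so the 5th/95th percentiles carry sampling noise of order
  $1/\sqrt{n}$; at typical single-cell $n$ this is negligible.
* A full joint UMAP sweep costs |`n.neighbors`| $\times$ |`min.dist`|
  pipeline evaluations (300 by default); settings are independent and
  may be evaluated concurrently by the user, but the package itself
  runs them serially.
* Scores compare the embedding against the pre-embedding space, not
  against biology: a distorted PCA distorts the reference too.

# A worked run

```{r, eval = FALSE}
library(scEmbedQC)

sim <- simulateClusters(nCells = 600, nGenes = 1000, kClusters = 3,
                        separation = 8, seed = 1)
r <- scoreEmbedding(sim$matrix, tsneSetting(perplexity = 30), numPCs = 12)
r                       # label counts and null cutoffs
opt <- gridSearch(sim$matrix, defaultGrid("tsne", n = 600), numPCs = 12)
gridResults(opt)        # dubious count per perplexity
bestSetting(opt)
```
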