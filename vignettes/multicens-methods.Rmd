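---
title: "Hierarchical multilayer centrality: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical multilayer centrality: model, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multicens)
```

## The model

A multi-tissue system is represented as an undirected weighted multilayer
network: `L` layers (tissues), the same ordered set of `n` nodes (genes) in
every layer, and arbitrary weighted edges both within and across layers.
Everything lives in one supra-adjacency matrix `M` of dimension `N × N`,
`N = n·L`, with supra-index `(α − 1)·n + i` for node `i` in layer `α`.
`decompose_supra()` splits `M = A + C`: `A` holds the `L` diagonal blocks
(intra-layer edges), `C` the off-diagonal blocks (inter-layer edges). The
network is undirected, so `M`, `A`, `C` are symmetric; weights are
nonnegative and the diagonal is zero.

The centrality family consists of damped linear fixed points with restart
probability `1 − p` (see `?query_set_centrality` for the five systems).
Two structural facts make the family useful:

* **Convergence.** After normalization the spectral radius of every
  operator is at most 1, so with `p < 1` each iteration is a convergent
  geometric series. This holds for the full operator `A + C`, for the
  block-diagonal `A`, and for any column-masked `A[i]` (a sub-matrix of a
  nonnegative matrix with unit spectral bound).
* **Decomposability.** The systems are linear in their forcing vectors and
  the masked operators are additive over layers, so per-layer local
  centralities sum to local centrality, layer-specific centralities sum to
  global centrality, set centralities over any partition of a layer sum to
  that layer's centrality, and `l + g = (L + 1)·x` with `x` the PageRank
  versatility. The test suite verifies each identity to `1e-8` on random
  instances; they are exact in exact arithmetic.

## Why the solvers use the transition (column-stochastic) orientation

The systems are written as `x = p·W·x + b` over a normalized `W` derived
from `A + C`. There are two possible orientations for `W`:

* **smoothing**: row-normalize `A + C` and multiply as written, so every
  node averages its *neighbors'* scores;
* **random walk**: use the transition matrix (for our symmetric input, the
  transpose of the row-normalized matrix), so every node accumulates the
  score mass its neighbors *send* it, each neighbor splitting its mass in
  proportion to edge weights — the PageRank convention.

The smoothing orientation is degenerate for this family: a row-stochastic
`W` satisfies `W·(1/N)·1 = (1/N)·1`, so the uniform vector is the *exact*
versatility fixed point (every node would be equally versatile), and by the
same argument `l + g` is exactly constant, collapsing global centrality
into an affine flip of local centrality. The random-walk orientation has
none of these degeneracies, leaves every convergence and decomposability
property intact (a matrix and its transpose have the same spectrum), and
matches the transition-matrix interpretation under which the walk-based
RWR-H baseline is defined. `row_normalize()` therefore presents
row-stochastic `A` and `C` (a convenient, testable invariant: positive rows
of `A + C` sum to 1, rows of isolated nodes stay zero), and every solver
applies the transposed operators.

Zero-degree supra-nodes keep all-zero rows and columns: they receive only
the restart mass and send nothing, and convergence is unaffected since the
spectral radius only drops.

## Parameters that matter

* **`p` (damping, default 0.85)** — the probability of continuing the walk
  rather than restarting at the forcing indicator. Higher `p` integrates
  longer paths (more multi-hop context, slower convergence); `p = 0`
  returns the forcing vector itself. 0.85 is the classic PageRank default
  and is used everywhere unless overridden; all identity checks in the
  suite are run at several values of `p`.
* **`tol` (default `1e-10`) and `max_iter` (default 1000)** — `tol` is
  enforced as a bound on the distance to the fixed point, not on the raw
  iterate change: the iteration contracts with factor at most `p`, so the
  solver stops when the change is below `0.1·tol·min(1, (1−p)/p)`. Inner
  local solves inside global/layer-specific/query-set centrality run at
  `tol/100`, because their error enters the outer forcing term and is
  amplified by up to `p/(1−p)`. With these choices the iterative solutions
  agree with dense direct solves to better than `1e-8` relative
  L-infinity error at the defaults.
* **`lambda` (RWR-H, default 0.5)** — probability of jumping across layers
  at each step of the heterogeneous random walk.
* **Ranking ties** — rankings sort scores descending and break ties by node
  identifier, lexicographically, so results are stable across runs and
  platforms.

## The synthetic benchmark: what it emulates

`generate_synthetic()` reproduces a two-layer hormonal-signaling
caricature: hormone-responsive genes (the *query set*, layer 2),
hormone-producing genes directly coexpressed with them (*source set 1*,
layer 1), second-order mediators connected only through source set 1
(*source set 2*, layer 1), and unrelated dense gene clusters (three
*background communities*, layer 1; model 2 adds a distractor community in
layer 2 connected to the query set). Defaults are the stated study design:
500 nodes per layer, base edge probability 0.05, communities of 50,
connection strength swept from 0.05 to 1, pairs hit by both the base and
the planted process get weight 2. The desk-scale acceptance configuration
(200 nodes per layer, communities of 30, recall-at-60) preserves all
ratios except that planted communities cover 75% of layer 1 instead of
50%, which makes the background competition relatively harsher.

Ground truth mixes the two source sets: fraction `x` drawn from source set
2, the rest from source set 1. At `x = 0` any query-aware method (query-set
centrality, query-restricted inter-layer degree, RWR-H) recovers the truth;
as `x → 1` only measures that combine query focus with multi-hop
propagation keep finding it — the separation the benchmark exists to show.

Two deliberate choices: community membership uses contiguous index blocks
(reproducible without consuming random draws), and all three background
communities sit in the source layer, the conservative placement that
maximizes competition against the source sets. The benchmark protocol
restricts inter-layer degree *and* versatility to cross-layer edges
incident to the query set (`restrict_interlayer()`), so all compared
methods see the same cross-layer signal; without that restriction a
source-set-1 node's expected planted degree, `(3·cs − 1)·s`, exactly ties a
background node's, and versatility cannot separate them even at full
strength.

What a green benchmark does **not** establish: the generator is an
Erdos-Renyi construction with homogeneous communities — no degree
heterogeneity, no weight structure beyond {1, 2}, no correlation noise —
so it validates the *relative* behavior of the measures, not absolute
performance on coexpression data. One honest observation from our runs: at
both desk and full scale, RWR-H's recall on two-hop truth is close to (and
at moderate strengths above) query-set centrality's; the decisive
advantages of query-set centrality are its layer/set decomposability and
its margin over the degree- and versatility-style baselines.

## Network inference

`spearman_multilayer()` builds a complete weighted graph per tissue pair:
within-layer weights are `|Spearman rho|` over all of that tissue's
samples, cross-layer weights `|rho|` over the subjects the two tissues
share (at least 3 required; correlations of constant profiles are recorded
as 0 and counted in a message). Rank-based weights make the network
invariant to monotone transforms of expression. No pruning is applied by
default (`prune_below` is off); the graph stays complete. Standard
pre-steps are provided, not imposed: `top_variance_genes()` caps network
size (take each tissue's top-k by variance, use the union),
`adjust_covariates()` removes linear confounders per gene and restores
gene means, `augment_with_ppi()` adds one unit of weight to within-layer
pairs with physical-interaction evidence. The planted-module expression
generator (`generate_fixture_expression()`) shares one latent factor per
subject across tissues, giving module genes pairwise correlation `rho`
within and across tissues; it emulates a coexpression module, not library
size, batch, or count noise.

## Evaluation utilities

`recall_at_k()`/`auc_recall()` normalize the area under the recall curve so
an ideal ranking scores exactly 1 and a uniformly random ranking about 0.5.
`stratified_random_sets()` draws null gene sets matching a target's
composition over low/medium/high variance strata (33rd/66th percentile
cut-offs, boundaries to the lower stratum). `delta_ranks()` gives signed
positional differences between two rankings. `cooccurrence_support()` is
the observed-over-expected co-mention ratio
`joint/(H·G)·corpus` (corpus default 27 million), read directly as
"co-mentioned `support`-times more often than independence predicts", with
1 the conventional evidence threshold; `embedding_cosine()` supplies the
complementary contextual-similarity score.

## Known limitations

* Dense base-R matrices throughout: comfortable to `N` in the low
  thousands, not engineered for genome-scale `N` beyond ~10⁴.
* Undirected networks only; no multiplex coupling edges are auto-added.
* The evaluation universe for set-queries defaults to the target layer's
  nodes; hormone-style workflows that exclude the query set itself should
  pass `exclude_nodes` explicitly.
* Literature support consumes pre-computed article counts and embedding
  vectors; the package performs no corpus mining.
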