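# multicens

Hierarchical centrality measures for weighted multilayer networks, built to
find the molecular mediators of tissue–tissue communication.

## The problem

Communication between tissues — hormonal signaling between pancreas and
skeletal muscle, coordination between brain regions — is carried by genes
whose influence crosses tissue boundaries. A multi-tissue system can be
modeled as a *multilayer network*: each layer is a tissue, nodes are genes
(the same gene set replicated in every layer), and weighted undirected
edges connect genes both within a layer and across layers. Classical
centrality (PageRank, degree) either ignores the layer structure or counts
only direct cross-layer edges; neither can answer the question practitioners
actually ask: *which genes in tissue A most influence this particular set of
genes in tissue B, through any number of within- and across-tissue hops?*

## The measures

The network is a supra-adjacency matrix `M` of dimension `N × N`
(`N = n·L`), split as `M = A + C` with `A` the block-diagonal intra-layer
part and `C` the inter-layer part. After joint normalization, a family of
damped fixed-point scores (restart probability `1 − p`, default `p = 0.85`)
decomposes a node's overall influence hierarchically:

| measure | fixed-point system | captures |
|---|---|---|
| local `l` | `l = pAl + (1−p)/n·1` | within-layer influence |
| local, layer *i* | `lᵢ = pA[i]lᵢ + (1−p)/n·1[i]` | within layer *i* only |
| global `g` | `g = p[(A+C)g + Cl] + (1−p)/N·1` | cross-layer influence |
| layer-specific `gᵢ` | `gᵢ = p[(A+C)gᵢ + Clᵢ] + (1−p)/N·1[i]` | influence on layer *i* |
| query-set `gᵢˢ` | `gᵢˢ = p[(A+C)gᵢˢ + Clᵢˢ] + (1−p)/N·1ᵢˢ` | influence on a gene set in layer *i* |

(`A[i]` masks all but layer *i*'s column block; `1[i]`/`1ᵢˢ` are layer/set
indicators; all operators are applied in the random-walk transition
orientation — see the vignette.) The family is exactly decomposable:
`Σᵢ lᵢ = l`, `Σᵢ gᵢ = g`, set centralities over a partition of a layer sum
to the layer's centrality, and `l + g` equals PageRank versatility times
`L + 1`. Every solver converges for `0 ≤ p < 1`. **Query-set centrality**
is the headline measure: seed it with, say, insulin-responsive genes in
muscle and it ranks pancreas genes by their direct *and multi-hop* influence
on that set.

The package also provides the comparison baselines (intra-/inter-layer
degree, PageRank versatility, RWR-H — random walk with restart on a
heterogeneous network), a planted-community benchmark generator with known
ground truth, Spearman-correlation multilayer network construction from
expression matrices (with PPI edge augmentation and linear covariate
adjustment), and ranking evaluation (recall-at-k, normalized AUC,
variance-stratified random gene sets, delta ranks, literature co-occurrence
support).

## Worked example

Build a two-layer benchmark network in which a *query set* in layer 2 is
connected to *source set 1* in layer 1 directly, and to *source set 2* only
through source set 1 (two hops). With the ground truth set to source set 2,
only a measure that follows multi-hop cross-layer paths can find it:

```r
library(multicens)

cfg <- synthetic_config(model = 2, n_per_layer = 200, community_size = 30,
                        strength = 1, fraction_x = 1, seed = 42)
gen <- generate_synthetic(cfg)
gen$network
#> multilayer_network: 200 nodes x 2 layers (N = 400 supra-nodes)
#>   layers: L1, L2
#>   edges:  12031 (weight > 0)

dec <- row_normalize(decompose_supra(gen$network))
qc  <- query_set_centrality(dec, gen$truth$query_set, p = 0.85)
qc
#> centrality_result: measure = query_set, N = 400, p = 0.85, target layer = L2
#>   converged in 112 iterations (residual 1.57e-12)

rk <- rank_nodes(qc, layers = "L1")
ev <- recall_at_k(rk$node, gen$truth$ground_truth)
cat(sprintf("recall-at-60: %.2f   AUC: %.3f\n", ev$recall[60], auc_recall(ev)))
#> recall-at-60: 0.93   AUC: 0.837
```

93% of the two-hop ground truth lands in the top 60 of 200 ranked
source-layer genes (the directly connected source set 1 occupies the very
top, the two-hop source set 2 follows). Inter-layer degree, which sees only
direct connections, recovers about 20% here; versatility restricted to
query-incident cross edges recovers none (`run_benchmark()` reproduces the
full method comparison over strength/mixing grids).

For real data, `spearman_multilayer()` builds the network from per-tissue
expression matrices (genes × samples; cross-layer correlations use shared
subjects), `augment_with_ppi()` adds +1 to pairs with physical interaction
support, and `adjust_covariates()` removes linear confounders first.

## Command line

A thin CLI over the same functions ships at `inst/cli/multicens.R`:

```sh
Rscript inst/cli/multicens.R synth --model 2 --n 200 --community-size 30 \
    --strength 1 --x 1 --seed 42 --out net.tsv --truth truth.json
Rscript inst/cli/multicens.R centrality --measure query-set --network net.tsv \
    --layers L1,L2 --target-layer L2 --query query.txt --out scores.tsv
Rscript inst/cli/multicens.R evaluate --scores scores.tsv --truth truth.txt \
    --layer L1 --out eval.json
```

Other subcommands: `build-network`, `baseline`, `benchmark`, `support`,
`fixture`.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computations from scratch
against the installed package: the model-2 benchmark grid (all methods,
direct and two-hop ground truth) and a coexpression-network analysis in
which a module planted across two synthetic expression datasets is recovered
by query-set centrality. Run it from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It prints the benchmark summary and ranking statistics and writes the
results JSON to `--out`.
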