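# graphflux

Context-specific network inference from omic hits, combining **graphlet
statistics** with **Personalized-PageRank edge flux**.

## What it does, and for whom

Given a confidence-weighted reference interactome *R(V, E, c(e))* and a set
of seed proteins/genes (phosphoproteomic hits, mutated genes, DE genes — any
omic hit list, optionally weighted), `graphflux` infers the subnetwork most
relevant to that context. It is aimed at systems-biology analyses where the
hits are sparsely connected in the interactome and where hub proteins would
otherwise flood a propagation-based reconstruction with nonspecific
interactions.

The method has three stages:

1. **Graphlet-guided network (GGN).** The nine connected non-isomorphic
   graphs on 2–4 nodes (graphlets G0–G8) are counted under a seed
   constraint: an occurrence must place an *intermediate* node at a
   maximum-degree orbit and seeds at every other position (both endpoints
   seeds for G0). Counts are tested against 100 degree-preserving
   double-edge-swap permutations of the interactome with a one-sided z-test
   (z > 1.65). The union of all matches of significant graphlets, with
   confidences inherited from *R*, is the GGN *G ⊆ R* — a seed-covering
   core with hubs largely trimmed away.

2. **PageRank flux.** Personalized PageRank
   p = (1−λ)·π + λ·W·p (teleport π on the weighted seeds, damping
   λ = 0.85) propagates the seeds over the reference. Each edge
   {u,t} is scored in both directions,

   f(u→t) = p(u)·c(e)/deg(u),  f(t→u) = p(t)·c(e)/deg(t),

   keeps the minimum, and receives the final score
   f(e) = −log10(min flux). The degree denominator is the hub penalty.

3. **τ selection.** GGN edges are ranked by descending minimum flux and
   accumulated until the running sum of f(e) reaches τ·F, where
   F = Σ f(e) over GGN edges, yielding the context network *C ⊆ G ⊆ R*.

Downstream, Louvain modules are tested for annotation over-representation
with the exact hypergeometric tail (BH-adjusted), networks are compared by
enrichment-profile cosine similarity, and recovery of gold-standard
pathways is scored by step-wise AUPRC, precision/recall/F1, hub reduction
ratios and power-law degree fits. A synthetic generator produces
scale-free interactomes with planted pathways so everything is testable
offline. See the vignette in `vignettes/` for the full methods account.

## Worked example

```r
library(graphflux)

# a 500-node scale-free interactome with a planted 25-node pathway,
# 40% of whose nodes are revealed as seeds
inst <- generate_benchmark(rng_seed = 7)
inst
#> benchmark instance: 500-node interactome, 25-node planted pathway, 10 seeds

fit <- infer(inst$interactome, inst$seeds, tau = 0.5, rng_seed = 7)
fit$census$table
#>    graphlet observed perm_mean perm_sd      z significant
#> G0       G0        5      0.78   0.860  4.909        TRUE
#> G1       G1       11      4.64   2.476  2.568        TRUE
#> G2       G2        0      0.23   0.633 -0.363       FALSE
#> G3       G3       12      1.50   2.163  4.855        TRUE
#> G4       G4        4      0.19   0.465  8.197        TRUE
#> G5       G5        2      0.01   0.100 19.900        TRUE
#> ...
fit$ggn
#> graphlet-guided network: 15 nodes, 15 edges (significant: G0, G1, G3, G4, G5)
fit$network
#> context network: 12 nodes, 8 edges (tau = 0.5, F = 44.84)
```

Five graphlet families occur significantly more often around the seeds
than in degree-matched random rewirings; their union (the GGN) trims the
500-node reference to 15 nodes, and the τ = 0.5 flux budget keeps the 8
strongest edges. Evaluating against the planted truth:

```r
evaluate_recovery(fit$network, inst$truth,
                  node_scores = fit$propagation$p, edge_scores = fit$scores)
#> node: P=1.000 R=0.480 F1=0.649 AUPRC=0.699
#> edge: P=1.000 R=0.320 F1=0.485 AUPRC=0.483

hub_reduction(inst$interactome, fit$ggn)
#> hubs: 100 | removed entirely: 91 | mean reduction ratio: 0.974
```

Every selected node and edge is part of the planted pathway (precision 1),
about half the pathway nodes are recovered at this τ, and 91 of the 100
reference hubs are removed entirely — the hub-trimming behavior the GGN is
designed for. Module enrichment finds the planted term:

```r
part <- detect_modules(fit$network, rng_seed = 7)
enr <- enrich_modules(part, inst$annotations,
                      background = inst$interactome$nodes)
head(enr, 1)
#>   module            term k n  K  M  p_value adjusted_p significant
#> 1      1 PLANTED_PATHWAY 6 6 25 83 0.000469     0.0113        TRUE
```

## Command line

The same pipeline is scriptable via the installed entry point
(`inst/scripts/graphflux`):

```sh
graphflux simulate --n-nodes 500 --pathway-size 25 --seed-fraction 0.4 \
          --rng-seed 7 --out sim/
graphflux infer --network sim/interactome.tsv --seeds sim/seeds.tsv \
          --tau 0.5 --rng-seed 7 --out run/
graphflux modules --network run/network.tsv --gmt sim/sets.gmt --out mod/
graphflux evaluate --network run/network.tsv \
          --truth-nodes sim/truth_nodes.txt --truth-edges sim/truth_edges.tsv \
          --universe sim/interactome.tsv --out eval/
```

Each output directory contains a `run_meta.json` with every effective
parameter; a YAML `--config` file is supported with CLI flags taking
precedence.

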