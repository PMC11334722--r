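---
title: "Graphlet-guided PageRank-flux network inference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graphlet-guided PageRank-flux network inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphflux)
```

## The problem

Omic experiments yield lists of "hit" proteins or genes (phosphoproteins,
mutated genes, differentially expressed transcripts) that are sparsely and
indirectly connected in genome-scale protein-protein interaction networks.
Reconstructing the context-specific signaling network that links those hits
faces two systematic obstacles: reference interactomes aggregate evidence
across unrelated cell types and carry many false-positive interactions, and
highly connected hub proteins act as shortcuts that drag nonspecific
interactions into any propagation- or path-based reconstruction.

`graphflux` addresses both with a hybrid of subgraph statistics and network
propagation, in three stages.

## Stage 1: the graphlet-guided network (GGN)

Graphlets are the nine connected non-isomorphic undirected graphs on 2-4
nodes (G0 edge, G1 3-path, G2 triangle, G3 4-path, G4 3-star, G5 4-cycle,
G6 triangle plus pendant, G7 diamond, G8 4-clique). A graphlet occurrence
is only counted when it *covers the seeds*: the induced subgraph on a node
subset must match the pattern with an **intermediate node** placed at a
maximum-degree orbit and **seed nodes** in every remaining position. The
2-node graphlet G0 requires both endpoints to be seeds. The intermediate
may itself be a seed — the constraint is that the non-intermediate
positions are seeds, and treating a seed-dense region as less eligible
would only lose recall. A subset is counted once per graphlet type even
when several valid assignments exist.

Counting is seed-anchored rather than a full census: subsets with at most
one non-seed member are enumerated from the seed set and its
multi-neighborhoods, which keeps the census tractable on sparse
interactomes (cost grows with `choose(#seeds, 3)` times typical
neighborhood sizes, not with the interactome).

Observed counts are compared against `n_permutations = 100` degree-
preserving randomizations of the interactome. Each permutation performs
`ceiling(swap_factor * |E|)` attempted double-edge swaps
(`swap_factor = 10`, a standard mixing heuristic; the literature specifies
the swap move but not the count). A swap replaces edges (a,b), (c,d) on
four distinct nodes by (a,c), (b,d) or (a,d), (b,c) only when neither new
edge exists, so the degree sequence is preserved exactly. Each rewired
edge inherits the confidence of the edge it displaced, preserving the
confidence multiset so that flux computed on a permuted network remains
comparable.

The z-test uses the sample (n-1) standard deviation across permutations; a
graphlet is significant when `z > alpha_z` with `alpha_z = 1.65`, the
conventional one-sided 5% normal cutoff (`qnorm(0.95) = 1.645`). When the
permutation counts are constant (`sd = 0`, common for rare graphlets on
small graphs) the z-score is undefined and we fall back to a strict rule:
significant only if the observed count exceeds every permuted count.

The GGN is the union over significant graphlets of all matched nodes and
their induced edges, with confidences inherited unchanged from the
reference, so `G ⊆ R` by construction. G0 matches (direct seed-seed
edges) enter the GGN whenever G0 is significant; on realistic interactomes
G0 rarely reaches significance, so this choice has little practical effect
but avoids silently discarding direct evidence.

## Stage 2: propagation and edge flux

Personalized PageRank iterates

```
p[t+1] = (1 - lambda) * pi + lambda * W p[t]
```

with `W[y,x] = 1/deg(x)` on edges and teleport `pi`. Two teleport modes
exist because the printed update rule in this method family uses a uniform
`(1-lambda)/N` teleport while the surrounding description is explicitly
*personalized* ("propagates signals from seed nodes", weighted inputs).
The default `teleport = "seeds"` places teleport mass on seeds
proportional to their weights — without this, seed weights could not
influence the propagation at all — and `teleport = "uniform"` reproduces
the literal uniform-teleport formula. The damping factor is not reported
in the source method; we default to `damping = 0.85`, the conventional
PageRank choice, and expose it. Convergence is declared when the L1
change drops below `tolerance = 1e-8` (well below any downstream ranking
effect); mass on degree-0 nodes is redistributed to the teleport vector so
`sum(p) = 1` is maintained exactly.

Each edge `e = {u,t}` receives two directional fluxes

```
f_u->t = p(u) * c(e) / deg(u),     f_t->u = p(t) * c(e) / deg(t)
```

with `deg` taken in the **reference** interactome (fluxes are computed on
the reference and then mapped onto the GGN; using GGN degrees would undo
the hub penalty exactly where trimming was strongest). The edge keeps the
*minimum* of the two (both endpoints must support the edge), and the final
score is `f(e) = -log10(min_flux)`. The log base is a display/bookkeeping
choice — it rescales all scores by a constant, so rankings are unaffected
and the tau budget shifts only marginally through the summation; base 10
is the default and `log_base = "e"` is available, with the base recorded
on the score table. An edge whose minimum flux is exactly 0 (an endpoint
that received no probability mass) gets an infinite score and is excluded
from selection.

## Stage 3: tau selection

Scores are restricted to GGN edges, `F = sum(f(e))` over finite-score GGN
edges, and edges are taken in order of **descending minimum flux** until
the running score sum reaches `tau * F`; the edge that first reaches the
budget is included, so `tau = 1` keeps every finite-score edge and
`tau = 0` keeps none. Descending min-flux equals ascending `f(e)`, i.e.
the *strongest* edges (highest propagation mass, confidence, and lowest
hub dilution) are admitted first. The selection formula's printed index
convention can be read as the opposite order (descending `-log`), which
would admit the weakest edges first and contradict the stated intent of
preserving "high-scoring" GGN edges; `literal_ranking = TRUE` implements
that literal reading for comparison. Because `f(e)` is smallest for the
strongest edges, small tau values admit a large *edge count* but a small
*score mass* — tau is a mass budget, not an edge-count fraction.

Ties in min-flux are broken by node identifiers so runs are deterministic.
Degenerate corner: if every finite GGN edge has score exactly 0
(`min_flux = 1` everywhere, `F = 0`) any positive tau selects all finite
edges, since the budget is met trivially; `tau = 0` still selects none.
`tau` defaults to 0.5; like the source method we treat it as the main
user-facing dial (it was tuned per task there, with no stated default).

## Modules, enrichment, similarity

The inferred network is partitioned with Louvain modularity maximization
(igraph implementation, `resolution = 1`, topology-only by default;
deterministic given `rng_seed`, and module labels are renumbered by
decreasing size so they are stable). Each (module, term) pair is tested
with the exact hypergeometric upper tail `P[X >= k]`, followed by
Benjamini-Hochberg adjustment **across all module-term pairs** at
`fdr_alpha = 0.05`; the source method names only the hypergeometric test,
so the multiple-testing scheme is our addition and is recorded in the
output. The default universe is the background nodes appearing in at
least one annotation set ("annotated"): unannotated nodes can never
contribute to an overlap and would only inflate the universe size;
`universe = "interactome"` is available for comparability.

Networks are compared through enrichment profiles over a shared term
vocabulary — binary (term significant in >= 1 module) by default, or
weighted by `-log10` of the best adjusted p — with cosine similarity.
Whether the original analysis used binary or weighted profiles is
unstated; binary is the more conservative default. The average-linkage
hierarchical clustering in `cluster_contexts()` is a labeled convenience
for stratifying many contexts, not part of the method: the original
tumor-stratification analysis does not name its clustering algorithm, so
we make no attempt to reproduce any particular patient split.

## Evaluation utilities

AUPRC uses step-wise (trapezoid-free) average precision over the full
ranked universe, with unranked items placed last — no interpolation
optimism. Edge-level negatives default to all reference edges not in the
truth set, and the positives ratio is reported so sparsity regimes can be
compared. Hubs are the `ceiling(0.2 |V|)` highest-degree reference nodes
(ties by id); the reduction ratio `RR(h) = 1 - deg_trimmed/deg_ref` is 1
for hubs removed entirely. Power-law fits are least squares on
`log10 k` vs `log10 N(k)` over non-zero-frequency degrees, requiring at
least 3 distinct degrees; `gamma = -slope`. A 5-fold seed-masking
cross-validation utility scores recovery of held-out seeds.

## The synthetic benchmark

`generate_benchmark()` emulates the features the method actually exploits:
a scale-free reference (preferential attachment, so hubs and a power-law
degree spectrum exist), per-edge confidences in (0,1] (uniform by default,
or a high-skewed Beta(5,2) like curated interactomes), and a planted
connected pathway (random BFS growth) whose internal confidences are
boosted toward 1 with mixing weight 0.5 — a recoverable but non-trivial
signal: the pathway remains statistically invisible to anything that does
not combine seed coverage with confidence. A fraction of pathway nodes is
revealed as seeds; annotation sets contain the planted term plus degree-
and size-matched decoys so enrichment cannot win by size or degree alone.

The generator deliberately does **not** emulate measurement noise in seed
weights, patient-level heterogeneity, false edges correlated with degree,
or incomplete annotation — so passing tests demonstrate algorithmic
correctness and recoverability under clean conditions, not performance on
real interactomes.

Default study conditions (used throughout the tests and the acceptance
script): 500-node interactome with attachment 2, a 25-node planted
pathway, seed fraction 0.4, and full inference defaults including 100
permutations. Property suites use smaller instances (toy graphs, 4-12
node graphs for brute-force oracles, 20-200 node graphs for invariants)
so that exhaustive enumeration remains exact.

## Numerical choices and degenerate inputs

- Duplicate input edges keep the **maximum** confidence (evidence
  strength; conservative toward inclusion). Self-loops are dropped;
  directed input is symmetrized. Node ids are opaque, case-sensitive
  strings — no identifier mapping.
- Seeds absent from the interactome are dropped with a warning and
  reported via `coverage`; all seeds absent is a fatal error. Unweighted
  seeds and unweighted edges default to 1.0.
- Graphs admitting no legal double-edge swap (e.g. a triangle) are
  returned unchanged with a warning rather than looping forever.
- An empty GGN (no significant graphlet) propagates to an empty context
  network, each step warning rather than failing, so pipelines degrade
  gracefully on uninformative seed sets.
- TSV output carries 15 significant digits; round trips reproduce
  confidences and scores to well beyond 12 significant digits.

## Known limitations

- The constrained census enumerates seed triples; with thousands of seeds
  the `choose(s,3)` term dominates and a compiled census would be the next
  step. Typical omic hit lists (tens to a few hundred) are fine.
- Significance with few permutations is coarse; the sd = 0 fallback is
  deliberately strict and can mark rare graphlets insignificant on tiny
  graphs.
- Louvain is a heuristic; determinism is per-seed, not per-platform
  beyond the igraph version pinned by the environment.
- Power-law exponents from least squares on binned histograms are the
  field's conventional descriptive fit, not a maximum-likelihood tail
  estimate; they are used comparatively (reference vs GGN), not
  inferentially.
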