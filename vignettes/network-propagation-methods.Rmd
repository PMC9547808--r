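---
title: "Methods: random-walk prioritization on multi-layer knowledge networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random-walk prioritization on multi-layer knowledge networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwrnet)
```

## The model

rwrnet scores biomedical entities by how reachable they are from a seed
entity under a random walk with restart (RWR) on a multi-layer
heterogeneous network. Each layer is one evidence source — curated
disease–gene annotation, GWAS associations, pathway membership,
protein–protein interaction, knockout-phenotype annotation — holding typed
nodes (gene, disease, pathway, phenotype, chemical) and nonnegative edges.
An entity occurring in several layers exists as one *replica per layer*;
replicas are joined by weight-1 cross-layer links. This multiplex
representation keeps each layer's internal topology intact and makes the
inter-layer coupling an explicit, tunable quantity rather than a merge
decision.

The walk follows the recursion

$$S_{k+1} = \alpha M^{\top} S_k + (1-\alpha) S_0,$$

with restart distribution $S_0$ (mass 1 on the seed entities, split
equally over entities and then over each entity's replicas), continuation
weight $\alpha$ and the global transition matrix $M$ laid out as $K \times
K$ blocks for $K$ layers:

* off-diagonal block $(i,j)$: the bipartite cross-link matrix
  $A_{ij}$, row-normalized, scaled by the jumping probability
  $\lambda_{ij}$; a row without cross links stays zero;
* diagonal block $i$: the within-layer adjacency $A_i$, row-normalized,
  with row $k$ scaled by the stay probability
  $1 - \sum_j I_{kj}\lambda_{ij}$, where the per-node indicator $I_{kj}$
  is 1 iff node $k$ has at least one cross link into layer $j$.

The indicator is deliberately per node, not per layer: a gene that exists
in only two of the layers should not forfeit stay mass toward layers it
cannot reach. With that convention, every node with at least one
within-layer edge has outgoing mass exactly 1, and the only substochastic
rows belong to nodes that are isolated *within* their layer (see
"Degenerate inputs" below).

Because $\alpha < 1$ and every row sum of $M$ is at most 1, the map
$S \mapsto \alpha M^\top S + (1-\alpha) S_0$ is an L1 contraction with
rate at most $\alpha$; the fixed point is unique, the iteration converges
geometrically, and nothing in the propagation is stochastic.

## Parameters

* **`alpha`** (default 0.7, restart probability 0.3), dimensionless in
  $[0,1)$. Larger values let the walker range farther before restarting;
  0.7 is the conventional middle ground in network propagation and is
  fully configurable. The limit `alpha = 0` returns the restart vector —
  a useful sanity anchor.
* **`lambda` / `total_jump`** (default: total jump mass 0.5). The jumping
  probabilities govern how easily the walker crosses layers. No canonical
  values exist, so the default splits a total mass of 0.5 equally among
  the layers a given layer actually shares entities with
  ($\lambda_{ij} = 0.5/d_i$); pairs with no shared entity get 0. An
  explicit, possibly asymmetric $K \times K$ table overrides this. Rows
  must sum to at most 1 so the stay probability can never go negative.
* **`tol`** (default $10^{-9}$, L1 change per iteration) and
  **`max_iter`** (default 1000). With $\alpha = 0.7$ the residual shrinks
  by at least 0.7 per step, so the default tolerance is reached in roughly
  60 iterations; hitting `max_iter` raises a warning and flags the result,
  never fails silently.
* **`collapse`** (default `"sum"`). Replica scores are summed per entity,
  preserving total probability mass; `"max"` is offered for sensitivity
  analysis.

## Conventions with a rationale

* **Identity resolution.** Entities match across layers iff their
  `(entity_type, identifier)` key matches after trimming; gene symbols are
  upper-cased, all other namespaces kept verbatim. Nothing attempts
  symbol-to-accession mapping — feed the network consistent identifiers.
* **Directionality.** Annotation layers are often stored directionally
  (disease → gene). For walk purposes adjacencies are symmetrized
  (entrywise maximum with the transpose, so listing both orientations does
  not double an edge); otherwise a gene seed could never reach disease
  nodes at all. Direction metadata is retained, and
  `respect_direction = TRUE` restores one-way edges.
* **Duplicates and self-loops.** Duplicate edge rows collapse with a
  warning — weights summed for weighted input (evidence mass adds),
  weight 1 for unweighted input (the unweighted invariant). Self-loops are
  dropped: staying put is already modeled by the diagonal-block stay
  probability.
* **Ranking.** Per type, competition ranks (ties share the minimal rank)
  with lexicographic identifier order as the deterministic output order;
  percentile rank is $100 \cdot \text{rank}/n$. Seeds are excluded from
  their own type's table by default, the usual prioritization convention —
  a seed trivially ranks first on its own restart mass. Whether a screen's
  printed denominator counts the seed is a reporting choice; the default
  here excludes the seed from ranking while `n_candidates` counts what was
  actually ranked.

## Degenerate inputs and numerical choices

* **Zero rows.** Row normalization maps an all-zero row to an all-zero
  row, both in coupling blocks (a node with no cross link) and in diagonal
  blocks (a node with no within-layer edge). The alternative — redirecting
  the stay mass of within-layer-isolated nodes onto their cross links —
  was rejected: it changes the walk law in a way the block equations do
  not express. The cost is a substochastic row and slow mass leakage from
  such nodes; convergence is unaffected since the spectral radius of
  $\alpha M$ stays below $\alpha$. `row_sum_report()` audits the leaked
  mass per node.
* **Tolerances.** Row-sum exactness is asserted to $10^{-12}$; the
  closed-form oracle `closed_form_scores()` solves
  $(I - \alpha M^\top) S = (1-\alpha) S_0$ directly and is guarded to
  $N \le 5000$ — it is a verification tool, not the production path.
* **Determinism.** Propagation contains no randomness; all randomness
  lives in the synthetic generator behind one explicit seed
  (`withr::with_seed`, Mersenne–Twister), and replicate seeds are derived
  arithmetically (base + index) so any replicate is reproducible alone.

## The synthetic benchmark

`generate_toy_network()` emulates the statistical shape of a real
multi-layer knowledge network at desk scale: typed sparse layers (layer 1
disease–gene, layer 2 pathway–gene, layer 3 phenotype–gene, extra layers
gene–gene), coupling only through shared gene symbols, and one planted
partner gene directly connected to the seed in `planted_partner_degree`
layers. Reference conditions: 3 layers, 50 genes per layer,
within-layer edge probability 0.05, partner planted in all 3 layers.
The remaining knobs were fixed once at values typical for such a toy
screen: 20 context nodes per layer (mean gene degree about 1, matching
the sparsity of curated annotation), 20 noise edges per layer, and a
shared-gene fraction of 1 — all layers draw from one gene universe, as
genome-scale sources do, which also makes genes exchangeable under the
no-signal null so the planted partner's null percentile centers at 50.
The full gene roster belongs to every layer even when a gene drew no
edge (a screen ranks all genes, including zero-evidence ones); context
nodes exist only through their annotations.

`planted_recovery()` runs the entire pipeline per replicate and reports
the rank-1 fraction and median rank/percentile of the partner. Under the
reference conditions the partner is the only gene with direct seed edges
in every layer, so recovery is expected near 1; with no planted signal the
partner is exchangeable with its 48 non-seed peers and its percentile is
near-uniform.

What passing these tests does **not** show: robustness to the identifier
noise, degree heterogeneity (hubs), ascertainment bias and redundant
evidence of real databases — toy layers are Erdős–Rényi, real ones are
heavy-tailed. The benchmark validates the machinery (assembly,
propagation, ranking), not the biology of any particular database
snapshot.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` use networks of roughly 30–700
global nodes: 100 random 2–5-layer networks for the iterative-vs-closed-form
comparison (agreement to $10^{-8}$ in L∞), 100 replicates each for the
planted and null recovery runs, and small star/cycle fixtures for
symmetry and conservation. These sizes make every check exact or
well-powered while keeping a full run in tens of seconds.

## Limitations

* Layer count is generic; nothing hard-codes seven layers, and a chemical
  layer is supported by type but no chemical-specific reader is shipped.
* No identifier mapping, no database downloaders: ingestion starts from
  edge-list TSV and GMT files the user provides.
* Only row-stochastic normalization is implemented — no symmetric or
  Laplacian diffusion variants.
* The plain power-style iteration is adequate at the intended scale
  (tens of thousands of nodes); no accelerated solvers are provided.
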