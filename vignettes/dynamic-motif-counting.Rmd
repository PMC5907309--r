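---
title: "Counting motifs in dynamic networks: model, heuristics and design choices"
author: "dynamotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting motifs in dynamic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynamotif)
```

# The problem

A network motif is a small connected subnetwork whose frequency in a host
network carries biological signal. When the host network evolves — an
interactome rewiring across developmental stages, a co-expression network
shifting between conditions — every edge insertion or deletion invalidates
the counts, and recounting from scratch means re-solving a
subgraph-isomorphism problem per edit. `dynamotif` instead maintains the
counts incrementally, paying a per-edit cost proportional to the edited
edge's neighbourhood rather than to the whole network.

Three frequency measures are involved. **F1** counts all embeddings of the
motif — edge subsets of the host whose subgraph is isomorphic to the motif,
with overlaps allowed. **F2** counts a maximal collection of pairwise
*edge-disjoint* embeddings, and **F3** a maximal collection of pairwise
*node-disjoint* ones. An embedding is identified by its edge set:
automorphic re-mappings of the same edges are one embedding, so the
triangle in a 3-clique counts once, not six times.

F2 and F3 are maximum-independent-set problems on the *overlap graph*
(one node per embedding, an edge between embeddings sharing a host edge or
node), which is NP-complete; every practical method, static or dynamic, is
therefore a heuristic for these two measures, while F1 is exact.

# Static counting

`enumerateEmbeddings()` grows connected edge subsets from each anchor edge
(an ESU-style search on the line graph, in which every connected subset is
generated exactly once) and classifies each size-*q* subset by canonical
form. The canonical form is the minimum adjacency-matrix encoding over all
node permutations — exhaustive, hence exact, and perfectly adequate at
motif scale (at most 10 nodes; the four built-in basic motifs have 3 or
4). Tests cross-check both the enumeration (against a brute-force subset
search using igraph's independent isomorphism test) and the canonical form
(against igraph's isomorphism decisions on all small random graph pairs).

## The disjointness greedy

`greedyDisjoint()` visits overlap-graph nodes in ascending degree order,
ties broken by smallest embedding id, selecting every node not yet removed
and removing its neighbours; the result is a maximal independent set.

Two details deserve explanation.

**Static initial degrees.** The degree used for ordering is the node's
degree in the *full* overlap graph, computed once, rather than recomputed
on the residual graph after each removal. Both readings of "repeatedly
select a minimum-degree node" are defensible; we chose static degrees for
a scalability reason: residual-degree maintenance costs time proportional
to the number of overlap-graph *edges*, and on hub-dense hosts that number
explodes — a scale-free network of 1000 nodes with average degree 10 has
hubs of degree > 100, about 1.6 million 3-star embeddings, and on the
order of 10^10 overlap edges, well beyond both time and memory budgets.
With static degrees the overlap graph is never materialised: degrees are
obtained exactly by inclusion–exclusion over shared key subsets (per-edge
containment counts, minus shared-pair counts, plus shared-triple counts,
…), which costs O(F1 · 2^q). The greedy's output remains a maximal
independent set either way; the tests verify validity, maximality, the
exact optimum on all small fixtures (F1 = 4 / F2 = 2 / F3 = 1 on the demo
graph, F2 = 1 for triangles in K4), and bit-identical agreement between
this engine-side greedy and the explicit pure-R overlap-graph
implementation.

**Tie-breaking.** Default deterministic (smallest embedding id), so that
every run — and in particular the step-0 comparison between the dynamic
initialisation and a static recount — is exactly reproducible. A seeded
`tieBreak = "random"` mode draws uniformly within each equal-degree group
instead, reproducing the randomised flavour of the underlying procedure;
it is exercised in tests but not used in the reported experiments.

# Dynamic maintenance

`dynamicMotifCounter()` enumerates the embeddings of the starting network,
builds the per-edge index `D_e` (edge → ids of embeddings containing it),
and runs the greedy once to seed the F2 member set, marking each member's
edges as used.

**Deletion of edge e.** Every embedding in `D_e` dies; F1 decreases by
`|D_e|` — this is exact, no search involved. At most one F2 member X can
contain e (members are edge-disjoint). If one does, X's edges are released
first, and X's surviving overlap-graph neighbours — the union of the
`D_e'` lists over X's edges, restricted to live embeddings — are scanned
in ascending id for a replacement Y whose edges are all free. One
replacement attempt is made; we do not cascade to further repairs even if
several mutually disjoint free neighbours exist, keeping the update local
and cheap at a measured, small cost in F2 accuracy.

**Insertion of edge e.** New embeddings must contain e, so the search is
confined to the k-neighbourhood of e, k being the motif diameter (1, 2, 3
for the built-in motifs); the implementation grows connected subsets
anchored at e, which visits exactly that region. F1 grows by the number of
new embeddings — again exact. All new embeddings share e, so at most one
can join the F2 set: the first (ascending id) whose edges are all free, if
any.

Releasing X's edges *before* testing candidate freeness is deliberate:
replacements necessarily overlap X, so testing against the pre-release
usage map would reject every candidate and the repair rule would be
vacuous.

These rules make F1 maintenance exact under arbitrary valid scripts (the
test suite asserts equality of the whole embedding store, not just the
count, against fresh enumeration after hundreds of random edits), while F2
may drift from what a fresh greedy would return; the drift is the price of
locality and is quantified below.

# Edit scripts and the perturbation model

Scripts are explicit sequences of `+`/`-` operations with validation:
inserting a present edge or deleting an absent one raises an error naming
the step, rather than silently toggling. Node arrivals and departures are
expressed through their incident edges; nodes left isolated are retained
(they cannot host embeddings of a connected motif with ≥ 1 edge).

Synthetic perturbations use degree-preserving edge shuffles: two
node-disjoint edges (a,b), (u,v) are replaced by (a,v), (u,b). Candidates
whose replacement edges already exist are rejected and resampled, keeping
the graph simple; each accepted shuffle is emitted as two deletions and
two insertions in a random interleaving (any order is valid once the
rejection rule has passed, because the four edges are pairwise distinct).
Edge orientation is randomised when sampling, so both rewirings of an
unordered edge pair are reachable. Degrees are provably preserved after
every complete shuffle, and the tests assert this along every script.

# Synthetic generators and study conditions

`generateNetwork()` wraps seeded igraph generators: Erdős–Rényi G(n, p)
with p = degree/(size−1); Watts–Strogatz ring lattices with degree/2
neighbours per side and rewiring probability 0.1 (the conventional
small-world regime; the underlying study leaves this parameter unstated,
so it is a documented, configurable default); Barabási–Albert growth with
attachment m = degree/2.

The accuracy experiment in `scripts/acceptance.R` and
`test-acceptance.R` runs all three models at **size 1000, average degree
10, 1000 edit operations, five seeds, four basic motifs** (2-edge path,
3-edge path, triangle, 3-edge star — all connected topologies with two or
three edges; the numbering Motif 1–4 in that order is a package
convention). These sizes are deliberate scaled-down replicas of the
original study grid (sizes 2000–5000, degrees 10–20) chosen so that the
full experiment completes in minutes on one CPU; the statistic of
interest, accuracy = 100 · c_dynamic / c_static at the final topology, is
scale-free. Note one consequence of scaling down: 1000 operations rewire
about 20% of a size-1000, degree-10 network, a several-fold harsher
relative churn than in the original grid, so measured accuracies are
conservative.

Observed under these conditions (deterministic tie-breaks, seeds 1–5):
mean final F2 accuracy ≈ 98%, per-motif means ≈ 98.6 / 99.0 / 96.8 / 97.2
(path2 / path3 / triangle / star3). The one cell below 95% is
Watts–Strogatz with the triangle motif (mean ≈ 94%): the WS lattice is
triangle-dense and clustered, and degree-preserving shuffles destroy its
clustered triangles faster than local repair can recover, which is
exactly where a locality-restricted F2 heuristic is expected to be
weakest. F1 accuracy is 100% everywhere, by construction.

# Co-expression networks

`buildCoexpressionNetwork()` implements the paired two-threshold rule: an
edge joins genes u, v if their Pearson correlation in the primary
expression matrix exceeds the stringent cutoff (0.95), or exceeds the
relaxed cutoff (0.75) in the primary while exceeding the stringent cutoff
in the secondary matrix. "Exceeds" is strict and applies to the signed
correlation — negative correlations never create edges — with an
`absolute = TRUE` escape hatch for the common alternative. Genes absent
from one matrix and genes with zero variance are excluded by default
(`genes = "union"` keeps matrix-private genes reachable through the
stringent condition only). Correlations come from `stats::cor`; with
fewer than 3 samples the correlation is degenerate and the function
refuses to run.

`diffToScript()` turns a pair of networks into an edit script — one
deletion per edge private to the start network, one insertion per edge
private to the final one — in a seeded uniform-random order, since the
true temporal order of such edits is unknown; applying the script
reproduces the final edge set exactly.

Because the real transcription data behind such networks cannot be bundled,
`simulateExpression()` provides a synthetic stand-in: a latent-module
model in which genes within a module share a standard-normal latent
profile plus independent Gaussian noise (expected within-module
correlation 1/(1 + noiseSd²)). This reproduces the feature that matters
for this package — blocks of highly correlated genes yielding motif-rich
co-expression networks with controllable density — but not other features
of real expression data (mean–variance coupling, batch structure,
heavy-tailed counts), so passing tests demonstrate the correctness of the
network-construction pipeline, not biological fidelity of the fixture.

# Numerical and degenerate-input choices

* Edge identity is the unordered label pair, stored lexicographically;
  node labels are opaque strings. All file formats are plain TSV.
* Thresholds are compared strictly (`>`); ties at exactly 0.95/0.75 are
  measure-zero on real-valued data.
* The evolving graph may become disconnected; nothing in the algorithms
  requires host connectivity (only motifs must be connected).
* `accuracy(0, 0)` is defined as 100 (perfect agreement on an empty
  result); values above 100 are reported unclamped — the static reference
  is itself a heuristic and the dynamic set can occasionally beat it.
* Motifs are limited to 10 nodes / 12 edges (exhaustive canonical form);
  hosts are unlimited.

# Known limitations

* F2/F3 are greedy maximal sets, not maximum ones; tests verify
  `F3 ≤ F2 ≤ F1`, validity and maximality everywhere, and agreement with
  an exact branch-and-bound optimum on all fixtures with ≤ 20 embeddings.
* The dynamic F2 repair is local by design: one replacement attempt per
  lost member, no global re-optimisation. Accuracy degrades slowly with
  accumulated edits (a tendency the tests assert across seeds) and is
  weakest for clustered, triangle-dense hosts under heavy churn, as
  quantified above.
* F3 is computed statically only; no dynamic node-disjoint maintenance.
* Directed, weighted and multi-edge networks are out of scope.
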