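---
title: "Measuring the simpliciality of higher-order networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the simpliciality of higher-order networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simpliciality)
```

## The problem

A set of multi-way interactions can be represented as a hypergraph (no
structural assumptions) or as a simplicial complex (downward closure: every
sub-interaction of an observed interaction is assumed to exist). The choice
matters — dynamics such as synchronization and contagion behave differently
under the two representations — and it is ultimately an empirical question:
how close are the data to downward closure? This package answers that
question with three global measures and their local counterparts, plus
randomized baselines to judge whether a fitted generative model reproduces
the observed inclusion structure.

Throughout, a hypergraph is *simple*: no repeated edges, no repeated nodes
within an edge (`hypergraph()` enforces both by canonicalization).

## The measures and their assumptions

Let $\tilde E$ be the maximal edges (not contained in any other edge) and
$P_K(e)$ the power set of $e$ restricted to subset sizes in $K$. The
induced restricted simplicial complex is $C = \bigcup_{\tilde e} P_K(\tilde
e)$.

* **Simplicial fraction** $\sigma_{SF} = |S|/|E|$, the fraction of edges
  that are simplices. Highly interpretable, but an edge that is *almost*
  closed contributes nothing, and small simplices weigh heavily.
* **Edit simpliciality** $\sigma_{ES} = (|E|-|\tilde E|)/(|C|-|\tilde E|)$,
  the complement of the fraction of edges that would have to be added to
  reach closure. Sensitive to outliers: one large open edge contributes
  $2^{|e|}$ terms to the denominator.
* **Face edit simpliciality** $\sigma_{FES} = |F|^{-1}\sum_{e\in F}
  \bigl(1 - d_{FES}(e)/(|P_K(e)|-1)\bigr)$ with $d_{FES}(e)$ the number of
  missing subfaces of $e$ and $F = \tilde E$. The per-face normalization
  exponentially down-weights large edges. The $-1$ in the denominator makes
  the normalized distance of an edge with no subfaces exactly 1.

Design principles: a simplicial complex scores 1 on every measure; defined
values lie in $[0,1]$; adding a subface increases ES strictly and never
decreases FES; the measures of an empty hypergraph are undefined. SF is
*not* strictly monotone under subface addition (adding a non-simplex
subface can enlarge its denominator), so the test suite asserts
monotonicity for ES and FES only.

## Size restriction and minimal faces

Strict downward closure demands singletons and the empty set, which many
datasets lack by construction; such data would score 0 on every measure for
an uninteresting reason. `size_restriction()` therefore restricts closure
to subface sizes in $K$, default $K = \{2,\dots,11\}$:

* `min_size = 2` excludes singletons (set it to 1 for data where
  single-entity interactions are meaningful, e.g. single-author papers in
  co-authorship data);
* `max_size = 11` caps edge size, because the number of potential subfaces
  grows as $2^{|e|}$; larger edges are **dropped**, not truncated, by
  `preprocess()`, which also removes edges below `min(K)` and then any node
  left isolated. (Whether the cap or the isolated-node pruning is applied
  first changes reported node counts on real data; this implementation caps
  first, then prunes.)

Under a size restriction, edges of size $\min(K)$ — *minimal faces* — are
trivially simplices: there is nothing smaller for them to include. Counting
them would inflate every measure, so each measure focuses on faces where
inclusion is possible: for SF, both the simplex count and the edge count
exclude minimal faces; for ES, maximal edges that are also minimal faces
are excluded from $\tilde E$ and from $C$, and the edge count is taken as
$|E \cap C|$ (edges lying in the reduced complex), which keeps the ratio
within $[0,1]$ for any $K$; for FES, the average runs over maximal edges
that are not minimal faces. Non-maximal minimal faces (a pair inside a
triangle) still count toward the ES numerator — they are genuine
inclusions.

A measure whose denominator degenerates (empty hypergraph, no candidate
simplices, only minimal maximal faces) is `NA`, with a reason code in
`simpliciality_report()`'s `undefined` field. Silent 0/1 defaults would
corrupt downstream statistics such as the assortativity, where undefined
nodes must be dropped, not imputed.

All ratios are single divisions of integer counts, so results are exact at
the precision of the counts; the test suite compares them as exact
rationals against a brute-force subset-enumeration oracle.

## Local simpliciality and assortativity

The ego-hypergraph of node $v$ is the subhypergraph on $\hat V = \{v\}\cup
n(v)$ with all edges contained in $\hat V$ — including edges that do not
touch $v$ itself. Nodal simpliciality is a global measure applied to this
ego-hypergraph; it is undefined for isolated nodes and for nodes whose ego
contains only minimal faces. Local ES *tends* to exceed global ES because
ego maximal edges are smaller, shrinking the denominator; this is a
tendency of typical draws, not a per-node or per-draw guarantee.

Simplicial assortativity is implemented as the Pearson correlation of
nodal values over the *ordered* adjacent pairs of the unweighted pairwise
projection ($A_{ij}=1$ iff $i\neq j$ share an edge), which makes it the
standard assortativity coefficient of the nodal score on the projection
graph and independent of node labelling and of affine rescaling of the
scores. Pairs with an undefined endpoint are dropped; fewer than two
usable pairs, or zero variance among endpoint values (e.g. a perfectly
closed complex), gives `NA`. For tractability on large data the
conventional recipe filters to interaction sizes $\{2,3\}$ —
`size_restriction(max_size = 3)` — applying the size filter *before*
isolated-node removal and using $K = \{2,3\}$ for the nodal measures.

## Null models

* **Configuration model**: bipartite double edge swaps exchange the node
  endpoints of two uniformly chosen (node, edge) incidences, rejecting
  swaps that would repeat a node within an edge or duplicate an existing
  edge, so the node degree sequence and edge size sequence are preserved
  *exactly*. `n_swaps` counts accepted swaps (default $10\,|E|$, the
  conventional mixing allowance); rejected attempts are retried, with a
  safety cap of $\max(100\,|E|,\,10\,n_{swaps})$ attempts for inputs with
  few admissible swaps.
* **Bipartite Chung-Lu**: node $i$ joins an edge of size $s$ with
  probability $\min(1, k_i s / \sum_j k_j)$, sampled with the
  geometric-skipping construction over nodes sorted by weight, so degrees
  and sizes are matched in expectation only. Duplicate sampled edges are
  collapsed to keep the simple-hypergraph contract (the count is recorded
  in an attribute); this slightly deflates edge counts.
* **External**: the ensemble harness also scores user-supplied samples,
  the hook for models sampled with outside tooling such as a bipartite
  degree-corrected stochastic block model, which this package deliberately
  does not reimplement.

`ensemble_simpliciality()` preprocesses every sample identically to the
empirical data (the symmetric choice; samples can exceed the size cap only
if the empirical data did), scores each with the full report, and drops
undefined per-sample values from the summaries with a recorded count. One
master seed spawns per-sample seeds, so ensembles are bit-reproducible and
order-invariant.

## The planted-inclusion generator

`generate_planted_inclusion()` draws `n_maximal_edges` planted edges
(sizes from `size_distribution`, members uniform without replacement) and
includes each restricted proper subface independently with probability
`q`. It emulates exactly the feature the measures detect — a tunable
density of inclusions under a specified maximal-edge size distribution —
with `q = 1` yielding a restricted simplicial complex (all measures 1) and
`q = 0` with non-nested planted edges yielding no inclusions (all measures
0). It does **not** emulate degree heterogeneity, community structure,
temporal aggregation, or correlated subface presence, all common in real
interaction data; a passing test on planted data therefore validates the
measures' response to inclusion density, not distributional realism.
Defaults used in the shipped analyses: 40 nodes, 8–12 planted edges, sizes
3–5 with weights (0.4, 0.4, 0.2) — small enough for exhaustive oracles,
large enough that planted edges are almost never nested.

## Numerical choices and problem sizes

Edges are stored as sorted tuples with hashed string keys, so membership
tests are $O(1)$ expected — `is_simplex()` performs up to $2^{11}$ of them
per edge. Maximal-edge detection tests containment only against larger
edges incident to an edge's least-frequent node; the $O(|E|^2)$ all-pairs
scan is kept as a test oracle. Writers emit edges in canonical order
(size, then lexicographic), so outputs are byte-stable for a fixed seed.

The shipped validation uses problem sizes chosen to keep exhaustive
oracles exact and runs fast: 500 random hypergraphs (≤ 12 nodes, ≤ 40
edges) for oracle equivalence, 200 generator draws per inclusion
probability for the monotonicity sweep, and 1000 Chung-Lu samples for the
3-standard-error degree calibration.

## Limitations

* Replicating published per-dataset values requires the public xgi-data
  datasets, which are not redistributed here; the replication test runs
  only when they are present locally (see the README).
* $K$ is assumed contiguous in the shipped analyses; gappy $K$ is
  supported but ES counts then depend on the $|E \cap C|$ convention
  described above.
* No weighted complexes, no mesoscale/community simpliciality, no
  nestedness measures — adjacent questions, different machinery.
* The configuration model counts *accepted* swaps; with heavily
  constrained inputs the attempt cap may stop the chain early (a warning
  reports the shortfall).
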