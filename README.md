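# simpliciality

Higher-order interaction data — group conversations, multi-recipient
emails, multi-protein complexes, co-sponsored bills — are modelled either
as **hypergraphs** (arbitrary hyperedges, no structural assumptions) or as
**simplicial complexes** (every sub-interaction of an interaction is
assumed present: *downward closure*). Real datasets almost never sit at
either extreme. This package quantifies where a dataset actually lies on
that spectrum, for data scientists choosing a higher-order representation
and for modellers checking whether a generative model reproduces the
inclusion structure of the data they fit it to.

## Measures

For a hypergraph `H = (V, E)` with maximal edges `Ẽ` (edges not contained
in any other edge) and induced simplicial complex
`C = ∪_{ẽ∈Ẽ} P_K(ẽ)`, where `P_K(e)` is the power set of `e` restricted
to subset sizes in `K` (default `K = {2, …, 11}`, excluding singletons and
the empty set and capping edge size for tractability):

- **Simplicial fraction** `σ_SF = |S| / |E|` — the fraction of hyperedges
  that are simplices (all their allowed subfaces present).
- **Edit simpliciality** `σ_ES = (|E| − |Ẽ|) / (|C| − |Ẽ|)` — the fraction
  of the induced complex already present; equivalently `1 − d_NES` where
  `d_ES = |C| − |E|` is the number of edges that must be added to reach
  downward closure.
- **Face edit simpliciality**
  `σ_FES = |F|⁻¹ Σ_{e∈F} (1 − d_FES(e) / (|P_K(e)| − 1))` with
  `d_FES(e)` the number of missing subfaces of `e` and `F` the maximal
  edges — a per-face-normalized variant that removes the dominance of
  large edges.

Minimal faces (edges of size `min(K)`, trivially simplices under the
restriction) are excluded from the candidate sets throughout; degenerate
cases (empty hypergraph, only minimal faces) are reported as undefined,
never as 0 or 1. The same measures evaluated on a node's ego-hypergraph
give **nodal simpliciality**, and their correlation across adjacent node
pairs in the pairwise projection gives the **simplicial assortativity**.
Randomized baselines come from a degree- and size-preserving
**configuration model** (bipartite double edge swaps) and a **bipartite
Chung-Lu** sampler.

## Worked example

```r
library(simpliciality)
h <- read_hypergraph(system.file("extdata", "two_triangles.txt",
                                 package = "simpliciality"))
simpliciality_report(h)
#> Simpliciality report
#>   simplicial fraction (SF):        0.5
#>   edit simpliciality (ES):         0.5
#>   face edit simpliciality (FES):   0.5
#>   edit distance d_ES = 3 (normalized   0.5)
#>   counts: |E| = 5, |E~| = 2 (non-minimal 2), |C| = 8, |S| = 1/2
```

The fixture holds two 3-edges, one with all of its pairs and one bare, so
exactly half of the possible inclusion structure exists and all three
measures agree at 0.5: of the two candidate simplices one is closed
(`|S| = 1/2`), and 5 of the 8 edges of the induced complex are present
(`(5−2)/(8−2) = 0.5`, with `d_ES = 3` edges missing). Locally,

```r
nodal_simpliciality(h, "sf")
#> 1 2 3 4 5 6
#> 1 1 1 0 0 0
```

the nodes of the closed triangle have nodal SF 1, the others 0. Comparing
against the configuration-model null:

```r
ensemble_simpliciality(h, "configuration", n_samples = 100, seed = 1)
#> Simpliciality ensemble: model = configuration, 100 samples
#>   sf  empirical  0.5 | ensemble mean    0 (sd    0, 0 undefined)
#>   es  empirical  0.5 | ensemble mean 0.216 (sd 0.103, 0 undefined)
#>   fes empirical  0.5 | ensemble mean 0.21 (sd 0.0994, 0 undefined)
```

degree- and size-preserving randomization destroys most of the inclusion
structure, so the empirical values sit well above the null means.

## Command line

```sh
inst/cli/simpliciality compute --max-size 11 mydata.txt        # measure table
inst/cli/simpliciality local mydata.txt --output nodes.csv     # per-node CSV
inst/cli/simpliciality assortativity --max-size 3 mydata.txt
inst/cli/simpliciality null-ensemble --model configuration \
    --samples 1000 --seed 7 --output ens mydata.txt
inst/cli/simpliciality generate --nodes 100 --edges 20 --q 0.8 \
    --seed 1 --output synth.txt
```

Formats: hyperedge lists (one edge per line, comma- or
whitespace-separated), bipartite node/edge-id incidence lists, and the
JSON hypergraph dialect used by the public `xgi-data` repository. No
dataset downloader is bundled; to analyze the named public datasets
(contact-primary-school, contact-high-school, hospital-lyon, email-enron,
email-eu, diseasome, disgenenet, ndc-substances, congress-bills,
tags-ask-ubuntu), fetch their JSON files from the `xgi-data` repository
into a directory and point the tools at them, e.g.
`options(simpliciality.data_dir = "~/xgi-data")` for the dataset
replication test.

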