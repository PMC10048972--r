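---
title: "Integrative network-pharmacology screening: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative network-pharmacology screening: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytonet)
```

## The screening problem

A multi-component herbal extract acts through many constituents hitting
many targets. Ranking constituents by network degree alone is known to
nominate the same promiscuous polyphenols for almost any herb, because
target-prediction databases link them to hundreds of proteins regardless of
context. `phytonet` implements a screen that requires convergent evidence
from three independent sources before a compound is called *key*:

1. **topology** — its position in the compound–target–pathway network,
2. **literature** — how often it has been studied in the disease model,
3. **quantitation** — how abundant it actually is in the extract
   (MS peak response as a proxy).

A compound must pass at least two of the three. Targets are screened by
network topology alone (the *hub* rule). All thresholds are medians of the
relevant populations, re-computed from the data of every run; the package
never hard-codes a published threshold, and the run report prints the
medians it used.

## Target-space model

The drug-target set is the union over compounds of predicted targets with
Tanimoto fingerprint similarity at or above `tanimoto_min` (default 0.7).
The comparison is **inclusive**: predictions exactly at the cutoff were
collected by the upstream prediction platform and must survive the replay.
Disease genes are taken per record with **strict** source thresholds
(GeneCards relevance > 10, DisGeNET score > 0.1 by default, as these rules
are conventionally stated), and curated sources pass untresholded; a gene
enters the disease set as soon as one source supports it. Thresholding is
applied per record *before* de-duplication — with per-record thresholds the
two orders give the same union, and the record-wise rule keeps the audit
trail simple. No gene-alias mapping is attempted beyond upper-casing:
synonym resolution is a curation step that belongs upstream of the tables
this package ingests.

## Enrichment statistic

Over-representation of a query gene set in an annotated set is scored by
the hypergeometric upper tail $P(X \ge k)$ with population size $N$
(default: the union of all genes in the annotation collection, mimicking
annotation-tool practice; an explicit universe can be supplied), $K$
annotated genes, query size $n$ and overlap $k$. The sum is computed in log
space via `lchoose` with a log-sum-exp reduction, so tail values around
$10^{-300}$ remain exact to at least ten significant digits; tests verify
agreement with exhaustive probability-mass summation for every
parameterization with $N \le 30$ and with `stats::phyper` deep in the tail.
The EASE variant (the tail evaluated at $k-1$) reproduces the conservatism
of the DAVID web tool; it is available but not the default, because the
standard tail is the better-defined statistic. Multiple-testing correction
defaults to `none` — published term counts in this field are convention-
ally raw $p < 0.05$ — with Benjamini–Hochberg per namespace available and
recommended for new analyses. Terms with zero overlap are not reported:
their tail probability is 1 by construction and they carry no evidence.

Functional-module labels (inflammation / metabolism / other) are an
explicit curated mapping supplied as input. Selecting which pathways are
disease-relevant is likewise a curation decision; the pipeline takes an
allow-list GMT and never infers it.

## Network conventions

The compound–target–pathway graph is **undirected and unweighted**.
Compound abundance influences the screen only through the quantitation
criterion, never as an edge weight, since no principled weighting of
prediction edges by abundance is available. Edges connect a compound to a
target (surviving prediction whose target lies in the effective target set
— the overlap genes found in the selected pathways) or a target to a
pathway (set membership). Isolated nodes are dropped; building an edgeless
network is an error.

Centralities are computed on the whole tripartite graph:

- **degree** — incident edge count;
- **closeness** — for node $v$ in a connected component of size $m$,
  $(m-1)/\sum_u d(v,u)$ over that component, 0 for isolated nodes.
  Cross-component distances are treated as undefined, not infinite;
- **betweenness** — endpoint-excluded shortest-path betweenness over
  unordered pairs, normalized by $2/((n-1)(n-2))$ with $n$ the total node
  count, so values lie in $[0,1]$; networks with fewer than three nodes
  score 0 everywhere.

These are the conventions of the network-analysis tool used to produce the
published tables this package replays (all printed centralities lie in
$[0,1]$). Degree and closeness are computed directly from the igraph
distance matrix; betweenness wraps `igraph::betweenness` with the above
normalization. Both are verified in the test suite against brute-force
Floyd–Warshall / path-counting oracles on hundreds of random small graphs.

## Screening rules and tie policy

- Hub targets: degree **strictly** greater than the target-degree median.
  Strictness matters: in the published replay the stated median is 6 and
  the smallest printed hub degree is 7, which only the strict rule
  reproduces. With all degrees equal, nothing is a hub.
- Key components: degree strictly above the component-degree median;
  study count **at or above** the literature median; response **at or
  above** the response median. The inclusive comparators on the two
  evidence criteria reflect how borderline compounds are treated in
  practice (a compound sitting exactly on the literature median counts as
  supported); all comparators are configurable.
- The literature median is computed over the compounds that already pass
  the topology criterion — literature mining is a verification step on the
  topologically nominated candidates, not an independent survey of all
  constituents — with a configurable override. Compounds with no
  literature record count as zero studies.
- The response median is taken over **all** ingested components, not only
  those reaching the network, since abundance ranking happens at the
  chemistry stage.
- Median convention: `stats::median` (mean of the middle two for even
  counts). Ranking ties are broken alphabetically for reproducibility.
- Docking: a pose passes strictly below the affinity cutoff
  (−5.0 kcal/mol default); a pose exactly at the cutoff fails.

One known edge of the published replay: one compound (rutin) appears among
the published key components although the printed medians support at most
one criterion for it. The package reproduces the *rule*, not individual
exceptions; replaying the published component evidence will therefore not
select rutin.

## Synthetic evidence generator

`generate_bundle()` emulates the statistical shape of a real screen so that
every stage is testable without any external download:

- **responses** are log-normal (meanlog 11, sdlog 1.5), spanning roughly
  two orders of magnitude as real MS peak responses do;
- **prediction counts** per compound are heavy-tailed (1 + negative
  binomial with size 1, mean 6). Planted hub compounds draw
  Poisson-concentrated counts at `hub_degree_multiplier` (default 4) times
  the baseline mean — the elevated degree *is* the planted property, so it
  is guaranteed per hub rather than only in expectation;
- **Tanimoto scores** are a mixture with 65% of mass at or above 0.7, so
  the similarity filter has real work to do;
- **literature counts** are zero-inflated negative binomial (size 1, mean
  3, 30% extra zeros) — many identified phytochemicals have never been
  studied in the disease model. Planted hubs draw plain negative binomial
  counts at mean 10, without the extra zeros: a well-studied hub is
  definitionally studied;
- **disease-gene scores** use the native source scales (GeneCards-like
  uniform(0, 30), DisGeNET-like uniform(0, 0.5)); planted hub targets
  always carry a curated-source record so the planted disease-relevant
  structure survives source thresholding, and a configurable fraction of
  predicted targets (default 0.2) appears in the disease table;
- **annotations** are 150 terms of 10–40 genes; five planted terms draw
  ~60% of their genes from the planted hub targets.

Everything is driven by a single integer seed; the same configuration
yields byte-identical files, which the determinism tests hash.

What the generator does *not* emulate: correlated target profiles between
chemically similar compounds, gene-alias noise, annotation-term overlap
structure (GO's DAG), or any relationship between abundance and activity.
Passing the recovery benchmark therefore shows the screen recovers planted
multi-evidence structure under realistic marginals — it does not certify
performance on real, correlated evidence.

## Benchmark and problem sizes

The package's recovery benchmark runs the full pipeline on 25 seeded
default bundles (80 compounds, 500 targets, 150 terms each) and requires
mean recall of the 10 planted hub compounds under the default two-of-three
screen to reach at least 0.8; precision is reported but not thresholded,
because the screen is designed as a nomination step with downstream
experimental verification. Graph-metric oracles run on 200 random graphs
of up to 12 nodes, and the enrichment statistic is checked against
exhaustive summation for all parameterizations with $N \le 30$; these sizes
make the brute-force oracles exact and exhaustive while keeping the default
test run fast on a single CPU.

## Degenerate inputs and failure modes

Readers fail loudly with the offending column, row or line number; unknown
disease-gene sources (no configured threshold) are a configuration error
rather than a silent drop; an empty edge set, an empty screening
population, or a query disjoint from the annotation background each
produce an explicit error or warning. The pipeline wraps stage failures
with the stage name, and `render_report()` regenerates byte-identical
reports from the same run.

## Known limitations

- No gene-identifier mapping: symbol case-folding only.
- The replay of published tables is desk-scale: full replication of the
  published overlap (105 genes), network size (160/729) and 19
  topology-passing components requires the study's supplementary tables,
  which were never publicly deposited.
- Enrichment term counts depend on the annotation snapshot; published
  GO/KEGG term counts are not reproducible without the original
  annotation database version.
- The docking stage only screens supplied affinities; it does not run a
  docking engine.
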