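---
title: "Seed-gene networks, structural modules and pathway enrichment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-gene networks, structural modules and pathway enrichment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(seednet)
```

## The problem

A disease gene signature — a few dozen genes from an expression, proteomic
or GWAS study — rarely explains its own biology. Placing those *seed genes*
inside a protein–protein interaction (PPI) network, finding the densely
interconnected *functional modules* they fall into, and annotating each
module with pathway enrichment turns a flat gene list into mechanistic
hypotheses: genes sharing a module with many seeds are candidate biomarkers
for the same process, even when they never appeared in the original
signature.

seednet implements that workflow end to end: a multi-source consensus
knowledge base, seed-based network expansion, SCAN structural clustering
with hub/outlier roles, per-module modularity scoring, node centrality
statistics, and one-sided Fisher exact enrichment per module.

## Consensus knowledge base

Interaction records arrive as `(id_a, id_b, source)` triples in mixed
identifier formats. `map_ids()` translates every identifier to a canonical
(Entrez-style) ID through an alias table; symbol aliases are matched
case-insensitively, purely numeric aliases exactly, and an alias pointing
at two canonical IDs is rejected outright at load time because silent
ambiguity would corrupt the seed list. `merge_sources()` collapses the
records to one edge per unordered canonical pair and keeps the set of
*distinct* sources supporting each edge — repeated records within one
database add no evidence, so multiplicity is ignored. Records that fail to
map, or whose endpoints collapse to one canonical ID (self-interactions),
are dropped and counted: self-loops carry no information for a
common-neighbor similarity.

`kvotes_filter(kb, k)` keeps edges reported by at least `k` sources.
`k = 1` is the plain union of all databases; `k = 2` is the stringent
consensus preset that trades coverage for reliability; `k` equal to the
number of sources is their intersection. The edge sets are nested in `k`
by construction, which the tests assert.

## Network construction around seeds

Three modes build the analysis network from the knowledge-base graph:

* **direct_neighbors** (default below 1000 seeds): the seeds plus every
  gene directly interacting with a seed. Edges are added only when at
  least one endpoint is a seed, so no edge ever joins two added genes.
* **min_seed_links(t)**: as above, but a non-seed gene is kept only when
  it interacts with *more than* `t` seeds (default `t = 2`, read
  literally as a strict inequality). Useful for large, noisy signatures.
* **seeds_only** (default above 1000 seeds): the subgraph induced by the
  seeds alone.

The mode boundary at exactly 1000 seeds resolves to expansion, since
expansion is the tool's characteristic behavior; lists above 3000 seeds
trigger a soft warning rather than an error. Mapped seeds absent from the
knowledge base are retained as isolated, flagged nodes so the seed
accounting of a run always matches the user's mapped list. Seed–seed edges
satisfy the seed-incidence rule and are kept in every mode.

## SCAN structural clustering

For adjacent nodes $u, v$ the structural similarity is the cosine overlap
of their *closed* neighborhoods $\Gamma(\cdot)$ (the node plus its
neighbors):

$$\sigma(u,v) = \frac{|\Gamma(u)\cap\Gamma(v)|}{\sqrt{|\Gamma(u)|\,|\Gamma(v)|}} \in [0,1].$$

Including the node itself follows the original SCAN formulation and makes
$\sigma = 1$ exactly when two nodes have identical closed neighborhoods. A
node is a **core** when at least $\mu$ members of its closed neighborhood
are $\varepsilon$-similar to it (the node itself always counts, since
$\sigma(v,v)=1$); clusters grow by structure-reachability from cores,
collecting cores and the non-core *border* nodes they claim. Unassigned
nodes are **hubs** when their neighbors span two or more modules — they
bridge processes and may play several biological roles — and **outliers**
otherwise.

Defaults are $\varepsilon = 0.7$, $\mu = 2$, the canonical SCAN setting;
both are exposed everywhere. Traversal runs in lexicographic node order,
so module numbering and the assignment of border nodes claimed by several
clusters are reproducible run to run; the test-suite checks clusterings
against the $\varepsilon/\mu$ *definitions* by exhaustive brute force, not
against fixed labels, so the determinism choice is a presentation detail,
not a semantic one. No significance test is attached to modules: ranking
(below) orders them, and nothing stronger than that ordering is claimed.

Worked example, two triangles joined by a bridge:

```{r}
g <- ppi_graph(data.frame(a = c("a", "a", "b", "c", "d", "d", "e"),
                          b = c("b", "c", "c", "d", "e", "f", "f")))
structural_similarity(g, "c", "d")   # the bridge edge: 2/sqrt(16) = 0.5
cl <- scan_cluster(g)
tidy(cl)
```

A subtlety worth knowing: a pendant node attached to a degree-2 member of
a triangle has $\sigma = 2/\sqrt{8} \approx 0.707 \ge 0.7$ and is
therefore *claimed as a border member* at the default $\varepsilon$; only
weaker attachments (e.g. to the degree-3 bridge endpoint,
$\sigma = 2/\sqrt{10} \approx 0.632$) become outliers. The definitional
tests pin this behavior down.

## Per-module modularity and ranking

Newman's modularity is a whole-partition score; its standard per-community
decomposition serves here as a single-module quality measure:

$$Q_i = e_{ii} - a_i^2,$$

where $e_{ii}$ is the fraction of all edges inside module $i$ and $a_i$
the fraction of edge endpoints attached to it. Summing $Q_i$ over any
complete partition recovers global $Q$ exactly (asserted to $10^{-12}$
against an independently coded dense-matrix $Q$). For the two-triangle
graph above, one triangle scores $3/7 - 0.25 \approx 0.179$.

`rank_modules()` orders modules by seed count (default), size, or
modularity, reporting the top six by default; ties resolve to the larger
module, then to the lexicographically smallest member. Seed count is the
default criterion because the question a signature analysis asks is
"which modules concentrate my input genes".

## Centrality statistics

Four standard node measures accompany every run; the tool names them
without prescribing formulas, so the conventional definitions are used:

* **Degree centrality**: degree over $n-1$.
* **PageRank**: fixed point of $x \gets (1-d)/n + d\,Mx$ with uniform
  teleport, $d = 0.85$, tolerance $10^{-10}$. Columns of isolated nodes
  are zero, so isolated nodes hold exactly the teleport mass before the
  final normalisation to sum one; the iteration is checked against a
  dense linear solve to $10^{-8}$.
* **HITS**: on an undirected graph hub and authority scores coincide with
  the principal adjacency eigenvector. The power iteration runs on
  $A + I$ from the uniform vector — the shift leaves eigenvectors
  untouched but prevents the sign oscillation that plain $A$ suffers on
  bipartite graphs (a star never converges otherwise). On disconnected
  graphs whose components tie on the leading eigenvalue, the uniform
  start spreads mass evenly across the tied components; that outcome is
  deterministic and documented rather than an error.
* **Betweenness**: Brandes-style shortest-path betweenness over unordered
  pairs, fractional credit across equally short paths, reported
  unnormalized (a `normalized` flag divides by $(n-1)(n-2)/2$). Verified
  against an exhaustive all-shortest-paths enumeration on small graphs.

## Enrichment

Each reported module is tested against every gene set of a GMT collection
with the one-sided Fisher exact test: $p = P(X \ge k)$,
$X \sim \mathrm{Hypergeometric}(N, K, n)$, computed as an exact
hypergeometric tail (no approximation) and verified against a
`choose()`-ratio tail sum to $10^{-12}$ over all tables with $N \le 60$.

The background universe defaults to all genes in the collection — the
tool never states a background, and the universe changes every p-value,
so it is explicit and overridable (`collection`, `network`, or a file).
Raw p-values are reported, matching how pathway summaries are
conventionally printed; a Benjamini–Hochberg column is available but off
by default. Values below $10^{-4}$ print as `<0.0001` in the
human-readable column while machine-readable output keeps full precision.
All module genes are tested (not only seed members), with seed overlaps
flagged separately — enrichment driven by added genes is exactly the
novel-mechanism signal the expansion exists to find.

## Synthetic fixtures: what they emulate, and what not

`planted_partition_graph()` plants ground-truth modules: blocks of nodes
with within-block edge probability `p_in` and between-block `p_out`. The
study conditions used throughout the tests are 4 blocks × 20 nodes,
`p_in = 0.9`, `p_out = 0.02` — dense, well-separated modules of the size
real signature modules tend to have. Edge counts per block pair are drawn
binomially and pairs sampled uniformly without replacement, which is
distributionally identical to independent per-pair coin flips but scales
to the $10^5$-edge graphs used in the runtime checks.
`make_multisource_kb()` has each of 3 sources report each edge with
probability 0.8, emulating partially overlapping curated databases;
`make_aligned_annotations()` builds one gene set per block plus random
decoys; `sample_seeds()` draws half of each chosen block as the seed
signature. One integer seed reproduces a whole scenario bit for bit.

These fixtures deliberately omit two properties of real PPI data:
heavy-tailed degree distributions and literature-curation bias (popular
genes accumulate interactions). Passing the planted-recovery tests
therefore demonstrates correctness of the algorithms under clean modular
structure, not that any particular biological network will yield modules
of this quality.

## Problem sizes and numerical choices

The test-suite and the acceptance script use: 200 random graphs with
$n \le 40$ for the SCAN definitional oracle; 20 planted-partition
replicates for recovery (adjusted Rand index vs planted labels); 100
random graph/partition pairs for the modularity identity; every
margin-consistent hypergeometric table with $N \le 60$; 100 graphs with
$n \le 10$ for betweenness enumeration and $n \le 50$ for the PageRank
solve; 50 replicates each for the k-votes and expansion properties; one
$\approx 1.2\times10^5$-edge planted graph for the near-linear runtime
check; and 40 end-to-end scenarios for recovery of the seeded blocks'
aligned gene sets. These sizes keep every brute-force oracle exact while
exercising each code path hundreds of times.

Other numerical choices: $\sigma \ge \varepsilon$ comparisons use a
$10^{-12}$ guard against floating-point grazing; empty graphs cluster to
zero modules; modularity of an edgeless graph is an error (undefined),
while a module with no incident edges scores 0; enrichment of a module
disjoint from the universe returns an empty table rather than an error.

## Limitations

* Interactions are unweighted and undirected; confidence scores and
  signaling direction in source databases are discarded.
* Expansion is single-hop; genes two steps from every seed are invisible.
* Border nodes claimed by several SCAN clusters go to the first cluster
  in deterministic traversal order; overlapping membership is not
  modelled.
* Enrichment treats gene sets as flat; hierarchical relations between
  pathways are ignored.
* The per-module $Q_i$ of small modules in large networks is dominated by
  $e_{ii}$; comparing $Q_i$ across networks of very different size is not
  meaningful.
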