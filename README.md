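# seednet

Seed-gene protein–protein interaction (PPI) network analysis in R: build a
network around a disease gene signature, detect its functional modules with
SCAN structural clustering, score and rank the modules, and annotate each
one with Fisher-exact pathway enrichment.

## Who it is for, and what it does

Given a list of *seed genes* (e.g. a published biomarker signature), a
multi-source interaction knowledge base, an identifier-mapping table and a
GMT gene-set collection, seednet:

1. maps heterogeneous gene identifiers to canonical IDs,
2. merges tagged interaction sources into one consensus graph, keeping an
   edge only if at least *k* distinct databases report it (*k*-votes;
   `k = 1` union, `k = 2` stringent consensus),
3. builds the analysis network by adding direct interactors of the seeds
   (or only genes linked to more than *t* seeds, or the seeds alone), with
   every added edge touching at least one seed,
4. clusters the network with **SCAN**, which assigns adjacent nodes to the
   same module when their closed neighborhoods overlap strongly,

   σ(u,v) = |Γ(u) ∩ Γ(v)| / √(|Γ(u)|·|Γ(v)|),

   declaring a node a *core* when ≥ μ of its closed neighborhood is
   ε-similar (defaults ε = 0.7, μ = 2), growing modules by reachability
   from cores, and labelling leftover nodes *hubs* (neighbors in ≥ 2
   modules) or *outliers*,
5. scores each module with the per-community Newman modularity term
   Qᵢ = eᵢᵢ − aᵢ², ranks modules by seed count, size or modularity
   (top 6 by default),
6. computes PageRank, degree centrality, HITS and betweenness per node, and
7. tests every reported module against each gene set with the one-sided
   Fisher exact (hypergeometric tail) test.

Results are tibbles throughout; fitted objects support `tidy()`,
`glance()` and `autoplot()`. Outputs are written as TSV plus GUESS GDF,
and byte-identical on re-run.

## Worked example

No downloads are needed: the package generates planted-module scenarios
with known ground truth.

```r
library(seednet)

# 4 planted blocks of 20 genes; 3 overlapping sources; seeds = half of
# blocks 1 and 2; pathway sets aligned with the blocks plus decoys
sc <- make_scenario(rng_seed = 17, dir = "scenario")
cfg <- pipeline_config(sc$paths$interactions, sc$paths$id_map,
                       sc$paths$seeds, sc$paths$gmt, "scenario/out")
report <- run_pipeline(cfg)
report
#> <run_report>
#>   seeds: 20 input, 20 mapped, 20 in knowledge base
#>   network (direct_neighbors): 52 nodes, 289 edges, 32 added genes
#>   modules: 2

report$module_summary
#> # A tibble: 2 x 4
#>   module_id n_nodes n_seeds modularity
#>       <int>   <int>   <int>      <dbl>
#> 1         1      20      10      0.229
#> 2         2      17      10      0.174

head(report$enrichment[, c("module_id", "set_id", "k", "set_size",
                           "module_size", "p_value")], 3)
#>   module_id  set_id  k set_size module_size      p_value
#> 1         1 block_1 20       20          20 2.828601e-19
#> 2         1 decoy_2  7       20          20 1.841813e-01
#> 3         1 decoy_3  6       20          20 3.743558e-01
```

Reading this: the 20 seeds (10 each from planted blocks 1 and 2) pulled in
32 direct interactors; SCAN found two modules of 20 and 17 genes, each
containing 10 seeds; and each module's top-enriched gene set is exactly
the pathway aligned with its planted block, with the decoy sets far
behind — the signature's processes were recovered and annotated. The
written outputs land in `scenario/out/`: `modules.tsv`,
`module_summary.tsv`, `enrichment.tsv`, `node_stats.tsv`, `network.gdf`
and `run.log`.

A command-line front end wraps the same pipeline:

```sh
Rscript inst/cli/netmod.R fixtures --blocks 4x20 --seed 17 --out scenario
Rscript inst/cli/netmod.R run --interactions scenario/interactions.tsv \
    --idmap scenario/id_map.tsv --seeds scenario/seeds.txt \
    --gmt scenario/annotations.gmt --out scenario/out
```

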