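# ddsn

Target-based drug–drug similarity networks for drug repurposing.

## What it does, and for whom

Most computational repurposing starts from chemical structure; `ddsn`
starts from behaviour. Two drugs are considered similar when they act on
the same biological targets *in the same way* — both agonistically or
both antagonistically. From a typed drug–target interaction table the
package builds the weighted **drug–drug similarity network (DDSN)**
$G = (V, E, w)$, where the weight

$$w(e_{j,k}) = |\{\, t : \mathrm{act}(v_j,t) = \mathrm{act}(v_k,t) \in
\{\text{agonist},\text{antagonist}\} \,\}|$$

counts shared same-type targets. On this network it then runs the full
repurposing analysis:

* **community detection** by weighted-modularity maximization
  (recursive spectral bisection with Kernighan–Lin refinement; Louvain
  as an alternative),
* an **energy-model force-directed layout** (LinLog family, exponents
  $a, r$) with a k-means/NMI check that spatial clusters and modularity
  communities agree,
* **centralities** — degree $d$, weighted degree $d_w$, betweenness $b$
  (with the global $\binom{|V|}{2}$ normalization and the conventional
  one), the prioritization score $b/d$, and Clauset-style **power-law
  tail fits** of their distributions,
* **community labeling** by dominant annotated property (> 50% of
  members) and per-community **top-$t$ $b/d$ ranking**: top drugs that
  do *not* carry their community's dominant property are repurposing
  **hints**, with DATABASE/LITERATURE confirmation bookkeeping,
* **molecular-docking work orders** (drug–target pair lists for hinted,
  negative and reference drugs) ready for external docking software,
* a **synthetic generator** of typed bipartite interaction data with
  planted blocks, so the entire pipeline is testable without any
  licensed database.

It is aimed at computational pharmacology and network-biology users who
have (or can extract) a drug–target interaction table and want
reproducible, scriptable repurposing candidates rather than a GUI
workflow. Graphs export to GEXF/GraphML for Gephi.

## Worked example

The three-drug toy network: Drug1 and Drug2 act identically on all three
targets (agonist on T2, antagonist on T1 and T3), Drug4 differs from
Drug2 only on T3.

```r
library(ddsn)
library(dplyr)

interactions <- tibble::tibble(
  drug_id   = rep(c("Drug1", "Drug2", "Drug4"), each = 3),
  target_id = rep(c("T1", "T2", "T3"), 3),
  action    = c("antagonist", "agonist", "antagonist",
                "antagonist", "agonist", "antagonist",
                "antagonist", "agonist", "agonist")
)

g <- build_ddsn(interactions)
tidy(g)
#> # A tibble: 3 × 3
#>   from  to    weight
#>   <chr> <chr>  <int>
#> 1 Drug1 Drug2      3
#> 2 Drug1 Drug4      2
#> 3 Drug2 Drug4      2
```

Drug1–Drug2 agree on all three targets (weight 3); Drug2–Drug4 agree
only on T1 and T2 (weight 2).

The full pipeline on a synthetic network with three planted drug blocks
(60 drugs, 30 targets, within/between-block interaction probabilities
0.6/0.05, 80% annotation dominance):

```r
sim <- simulate_interactions(n_drugs = 60, n_targets = 30, n_blocks = 3,
                             p_in = 0.6, p_out = 0.05, seed = 1)
ann <- simulate_annotations(sim$truth, dominance = 0.8, seed = 1)
run <- run_ddsn(sim$interactions, ann, seed = 1)
glance(run)
#>  ddsn_version seed    method  mode n_drugs n_edges total_weight n_communities
#>         0.1.0    1 bisection global     60    1104         2591             3
#>  modularity layout_nmi n_hints confirmation_rate
#>   0.3954429          1       2                85
```

The three planted blocks are recovered as three communities (modularity
0.395); k-means clusters of the energy layout match the modularity
communities exactly (`layout_nmi = 1`). 85% of drugs carry their
community's dominant property; the remaining top-ranked non-compliant
drugs are the repurposing hints:

```r
run$hints |> filter(status == "hint")
#> # A tibble: 2 × 6
#>   community  rank drug_id       bd status unresolved
#>       <int> <int> <chr>      <dbl> <chr>  <lgl>
#> 1         2     3 D029    0.000324 hint   FALSE
#> 2         3     5 D021    0.000180 hint   FALSE
```

Both hinted drugs are exactly the planted annotation-noise drugs: high
betweenness/degree members of a community whose dominant property their
annotations lack. A docking work order for such a hint is then one call:

```r
plan <- build_docking_plan(
  property   = "antifungal",
  hints      = "D029",
  refs_in    = c("RefA", "RefB"),
  negatives  = c("NegA", "NegB"),
  targets_in = c("T1", "T2", "T3"),
  known      = tibble::tibble(drug_id = "RefA", target_id = "T1")
)
```

A thin command-line wrapper covers the two ends of the workflow:

```sh
exec/ddsn simulate --drugs 60 --targets 30 --blocks 3 --seed 1 --out-prefix fixture
exec/ddsn run --interactions fixture.interactions.tsv \
              --annotations fixture.annotations.tsv --out results/
```

## Package tour

| Stage | Functions |
|---|---|
| I/O | `read_interactions()`, `read_annotations()`, `write_ddsn()`, `read_ddsn()` |
| Network | `build_ddsn()`, `largest_component()` |
| Communities | `detect_communities()`, `bisect_graph()`, `graph_modularity()`, `label_communities()` |
| Layout | `layout_ddsn()`, `layout_energy()`, `layout_partition_nmi()` |
| Centrality | `drug_centrality()`, `fit_power_law()`, `rplaw()` |
| Prioritization | `top_bd()`, `select_hints()`, `confirmation_summary()` |
| Docking | `build_docking_plan()` |
| Synthetic data | `simulate_interactions()`, `simulate_annotations()`, `write_fixture()` |
| Orchestration | `run_ddsn()`, `exec/ddsn` |

Every result type has `tidy()`/`glance()` and, where a picture helps,
`autoplot()`. See `vignettes/ddsn-methods.Rmd` for the models,
assumptions, parameter defaults and limitations.
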