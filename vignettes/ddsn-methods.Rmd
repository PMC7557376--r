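---
title: "Target-based drug–drug similarity networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target-based drug–drug similarity networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ddsn)
library(dplyr)
```

## The model

`ddsn` implements a network view of drug repurposing built entirely from
typed drug–target interaction data. The premise is behavioural rather than
structural: two drugs are similar not because their molecules look alike
but because they *act alike* — they hit the same biological targets in the
same direction. Chemical similarity is known to be a weak predictor of
shared pharmacology; shared target-action profiles are often a stronger
one.

Formally, from a table of interactions $(d, t, \text{action})$ with the
action typed as *agonist* (activating) or *antagonist* (inhibiting), we
build the weighted, undirected drug–drug similarity network (DDSN)
$G = (V, E, w)$: drugs are nodes, and two drugs $v_j, v_k$ are joined by
an edge whenever at least one target receives the same action type from
both. The integer weight

$$w(e_{j,k}) = \big|\{\,t : \mathrm{act}(v_j, t) = \mathrm{act}(v_k, t)
  \in \{\text{agonist}, \text{antagonist}\}\,\}\big|$$

counts those shared same-type targets. Records whose action cannot be
mapped to the binary typing are excluded from the count by default
(`include_unknown = FALSE` in `build_ddsn()`); they cannot agree "in the
same way" with anything. Interaction vocabularies are richer than the
binary typing, so `normalize_action()` maps common raw strings
(inhibitor, blocker, activator, inducer, ...) onto the two types through
a user-overridable table; the default table is a declared approximation,
not a ground truth. Conflicting duplicate records for the same (drug,
target) pair are dropped with a warning rather than silently arbitrated.

All downstream statistics are computed on the largest connected component
(`largest_component()`, deterministic tie-break by smallest drug id).

The analysis then proceeds in four stages:

1. **Communities** — maximize weighted modularity to group drugs into
   communities of shared target behaviour.
2. **Labels** — name each community by the drug properties that dominate
   it (strict majority among members).
3. **Prioritization** — within each community rank drugs by
   betweenness/degree ($b/d$); highly ranked drugs *not* carrying the
   community's dominant property are repurposing hints.
4. **Docking plan** — for a chosen hint, emit the drug–target pair lists
   an external docking study would run.

## Modularity and community detection

For a partition $\{C_1,\dots,C_m\}$ of $V$ the weighted modularity is

$$M_m = \sum_{C_i} \left[ \frac{w_{E_{C_i}}}{w_E} -
  \left(\frac{w_{C_i}}{2\,w_E}\right)^{\!2} \right],$$

with $w_E$ the total edge weight, $w_{E_{C_i}}$ the weight inside
community $C_i$ and $w_{C_i}$ the total weighted degree of its members.
With unit weights this is the standard Newman–Girvan edge-count form; the
package treats the unweighted form as the special case `weighted = FALSE`.
Two disjoint triangles split into their triangles score exactly $M = 0.5$,
and the all-in-one partition scores exactly $0$ — both are fixed points
used throughout the test suite.

`detect_communities()` defaults to recursive spectral bisection:

* A split into two groups is encoded by signs $s_i = \pm 1$, and its
  modularity change is $s^{\top} B s / (4 w_E)$ with
  $B = A - \mathbf{d}\mathbf{d}^{\top}/(2 w_E)$ the weighted modularity
  matrix. The leading eigenvector of $B$ supplies the starting signs.
* The signs are refined by deterministic Kernighan–Lin style hill
  climbing: each pass flips every node once in greedy order of modularity
  gain (ties broken by node order) and keeps the best intermediate state;
  passes repeat until none improves. On all random graphs up to 12 nodes
  exercised in the tests this refinement attains the exhaustive
  $2^{\,n-1}$ sign-vector optimum.
* Recursion applies the same optimizer inside each community using the
  generalized criterion (the restricted matrix $B^{(C)}$ with its row sums
  subtracted on the diagonal), so every accepted split increases the
  *overall* modularity. Recursion stops on exact non-improvement
  ($\Delta M \le 0$, with a $10^{-12}$ guard against floating-point
  noise); no tolerance parameter is exposed because none is needed at
  these scales.
* Disconnected inputs are handled per connected component, which also
  guarantees $M \ge 0$ for every returned partition.

`method = "louvain"` provides the weighted multilevel merge ascent
familiar from Gephi's modularity pipeline (via igraph) as a faster
alternative on large graphs; it is seeded and deterministic per seed. The
resolution parameter is fixed at 1. The number of communities is always
emergent, never user-set.

## Energy-model layout

The 2D layout minimizes the attraction–repulsion energy

$$E = \sum_{(i,j) \in E} w_{ij}\frac{\delta_{ij}^{\,a+1}}{a+1}
    \;-\; \sum_{i<j} w_i w_j \frac{\delta_{ij}^{\,r+1}}{r+1},$$

where $\delta_{ij}$ is Euclidean distance, attraction acts along edges
with weight $w_{ij}$, and repulsion acts between all distinct pairs with
the product of weighted degrees $w_i w_j$. Exponents $(a, r)$ select a
member of the LinLog family; any exponent that degenerates to $x^0/0$ is
replaced by its logarithmic limit $\ln\delta$. Within the admissible
region $a > -1,\ r > -1$, energy minima group densely connected nodes, so
spatial clusters and modularity communities are two views of the same
structure. The package verifies that equivalence empirically:
`layout_partition_nmi()` k-means-clusters the coordinates (seeded, best
of 10 restarts, $k$ = number of communities) and reports normalized
mutual information against the modularity partition.

Defaults are $(a, r) = (1, 0)$ with $(1, -1)$ available through the log
limit. The descent is plain gradient descent with an adaptive step and
backtracking: a step is accepted only if it lowers the energy (a proposal
that collides two nodes has infinite energy and is rejected), so the
final energy provably never exceeds the initial energy, for every seed.
Initial coordinates are uniform on a square scaled with $\sqrt{n}$,
jittered if coincident. The default 400 iterations are ample for the
graph sizes this package targets (hundreds to a few thousand drugs);
coordinates are reproducible per seed but — as with any force-directed
method — only the *structure* of the embedding is meaningful, not the
absolute coordinates.

## Centralities and heavy tails

`drug_centrality()` reports per drug: degree $d$, weighted degree $d_w$,
betweenness $b$ and the ratio $b/d$. Shortest paths are computed on the
unweighted topology — the similarity weight measures affinity, not
distance, and the ratio's denominator is explicitly the unweighted
degree. Two betweenness normalizations are exposed:

* `mode = "global"` (default): the Brandes dependency sum divided by the
  total number of node pairs $\sigma(G) = \binom{|V|}{2}$, yielding values
  in $[0, 1]$. This global normalization is nonstandard but is the form
  the prioritization consumes; a path graph's centre scores $1/3$, a
  3-leaf star's hub $1/2$.
* `mode = "standard"`: the conventional per-pair normalization (each pair
  contributes the fraction of its shortest paths crossing the node).

The two modes differ by the constant $\sigma(G)$, so rankings are
identical; both are validated against exhaustive shortest-path
enumeration in the tests. Isolated drugs take $b/d = 0$ by convention.

The rationale for $b/d$ as a repurposing score: high degree means many
similarity partners — properties likely already documented; high
betweenness with *low* degree marks a drug bridging communities without
belonging strongly to any, i.e. untapped cross-community potential.

Because all four centrality distributions are heavy-tailed,
`fit_power_law()` fits a Clauset-style power-law tail: maximum-likelihood
$\hat\alpha$ at each candidate cutoff, $x_{\min}$ chosen by minimizing
the Kolmogorov–Smirnov distance (discrete or continuous, detected from
the data; numerical core delegated to igraph's `plfit`). `rplaw()` draws
from a planted power law so the recovery error of $\hat\alpha$ is itself
testable; at $10^4$ draws from $\alpha = 2.5$ the fit recovers the
exponent within $\pm 0.15$. Fewer than 10 distinct positive values are
rejected, constant sequences with a dedicated degenerate-input error.
Distribution plots use 8 linearly spaced bins.

## Labels, prioritization and confirmation bookkeeping

`label_communities()` calls a property *dominant* when strictly more than
50% of a community's drugs carry it (exactly 50% does not qualify);
communities with no such tag stay unresolved. `top_bd()` ranks each
community's drugs by decreasing $b/d$, excluding zeros. The top `t`
(default 5) *distinct values* are kept and drugs tying on a value share a
rank — so a top list can hold more than `t` drugs when ties occur, which
mirrors how grouped rank cells arise in practice; raising `t` never
removes a drug.

`select_hints()` partitions each top list: drugs whose annotations
include a dominant label of their community (case-insensitive exact tag
match, DATABASE evidence taking precedence over LITERATURE) are
confirmed; the rest are hints, $B^h_x = B^t_x \setminus B^c_x$. Matching
is deliberately mechanical — fuzzy or ontology-based matching would blur
what the tests can verify, and expert judgment enters through the
annotation table, not through code. `confirmation_summary()` applies the
same rule to *all* community members and reports per-community
DATABASE / LITERATURE / unconfirmed percentages (summing to 100) plus the
overall confirmation rate.

## Docking plans

`build_docking_plan()` turns one hint into a docking work order: tested
pairs are the full Cartesian product of (hinted + negative) drugs with
all property-relevant targets, while reference pairs (reference drugs in
and out of the hint's community, against their respective target sets)
are restricted to pairs with a database-listed interaction, so every
reference docking has a known positive to compare against. The output is
a plain pair table with role labels; running AutoDock/Vina, preparing
ligands or handling structures is intentionally out of scope.

## The synthetic generator

No redistributable drug–target database exists at the license-free desk
scale, so `simulate_interactions()` generates typed bipartite tables with
planted structure: drugs and targets are split into `n_blocks` blocks;
a drug hits a target of its own block with probability `p_in`, another
block's with `p_out`; each target carries one action type, flipped per
interaction with probability `action_noise`. `simulate_annotations()`
tags each drug with its block's property with probability `dominance`,
otherwise with a foreign property. The reference study conditions —
60 drugs, 30 targets, 3 blocks, $p_{in} = 0.6$, $p_{out} = 0.05$,
agonist fraction 0.5, action noise 0.05, dominance 0.8, evidence split
0.7 DATABASE / 0.3 LITERATURE, seed 1 — were chosen once as a
desk-scale regime with realistic annotation error, and the seed-1 fixture
is committed under `inst/extdata/` (filenames prefixed `synthetic_`) and
regenerated byte-identically in the tests.

What the generator emulates: block-structured target sharing with
coherent action types and noisy, property-coherent annotations. What it
does not: real polypharmacology degree distributions, target families,
correlated annotation errors, or the scale of a curated database. Tests
passing on these synthetics demonstrate that the machinery recovers
planted structure under its own assumptions — not that any particular
real-world hint is pharmacologically valid.

## Numerical choices and limitations

* Ties everywhere break deterministically (node id order, smallest-member
  community renumbering), so fixed seeds give byte-identical outputs.
* Exhaustive-oracle testing uses graphs up to 8 nodes (all-partition
  enumeration), 12 nodes (sign-vector bisection search) and 10 nodes
  (shortest-path enumeration); planted-recovery tests use the 60-drug
  reference fixture. These sizes keep the oracles tractable while
  covering the combinatorial corner cases.
* The spectral+hill-climbing bisection is a heuristic: global optimality
  is verified on small graphs, not guaranteed in general; recursive
  bisection can in principle miss partitions reachable only by merging
  across earlier splits.
* Modularity maximization inherits the resolution limit; very small
  communities attached to large ones may be absorbed.
* The layout gradient descent is $O(n^2)$ per iteration — fine up to a
  few thousand nodes, no Barnes–Hut acceleration.
* Graph exports: GEXF 1.2 and GraphML carry node attributes and layout
  coordinates; the 3-column edge list cannot represent isolated nodes.
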