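---
title: "Cross-species PPI network analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species PPI network analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoppi)
```

`orthoppi` implements a comparative network workflow for transferring
disease-gene knowledge from human case/control expression studies into a
model organism. This vignette documents the statistical model behind each
stage, the tunable parameters and their defaults, the numerical and design
choices that were genuinely open, and what the synthetic-data module does and
does not emulate.

## The workflow

1. Screen differentially expressed genes (DEGs) per dataset and merge across
   datasets.
2. Build a PPI network over the merged DEG list from a scored edge table.
3. Compute node centralities; intersect the top-N lists of several metrics to
   define *key regulators* (KRs).
4. Extract the KRs' closed first neighborhood and project it into the model
   organism through ortholog tables.
5. Build the orthologous-gene network; repeat the centrality/KR analysis
   (adding bottleneck centrality); detect dense modules with MCODE.
6. Run hypergeometric over-representation in both species and intersect the
   significant terms through an identifier crosswalk.

`run_pipeline()` executes all stages from one configuration object and emits
every intermediate table plus a deterministic JSON manifest.

## DEG screening

For gene $g$ with case samples $x$ and control samples $y$ on the log2
scale, the effect is the difference of group means
$\mathrm{log2FC}_g = \bar x_g - \bar y_g$, tested with Welch's
unequal-variance t-test. Welch is the default because the generator's noise
model (Gaussian on the log2 scale) satisfies its assumptions exactly and it
is robust to unequal group variances in real data; a pooled-variance mode
(`pooled = TRUE`) is available. Microarray-style moderated-variance
statistics are deliberately out of scope: the screening *logic* (thresholds,
band, merging) is the subject here, not the variance estimator.

Screening retains genes with $p \le$ `p_max` (default 0.05, on the raw
p-value; the BH-adjusted column is always computed and reported, and
`use_adjusted = TRUE` gates on it) and `lfc_min` $\le |\mathrm{log2FC}| \le$
`lfc_max` (defaults 0.25 and 1.5). The band is implemented literally as
two-sided; users wanting the conventional one-sided rule set
`lfc_max = Inf`. Whether an upper fold-change bound should be exclusionary is
ambiguous in practice, so both bounds are plain parameters.

Merging de-duplicates genes across datasets, records provenance, and flags
direction conflicts (`direction = "conflict"`) instead of resolving them —
a conflicted gene is real signal about dataset heterogeneity and should not
silently survive as "up". Merging is idempotent.

Degenerate inputs: a group with fewer than two samples is an error naming the
group; a gene with zero variance in both groups gets $p = 1$ when the means
are equal and the smallest representable $p$ otherwise.

## Network construction

`build_network()` applies, in order: optional whitelist restriction (both
endpoints), self-loop removal, duplicate unordered-pair collapse keeping the
**maximum** score (conservative retention of the strongest evidence),
isolated-node removal. Human symbols are upper-cased
(`uppercase = TRUE`); worm gene names (`pmk-1`, `daf-21`, ...) are
case-sensitive and left verbatim. The default edge-score cutoff is 0.4 — the
"medium confidence" convention for STRING-like combined scores — because no
single universal cutoff exists; it is configurable and logged in the
manifest. An input that cleans down to nothing yields an explicit empty
network, not an error.

## Centralities

All topology code operates on integer adjacency lists ordered
lexicographically by gene symbol; every tie-break below inherits that order,
making all results deterministic.

* **Degree** $k_v$: adjacency count.
* **Betweenness** $C_B(v)$: Brandes' single-source accumulation over BFS
  shortest-path DAGs, endpoints excluded, divided by $(n-1)(n-2)/2$ so a
  star's center scores exactly 1. The test suite checks it against an
  independent oracle (Floyd–Warshall distances + dynamic-programming path
  counts + explicit pair-dependency summation) to $10^{-9}$ on random
  graphs, and against `igraph::betweenness` on connected graphs.
* **Closeness** $Cc(v)$: (number of reachable nodes) / (sum of distances to
  them) — the reciprocal mean distance *within the component*. This avoids
  infinities on disconnected graphs and matches common network-analyzer
  behavior; nodes with no partner score 0.
* **Bottleneck** $BN(v)$: for each root $s$, one BFS shortest-path tree
  $T_s$ is grown with parent ties broken lexicographically (the published
  description of bottleneck centrality does not fix the tree, so determinism
  has to be imposed); $v \ne s$ is a bottleneck of $T_s$ when its subtree
  ($v$ inclusive) exceeds $|V(T_s)|/4$ nodes. $BN(v)$ counts such roots.
  Subtree counting is $v$-inclusive with the root excluded as a candidate,
  which makes leaf-adjacent cases well defined (a single edge gives both
  endpoints $BN = 1$).

`compute_degree_profiles()` returns $P(k)$ (degree distribution,
$\sum_k P(k) = 1$), $C(k)$ (mean clustering coefficient of degree-$k$ nodes,
with $C_v = 0$ when $k_v < 2$), and $C_N(k)$ (mean neighbor degree). $C(k)$
is implemented as the clustering coefficient — the other plausible reading,
Cytoscape's "topological coefficient", measures shared-neighbor overlap and
is less standard in the P(k)/C(k)/C_N(k) triple.

## Key regulators

`top_n_genes()` ranks a metric descending with lexicographic tie-break and
returns the top N (default 20, the conventional hub-list size; report tables
use top 10). `intersect_top()` takes the set intersection of at least two
ranked lists — the human analysis conventionally uses three metrics (degree,
betweenness, closeness) and the model-organism analysis four (adding
bottleneck); the metric lists are configuration. The *closed* first
neighborhood includes the seeds themselves: a KR set of 11 genes with 637
distinct non-seed partners yields 648 genes, and that arithmetic
(|seeds in network| + |non-seed neighbors|) is asserted by tests. Hub
membership in detected modules is reported as the module-level view of the
KRs; no separate "hierarchical hub tracing" step exists because no algorithm
for it is well defined.

## Ortholog projection

Tables are merged by pair union with evidence-label union, and projection
fully expands one-to-many mappings — a human gene with several worm
co-orthologs contributes all of them; best-hit collapsing would silently
shrink the projected network. No minimum-evidence filter is applied by
default (`min_sources` is available): source databases already apply their
own meta-analysis thresholds, and stacking another one by default would be
double filtering.

## MCODE

The implementation follows the classic molecular-complex-detection scheme:

1. **Vertex weighting.** For each node $v$ with degree ≥ `degree_cutoff`
   (default 2), find the highest $k$-core of the subgraph induced by $v$'s
   closed neighborhood; $w(v) = k_{\max} \times$ density of that core.
   Simple-graph density $2E/(N(N-1))$ is used throughout.
2. **Expansion.** Seed from the highest-weight unassigned node; grow
   breadth-first, admitting a neighbor $u$ when
   $w(u) \ge w(\mathrm{seed}) \times (1 - \mathrm{node\_score\_cutoff})$
   (default cutoff 0.2), never revisiting nodes, to depth ≤ `max_depth`
   (default 100). Nodes touched by a cluster are never re-seeded, so
   clusters are vertex-disjoint (with fluff off).
3. **Post-processing.** Discard clusters lacking a `k_core`-core (default
   2); `haircut` (default on) removes singly-connected members in one pass;
   `fluff` (default off) adds boundary nodes whose closed-neighborhood
   density exceeds `fluff_density`.
4. **Scoring.** $\mathrm{score} = \mathrm{density} \times N$ over the edges
   the module's nodes induce in the *parent* network; a clique of size $n$
   scores exactly $n$. Scores are reported to three decimals and modules with
   score ≥ 5 (default) are called significant.

The expansion-order and tie-break conventions are not fixed by the original
description; lexicographic ordering was chosen so identical inputs always
give identical modules. The "k-score" parameter is interpreted as the
post-processing k-core requirement, matching the app convention its default
value (2) comes from.

## Enrichment and cross-species comparison

For a query of size $n$ from a background of size $M$, a term with $K$
members in the background and overlap $k$ gets the upper-tail hypergeometric
p-value $P(X \ge k)$; `ease = TRUE` decrements $k$ by one (floored at zero)
first, reproducing the conservative EASE score. Fold enrichment is
$(k/n)/(K/M)$. BH adjustment runs within each term category (BP/CC/MF/
pathway) separately, matching how per-category tables are conventionally
reported. The default background is the union of all term members in the
loaded collection — the only universe available offline — and an explicit
background is supported and preferable when the full annotation universe is
known.

`compare_species()` keeps terms significant in both species (default:
raw $p \le 0.05$; pre-intersection significance thresholds are rarely stated
in published comparisons, so the threshold and the adjusted-p switch are
explicit parameters). KEGG-style identifiers crosswalk by numeric suffix
(`hsa04010` ↔ `cel04010`); non-KEGG collections need an explicit mapping.

## The synthetic-data module

The generators produce every input the pipeline consumes, with ground truth:

* `generate_expression()` — log2-scale Gaussian noise (sd `sigma`, default
  0.5) around gene-specific baselines; planted DE genes get their case mean
  shifted by ±`effect_size` (default 1.0) with alternating signs. Gaussian
  log2 noise is chosen to match the t-test's assumptions so the type-I-error
  calibration test is meaningful.
* `generate_network()` — either preferential attachment (hub-dominated,
  matching the shape of disease PPI networks) or planted cliques on disjoint
  node blocks with superimposed Bernoulli noise edges (collisions keep a
  single edge); scores uniform on [0.5, 1].
* `generate_ortholog_table()` — `coverage` fraction of source genes mapped,
  `one_to_many_rate` fraction of mapped genes with two targets.
* `generate_annotations()` — planted terms draw 80% of members from the
  target set (far above a uniform draw); planted/background identifier
  suffixes are deterministic so two collections with different species
  prefixes crosswalk onto each other.

Every generator is a pure function of its arguments including the seed.

`simulate_bundle()` assembles a coherent study: two 600-gene datasets with
80 planted DEGs each (12 vs 12 samples), a preferential-attachment human
network dense enough (m = 10) that its restriction to the ~190 merged DEGs
keeps a hub-dominated shape, an 80%-coverage ortholog table, a worm network
with planted modules of sizes 24/12/8 over the genes the pipeline actually
reaches (the bundle replays the human half of the analysis to find them),
and nine matched planted pathways per species. These sizes are roughly a
10-fold scale-down of a typical published study (hundreds of DEGs, a
~1600-node human network, ~1100 orthologs) and keep a full pipeline run in
the low seconds.

What the generators do **not** emulate: probe-level microarray artifacts,
platform normalization, correlated gene expression, annotation redundancy
(parent/child GO terms), and the incompleteness biases of real interaction
databases. Passing tests therefore demonstrate the *algorithms* are correct
and calibrated on their stated models — not that any particular biological
conclusion transfers to real data.

## Numerical choices and limitations

* Betweenness/closeness are exact (BFS-based), not sampled; networks of a
  few thousand nodes are fine, but $O(nm)$ growth makes very large networks
  slow.
* All tie-breaks (ranking, BFS parents, MCODE seeds and candidates) are
  lexicographic by gene symbol; renaming genes can therefore change
  tie-broken outputs, which is inherent to any deterministic rule.
* `module_score()` requires $n \ge 2$; singleton "modules" are meaningless
  under density scoring and are discarded during post-processing.
* The pipeline's manifest contains counts, parameters, and input MD5
  checksums but no absolute paths or timestamps, so identical inputs and
  configuration reproduce it byte for byte.
* p-values are floored at the smallest positive double rather than reported
  as 0.

## Worked example

```{r example, eval = FALSE}
bundle <- simulate_bundle(tempfile("demo"), seed = 1)
res <- run_pipeline(bundle$config)
unlist(res$manifest$counts)
module_table(res$tables$modules_kept)
write_report(res)
```

On this bundle the planted 24-clique is returned as module 1 with 24 nodes,
276 edges and score 24.000, and all nine planted pathway pairs appear in the
common-terms table (see the README for the printed output).
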