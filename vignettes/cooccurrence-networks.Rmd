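---
title: "Co-occurrence networks from OTU tables: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence networks from OTU tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pandanet)
```

This vignette documents the statistical machinery of `pandanet`, the
reasoning behind its defaults, and the limits of what its synthetic-data
tests demonstrate.

## The analysis model

The pipeline treats microbial association analysis as a sequence of
well-defined transformations of a samples × OTUs count table.

**Relative abundance and taxon classes.** All abundances are per-sample
proportions recomputed from counts — never read from a file — to avoid
normalization-dialect bugs. An OTU's *overall mean* is the arithmetic
mean of its per-sample proportions over the samples in scope (a single
group for group networks, everything for the pooled network). Classes
use the conventional thresholds: rare below 0.01%, abundant above 0.1%,
with both boundaries belonging to the moderate class (the moderate
interval is written with inclusive bounds; abundant is a strict
inequality). Ranking for top-N selection uses the mean of proportions
rather than pooled counts: pooling would weight samples by sequencing
depth, while averaging matches the convention that abundance is averaged
over samples. The choice only matters when depths vary widely; both
behaviors are exposed through `relative_abundance()` +
`select_top_otus()`.

**Correlation and edges.** Spearman's rank correlation with average-rank
ties, computed on proportions (identical to counts when depths are
equal, since ranks are taken across samples). Significance uses the
two-sided t approximation `t = ρ√((n−2)/(1−ρ²))` on `n−2` degrees of
freedom — the conventional default of correlation tooling in this field;
an exhaustive permutation alternative is available for n ≤ 8 samples,
where the full `n!` null is enumerable (beyond that the approximation is
accurate and the permutation cost pointless). A pair becomes an edge
when `|ρ| ≥ 0.6` **and** `p ≤ 0.05`, both bounds inclusive. No
multiple-testing correction is applied by default; a Benjamini–Hochberg
switch exists (`adjust_p = TRUE`) but is off because the analysis this
package implements filters on the raw p-value, with the severe |ρ|
threshold doing the real work at practical sample sizes. OTUs with
constant vectors get ρ := 0, p := 1 (with a warning), so degenerate
taxa can never create edges. Isolated OTUs are dropped: a node must
carry at least one edge to be part of the network.

**Topology.** The graph is undirected and unweighted; ρ survives only
as an edge attribute. Betweenness is reported raw (shortest-path pair
counts, each unordered pair once) because integer keystone cut-offs such
as "betweenness < 5000" are meaningful only on that scale — a normalized
betweenness never reaches 5000; the pair-fraction normalization is
emitted alongside for plotting. Closeness uses the component-corrected
form `((n_c−1)/(n−1)) · ((n_c−1)/Σd)` so the disconnected graphs that
thresholding typically produces still yield values in [0, 1].
Eigenvector centrality is computed by power iteration on `A + I` — the
spectral shift removes the ±λ ambiguity of bipartite components that
makes plain power iteration oscillate — from a uniform start vector, to
a convergence tolerance of 1e-13 (tight enough that iteration error is
invisible at the 1e-9 tolerance of the test oracles), max-normalized.
On disconnected graphs the dominant component carries the mass and
other components get values near zero; this is documented behavior, not
an error.

**Modularity and module detection.** Newman's
`Q = Σ_s [ l_s/L − (d_s/2L)² ]`, unweighted and sign-blind; the few
negative edges these networks contain are counted as ordinary edges,
since sign-aware modularity would add machinery for a negligible effect.
Detection is agglomerative fast-greedy (CNM) followed by one
deterministic pass of local node moves in lexicographic node order
(best strict improvement; ties toward the smallest module id). This
choice favors reproducibility: the whole procedure is deterministic for
a given graph, unlike stochastic Louvain variants, and on the planted
benchmarks used in the tests it recovers the ground-truth partition
exactly. Module ids are relabeled 1..K by decreasing size (ties by
smallest member id), and "major" modules are those with more than
`min_major_size = 10` nodes — a threshold that differs across published
figures, hence configurable. The resolution parameter is fixed at 1.

**Roles and keystones.** `Zi` standardizes the within-module degree by
its module's mean and *population* standard deviation (the standard
convention of the Zi–Pi framework); a module whose members all have the
same within-degree has sd 0 and Zi := 0. `Pi = 1 − Σ_m (κ_im/k_i)²` is
the participation coefficient. Role thresholds are Zi 2.5 and Pi 0.62
with hub inequalities strict in Zi and the connector inequality strict
in Pi, so boundary nodes fall into the lower category. Keystones are
nodes with degree strictly above 50 and raw betweenness strictly below
5000. Both thresholds are calibrated for networks of several hundred to
a thousand nodes; on small synthetic networks (module size 20 caps the
degree near 25) the keystone set is legitimately empty, which the
pipeline reports as a zero count rather than adjusting the cut-offs.

**Network dissimilarity.** Edge identity is the unordered OTU-id pair,
ignoring sign and magnitude. The default index is Whittaker's
`β_w = (a+b+c)/((2a+b+c)/2) − 1 = (b+c)/(2a+b+c)`, bounded in [0, 1];
the Jaccard distance `(b+c)/(a+b+c)` is available since the literature
uses several members of this family interchangeably.

**Rounding.** Every reported percentage uses half-up rounding to two
decimals (`round_half_up()`), not banker's rounding — 65.625% prints as
65.63 — matching how such tables are conventionally printed.

## The synthetic-data generator

`simulate_otu_table()` emulates the structure the analysis assumes: three
sample groups of 207/139/148 (defaults), thousands of OTUs spanning all
three abundance classes, and blocks of co-varying OTUs with designated
hub and connector nodes. Its mechanism, all on the log-abundance scale:

* **Baselines** are drawn i.i.d. normal (log-normal abundances) with
  σ = 2.5 by default, winsorized at the 99th percentile. The
  winsorization reflects that no real gut community is a single taxon;
  mechanically, an unchecked tail draw would hold most of the community
  mass, and its fluctuations would put shared noise into every
  proportion through the compositional denominator, destroying rank
  correlations wholesale.
* **Placement.** Planted modules occupy the upper-middle abundance band:
  the globally dominant core (the top ~1%, at least 10 OTUs) stays
  background, and module members take the next ranks — abundant enough
  that count noise cannot erase their correlations, small enough that
  their factor-driven swings leave no compositional footprint. Within a
  module, the hub and connectors take the median baselines for the same
  two-sided reason. All placements are permutations of the same draws,
  so the marginal abundance spectrum is untouched.
* **Module factors.** One latent factor per module per sample, with a
  common host-level component giving every factor pair correlation 0.3.
  The overlap is not a nuisance parameter: a random variable cannot
  correlate more than √½ ≈ 0.707 with each of two *orthogonal* factors,
  so under independent factors no connector could ever clear a 0.6 edge
  threshold toward two modules at once. Correlated guilds are also the
  biologically expected situation. Cross-module member correlations stay
  near `icc × 0.3 ≈ 0.27`, far below the edge threshold.
* **Loadings.** A full-loading member has loading
  `λ = noise_sd·√(icc/(1−icc))`, making the latent correlation between
  two such members exactly `icc` (`intra_module_correlation`). Ordinary
  members get multipliers U(0.3, 0.7) — the spread produces the
  within-module degree gradient real networks show once thresholding
  acts. Hubs carry the largest loading in their module (0.8) and
  connectors 0.7 plus a weaker 0.5 loading on a rotating second module
  (the asymmetry keeps their primary membership identifiable). Both are
  *low-noise trackers*: their idiosyncratic noise is scaled by 0.1. This
  is the deliberate core of the design — a node becomes a topological
  hub by tracking its guild's dynamics faithfully, not by fluctuating
  violently; a large loading would swing the node to community dominance
  and compositionally squash its own module.
* **Counts.** Each sample's expected abundances are multinomially
  sampled at `sequencing_depth`, so row sums equal the depth exactly.
  One `set.seed(config$seed)` at entry drives every draw.

Defaults the data do not dictate were fixed once: 3000 OTUs and depth
50000 per sample (typical of a 16S V4 amplicon study), 10 modules of 20
OTUs, noise_sd 0.5, σ 2.5 (σ ≥ 2 is what makes all three abundance
classes appear).

**What the generator does not emulate.** Group-specific composition:
all three synthetic groups sample the same community, so group networks
differ only by sampling noise — synthetic between-group dissimilarities
(~0.4) are far below those of real captive-versus-wild comparisons, and
synthetic ternary coordinates cluster near the centroid. Rare taxa in
networks: at realistic depths a taxon below 0.01% relative abundance
has single-digit counts and cannot carry a detectable rank correlation,
so synthetic networks are built almost entirely from abundant nodes; the
high rare-taxon fractions seen in real networks come from data regimes
(very many samples, deeper sequencing, larger communities) that the
desk-scale simulations do not reach. Passing the recovery tests
therefore shows the machinery is correct — not that real data would
yield these particular summary values.

## Validation strategy and problem sizes

Every statistic has an independent brute-force oracle in the test suite:
explicit ranking + Pearson sums for Spearman ρ, full `n!` permutation
nulls for its exact p, all-pairs BFS path counting for betweenness and
closeness, dense eigendecomposition for eigenvector centrality, direct
edge counting for Q, explicit neighbor counting for Zi/Pi, pair counting
and exhaustive labeling enumeration for Mann–Whitney, and exhaustive
search over all set partitions (n ≤ 8) for module detection quality.
Agreement is asserted at 1e-9 over hundreds of randomized instances.

Parameter recovery runs the full pipeline on a planted configuration —
4 modules of 20 OTUs among 300, intra-module correlation 0.9, groups of
207/139/148 samples, depth 50000 — and checks that the detected
partition matches the planted one (adjusted Rand index ≥ 0.8; in
practice 1.0 across seeds), and that planted connectors rank top in
among-module connectivity and planted hubs in within-module connectivity
(one-sided Mann–Whitney, p < 0.01). The 300-OTU problem size keeps the
correlation stage to a fraction of a second while leaving two thirds of
the community as background against which false structure would show.

Determinism is asserted end to end: two pipeline runs from the same
config and seed must produce byte-identical output files.

## Interface choices

The package is an R API in the style of the field's analysis packages
(`phyloseq`, `vegan`, `picante`): exported functions per stage plus the
`run_pipeline()` orchestrator, with `scripts/acceptance.R` as a worked,
scriptable entry point. `igraph` supplies the graph container, GraphML
I/O, degree/betweenness/shortest paths and the fast-greedy agglomeration;
the thresholded network construction, component-corrected closeness,
power-iteration eigenvector, refinement pass, Zi/Pi, role and keystone
classification, Whittaker dissimilarity, exact permutation tests and the
generator are implemented here.

## Known limitations

* Spearman on proportions inherits compositional effects; the package
  deliberately mirrors the plain-Spearman convention of the workflow it
  implements rather than substituting SparCC-style inference.
* Exact Spearman permutation p-values stop at n = 8 samples (40320
  permutations); beyond that only the t approximation is offered.
* Modularity maximization is a heuristic; the exhaustive-search guarantee
  (within 0.05 of the optimum) is only verified for graphs of ≤ 8 nodes,
  though the planted-structure recovery gives end-to-end evidence at
  realistic sizes.
* Keystone and role thresholds are fixed conventions; on networks whose
  size makes a threshold unreachable the corresponding set is empty by
  construction, and interpretation is left to the analyst.
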