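# pandanet

Co-occurrence network analysis of gut-microbiome OTU tables, built around
the workflow used to compare captive and wild giant panda populations
(GPCAP, GPMS, GPXXL): from a samples × OTUs count table to per-population
correlation networks, their modular structure, the topological roles of
individual taxa, and edge-level dissimilarity between networks.

## What it computes

Starting from an OTU count table with sample-group labels and taxonomy:

1. **Abundance profiling** — per-sample relative abundances, group means,
   and the standard three-way classification: *rare* (mean relative
   abundance < 0.01%), *abundant* (> 0.1%), *moderate* (inclusive bounds
   in between).
2. **Network construction** — the top 1000 OTUs per group by mean
   relative abundance; all pairwise Spearman rank correlations; an edge
   for every pair with |ρ| ≥ 0.6 and p ≤ 0.05 (two-sided t
   approximation, `t = ρ√((n−2)/(1−ρ²))`), signed by the direction of
   the correlation.
3. **Topology** — degree, raw betweenness centrality, component-corrected
   closeness, and max-normalized eigenvector centrality per node, with
   Mann–Whitney U tests for comparing node-feature distributions between
   networks.
4. **Modularity and modules** — Newman's
   `Q = Σ_s [ l_s/L − (d_s/2L)² ]`, maximized by agglomerative
   fast-greedy clustering plus a deterministic local-refinement pass;
   per-module taxonomic composition.
5. **Node roles** — within-module connectivity `Zi` (z-score of the
   within-module degree) and among-module connectivity
   `Pi = 1 − Σ_m (κ_im/k_i)²`; nodes are network hubs (Zi > 2.5,
   Pi > 0.62), module hubs (Zi > 2.5, Pi ≤ 0.62), connectors (Zi ≤ 2.5,
   Pi > 0.62) or peripheral. Keystone taxa are nodes with degree > 50
   and betweenness < 5000.
6. **Network dissimilarity** — Whittaker's edge-turnover index
   `β_w = (b+c)/(2a+b+c)` from shared (`a`) and unique (`b`, `c`) edges.
7. **Synthetic data** — a seeded generator
   (`simulate_otu_table()`) producing grouped count tables with a
   log-normal abundance spectrum and planted correlation modules with
   designated hub and connector nodes, so the entire pipeline is testable
   without external sequence data.

## Worked example

```r
library(pandanet)

cfg <- simulation_config(n_groups = 3, samples_per_group = c(60, 50, 40),
                         n_otus = 400, n_modules = 5, module_size = 15,
                         sequencing_depth = 20000, seed = 42)
sim <- simulate_otu_table(cfg)
res <- run_pipeline(sim$table, run_config(top_n = 200, seed = 42))
res$summary
```

```
 network n_nodes n_edges n_pos n_neg pct_pos pct_rare pct_abundant modularity
      GP      64     233   233     0  100.00        0       100.00  0.7390171
   GPCAP      72     263   260     3   98.86        0        95.83  0.7039497
    GPMS     108     267   248    19   92.88        0        68.52  0.7120944
   GPXXL      94     290   287     3   98.97        0        77.66  0.7602556
```

One row per network (the pooled `GP` network first): node and edge
counts, positive/negative edge split (strong positive correlations
dominate, as expected when modules are driven by shared latent factors),
the share of rare and abundant nodes among network members, and the
modularity of the detected partition — here ≈ 0.7, i.e. strongly modular,
as built in by the generator's five planted modules.

```r
res$dissimilarity
```

```
 network_a network_b shared unique_a unique_b dissimilarity
     GPCAP      GPMS    145      118      122     0.4528302
     GPCAP     GPXXL    159      104      131     0.4249548
     GPCAP        GP    199       64       34     0.1975806
      GPMS     GPXXL    143      124      147     0.4865350
      GPMS        GP    168       99       65     0.3280000
     GPXXL        GP    180      110       53     0.3116635
```

About half the edges are shared between any two group networks (the
groups sample the same planted community), and each group network sits
much closer to the pooled network than to the other groups.

Per-node roles, keystone flags, module composition and ternary
coordinates are in `res$roles`, `res$keystones`, `res$composition` and
`res$ternary`; `run_pipeline(..., out_dir = "out")` writes everything as
TSV plus GraphML networks and a run log.

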