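# dynppi

Dynamic protein–protein interaction (PPI) network analysis of
multi-model, multi-timepoint phosphoproteome data.

## The problem

Cross-disease pathology hunting: given quantitative phosphoproteomes of
several disease models (e.g. four FTLD and four AD mouse genotypes),
each profiled at several ages with replicate animals, which part of the
interactome *moves together* over time in most models of every disease
group? Static, single-timepoint network analysis cannot answer this;
`dynppi` implements a dynamic method that can.

## The method

For each model *m* and timepoint *t*:

1. **Differential sites.** Per phosphosite, Welch's t-test on log
   disease vs control replicate signals (N = 3), Benjamini–Hochberg
   adjustment within the model × timepoint analysis; sites with
   p < 0.05 (or q < 0.05) are *changed*.
2. **Pathological network.** Changed proteins seed a PPI subgraph: all
   seed–seed database edges, plus any single bridge protein adjacent to
   ≥ 2 seeds.
3. **Hubs.** Betweenness centrality *g(v)* = Σ<sub>s&lt;t</sub>
   σ<sub>st</sub>(v)/σ<sub>st</sub> on each network; a changed protein is
   *high* when g(v) > 0 (loose) or g(v) > mean + k·SD (strict, k = 2),
   in at least one of the model's timepoint networks.
4. **Trajectory edges.** Each site gets a 3D vector **v** of mean
   disease/control ratios at the three ages; an edge is *highly
   correlated* when r = |**v**₁·**v**₂|/(‖**v**₁‖‖**v**₂‖) ≥ 0.9 for
   some site pair of its endpoints.
5. **Core networks.** A node (edge) is core for a group when it is high
   (correlated) in ≥ 2 of the group's models; the common core requires
   ≥ 2 models of *every* group. Only nodes connected by core edges
   remain.
6. **Comparison.** Commonness of two cores =
   100·|A∩B|/|A∪B| over node sets; group-specific components by network
   subtraction.

Validity is quantified by a bootstrap commonness null (random core-sized
sets from the detected-protein universe, truncated-normal
standardization), hold-out / cross-validation node and edge precision,
leave-one-replicate-out MAE/RMSE of edge correlations, and
physical-interaction enrichment (one-sided Fisher exact test).

## Worked example

Fully synthetic, no downloads: simulate the eight-model study design with
a planted 30-protein core module, run the inference chain, and score the
result against the planted truth.

```r
library(dynppi)

sim <- simulate_study(seed = 1)        # 8 models x 3 timepoints x 3 replicates
res <- infer_core_networks(sim$quant, sim$db)

res$group_cores$FTLD
#> Core network [FTLD]: 42 nodes, 42 edges
res$group_cores$AD
#> Core network [AD]: 43 nodes, 44 edges
res$common_core
#> Core network [AD-FTLD-common]: 29 nodes, 34 edges
res$commonness
#> [1] 54.5   # % node commonness between the AD and FTLD cores

evaluate_recovery(res$common_core, sim$truth)[c("node_f1", "edge_f1")]
#> $node_f1 0.98   $edge_f1 0.96

null <- bootstrap_commonness_null(
  n_total = length(unique(sim$quant$protein_id)),
  n_a = 43, n_b = 42, reps = 10000, seed = 1)
null
#> Commonness null: 10000 reps, |universe|=385, |A|=43, |B|=42
#>   fitted mean 5.910%, sd 2.516% (moments)
commonness_zscore(res$commonness, null)
#> [1] 19.3   # SD above the random-overlap null
```

The two group cores share over half their nodes — 19 SD above what
random selection from the detected proteome would give — and both the
nodes and the wiring of the planted module are recovered almost exactly
(F1 ≈ 0.96–0.98). `run_pipeline()` wraps the same chain with file
outputs (TSV tables, GraphML/SIF networks, JSON summary);
`inst/scripts/dynppi` is a thin command-line front end.

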