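---
title: "Dynamic PPI network analysis of time-course phosphoproteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic PPI network analysis of time-course phosphoproteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynppi)
```

## The problem

Molecular network analyses of disease tissue are usually static: one
network, one time point. Neurodegenerative pathology, however, unfolds over
months, and the proteins that matter are the ones whose phosphorylation
state *moves together* as disease progresses. `dynppi` implements a
dynamic-network method for exactly this setting: several disease models
(e.g. four FTLD knock-in and four AD transgenic mouse genotypes), each
profiled by quantitative phosphoproteomics at several ages (1, 3 and 6
months) with a few replicate animals per time point, against a curated
protein–protein interaction (PPI) database. The goal is a *core network*
per disease group, and the *common core* shared across groups — a compact
candidate pathomechanism.

## The procedure

The pipeline has six inference steps, mirrored by the exported functions.

**Step 1 — differential phosphorylation** (`differential_phospho()`).
Channel intensities are bias-corrected so every reporter channel carries
the same total signal (`normalize_channels()`); fragment-level intensities
for one phosphopeptide are combined as a geometric mean
(`aggregate_fragment_intensities()`). Each phosphosite, within each model
× timepoint analysis, is tested by Welch's unequal-variance t-test on the
log signals of disease versus control replicates, with
Benjamini–Hochberg adjustment within that analysis. Each mass run is
treated as one hypothesis family — 24 analyses in the eight-model,
three-timepoint design — because sites observed in one run share its
technical conditions. Sites with p < 0.05 (optionally q < 0.05) are the
*changed* sites; the strict inequality matters only at exact-threshold
boundary cases. Whether the original analysis tested two samples of
signals or one sample of ratios is not determinable from the method's
description; both modes are implemented (`welch_mode`), and the two-sample
mode is the default. At three replicates per group the Welch test is
conservative (its true size under equal variances is near 0.034 at nominal
0.05); this is a property of the Welch–Satterthwaite approximation, not of
the implementation, and the test suite asserts type-I *control* at n = 3
and nominal attainment at larger n.

**Step 2 — pathological networks** (`build_pathological_network()`).
Changed proteins seed a PPI subnetwork per model × timepoint: all seeds,
all database edges between seeds, plus any non-seed protein adjacent to at
least two seeds, with its edges to those seeds. "One additional node" is
thus read as *at most one interposed bridge, and only where it bridges*:
a pendant neighbour touching a single seed adds no path information and
would only dilute the betweenness field. The requirement is configurable
(`min_seed_neighbors = 1`) for sensitivity analysis. Seeds absent from the
database are kept as isolated nodes — visible, but never hubs.

**Step 3 — hub selection** (`betweenness_scores()`,
`high_betweenness_nodes()`, `model_high_nodes()`). Node importance is
unnormalized shortest-path betweenness on the undirected, unweighted
graph (computed with igraph; the test suite checks it exhaustively against
a path-enumeration oracle on small graphs). A node is "high" either when
its score is positive (the loose condition) or when it exceeds
mean + k·SD of the scores in the same network (sample SD; k = 2 by
default for the strict rule, with k = 3 available). Because the threshold
is relative to scores within one network, the betweenness normalization
convention is immaterial. A protein is high *for a model* when it is high
in at least one of that model's timepoint networks: pathology need not
peak at the same age in every genotype, so evidence is OR-aggregated over
time. Only a network's own changed proteins are core-node candidates;
bridges shape the topology but cannot themselves become core nodes.

**Step 4 — trajectory edges** (`trajectory_vectors()`,
`cosine_correlation()`, `correlated_edges_for_model()`). Each site's
chronological change is the 3D vector of mean disease/control ratios at
the three ages. Two sites are highly correlated when the absolute cosine
of their vectors is at least 0.9 (non-strict). Raw ratios, not log ratios,
are the default vector components; note that cosine similarity between
all-positive vectors is systematically inflated (it is bounded below by
the cosine of the positive-octant opening angle), which is precisely why
the cutoff is as high as 0.9. A `log_space = TRUE` option exists for users
who prefer sign-symmetric components. An edge of the model's network is
selected when *any* cross-site pair of its two endpoint proteins passes
the cutoff; candidate pairs are restricted to network edges, since the
point of Step 4 is to select edges of the pathological network, not to
propose new interactions. Sites missing a timepoint are flagged incomplete
and excluded — with three points there is no principled imputation.

**Steps 5–6 — core networks** (`core_nodes()`, `core_edges()`,
`assemble_core_network()`, `commonness()`, `network_difference()`).
A node (edge) is *core* when it is high (highly correlated) in at least
`min_support = 2` models of every group considered: one group for a group
core network, both for the common core. After support filtering, only core
edges with both endpoints core survive, and nodes left isolated are
dropped: the core network is by definition connected evidence. Commonness
between two core networks is 100·|A∩B|/|A∪B| over node sets — the union
denominator is fixed by the method's own worked arithmetic (43 shared
nodes between cores of 73 and 62 give 100·43/92 = 46.7%). Subtracting the
common core from a group core (`network_difference()`) isolates
group-specific components. Significance tier (p-only versus q-supported)
and the number of analyses detecting each protein are carried as node
metadata, not used as filters.

## Validation machinery

`bootstrap_commonness_null()` draws, from the universe of detected
proteins, random "core" sets of the observed sizes (10,000 replicates by
default) and records each pair's percentage commonness. The observed
commonness is then standardized against a truncated-normal fit of that
null (`commonness_zscore()`).

**Why the truncated-normal fit excludes boundary atoms.** The bootstrap
commonness statistic is discrete: with a universe of 1,965 proteins and
sets of 73 and 62, roughly one draw in ten shares *no* protein at all,
producing an atom at exactly 0% and a gap up to the first attainable
positive value. A continuous truncated normal cannot represent an atom;
fitting its likelihood to all samples lets the boundary mass drag the
location down and the scale up, badly misdescribing the visible bell of
the distribution. `fit_truncated_normal()` therefore estimates location
and scale from the samples strictly inside the bounds. The default
estimator is moment-based (mean and SD of interior samples — the ordinary
normal fit whenever the data sit well inside the bounds, as the
parameter-recovery test at N(50, 5) checks); a truncation-corrected
maximum-likelihood mode (`method = "mle"`) is provided and is the right
choice when the data really are a censored continuous quantity. On the
standard null (1,965 / 73 / 62, 10,000 reps) the default fit gives
z ≈ 43 SD for an observed commonness of 46.7% — overlap this large is
essentially impossible under random selection, which is the point of the
test.

`node_edge_precision()` implements hold-out and cross-validation
comparison: the share of a validation network's nodes (edges) recovered by
the estimation networks, with `single_model_core_network()` providing the
minimal single-model analogue of a core network (its high nodes connected
by its correlated edges) for use as the validation side.
`correlation_error_cv()` quantifies replicate-level stability: the
replicate animals of one model are split (by default all leave-one-out
partitions, the only threefold scheme at N = 3), per-edge correlations are
recomputed from each side's mean trajectories, and MAE and RMSE over the
shared edges are reported (MAE ≤ RMSE always, by the power-mean
inequality — asserted universally in the tests).

`physical_interaction_enrichment()` asks whether core edges are supported
by a physical-interaction database more often than chance: a one-sided
Fisher exact test (hypergeometric upper tail) of `supported` annotated
pairs among `total_edges` draws from the protein-pair population. The
default margin uses the full n² ordered-pair population — matching the
printed arithmetic of the reference analysis (62,724/20,395² = 0.015%) —
with an unordered C(n, 2) mode available; the choice moves the expected
ratio by a factor of two but not the qualitative conclusion.

## The synthetic-data generator

`simulate_study()` emulates the structure of the motivating study without
any external download: 8 models in two groups of four, 3 timepoints,
3 replicates, ~500 background phosphosites and a planted 30-protein core
module, on a random PPI graph of 800 proteins and ~2,000 edges. These
problem sizes are the package's reference conditions for its end-to-end
tests. Design choices:

* **Trajectory profile library.** Planted sites follow one of three log2
  shapes — monotone increase `(-1.5, 0, 1.5)`, monotone decrease, or a
  3-month peak `(-0.75, 1.5, -0.75)` — scaled so `effect_size` equals the
  mean absolute log2 ratio (default 1.5). The three shapes exercise the
  cosine selector with realistic kinetics; cross-shape cosines on raw
  ratio vectors fall well below 0.9 while same-shape cosines stay above
  it under the default noise.
* **Planted wiring.** The module is three 10-protein clusters (one shape
  each), wired as a cycle plus two chords so every planted node lies on
  internal shortest paths and acquires positive betweenness. Ground-truth
  core edges are all database edges joining same-shape planted nodes;
  cross-shape edges are not recoverable by construction and are not truth.
* **Noise and dropout.** Replicate noise is log-normal (log2 SD 0.2);
  whole (site, model, timepoint) blocks drop out independently at rate
  0.05, mirroring per-analysis detection. Control signals are a fixed
  baseline, so the disease replicates carry all the variability.
* **What it does not emulate.** Real reporter-channel interference,
  peptide-identification errors, correlated biological noise across sites,
  shared-peptide ambiguity, or hub-biased detection. Passing the planted
  recovery test therefore demonstrates that the inference machinery is
  correct and well-calibrated, not that real data meet its assumptions.

With the defaults the pipeline recovers the planted common core at node
and edge F1 ≥ 0.8, and with `effect_size = 0` the common core is empty in
at least 95% of seeded runs — the two ends of the operating range.

## Defaults worth knowing

| parameter | default | why |
|---|---|---|
| `log_base` | 2 | proteomics convention; significance is base-invariant |
| `alpha` | 0.05 | strict inequality at the boundary |
| `sig_mode` | `"p"` | q < 0.05 available; tier carried as metadata |
| `betweenness_rule` (pipeline) | `"positive"` | see below |
| `k` (z rule) | 2 | strict hub condition; 3 available |
| `correlation_threshold` | 0.9 | non-strict; inflated-cosine regime |
| `min_support` | 2 per group | "at least two models of each group" |
| `bootstrap_reps` | 10,000 | null SE ≈ 0.01% on the commonness scale |

The pipeline's default betweenness rule is `"positive"` rather than the
strict z-rule: a mean + 2 SD cut selects only the top hubs of each
network by construction, so it can never recover a full module — the
strict rule is the right instrument for *ranking* hubs inside an already
assembled core (the loose-versus-strict contrast is itself informative,
e.g. which kinases survive the 2 SD cut), while group-level support
filtering supplies the specificity that keeps the loose rule clean.
`high_betweenness_nodes()` keeps the strict rule as its own default.

## Numerical and degenerate-input conventions

* Equal-constant groups in `welch_test()` return p = 1 by convention;
  one constant group is handled by the ordinary Welch statistic.
* Cosines are computed as `|v1·v2| / sqrt(sum(v1²)·sum(v2²))` — the
  product under a single square root keeps exactly representable
  boundary cases (e.g. cosine exactly 0.9) exact.
* BH ties are resolved by stable sort; q-values are permutation-invariant.
* An empty core network is a valid outcome everywhere downstream;
  `commonness()` of two empty networks and precision against an empty
  validation network are rejected as undefined rather than returned as 0.
* All randomness flows from a single integer seed per entry point;
  reruns with the same seed are byte-identical.

## Known limitations

* Protein identifiers are opaque strings; any accession mapping must
  happen upstream.
* Binary PPI edges only — no confidence weighting or directionality.
* The three-timepoint design is structural: more timepoints are accepted
  by `trajectory_vectors()` but the cosine-threshold calibration (0.9 in
  the inflated all-positive regime) has only been examined for 3D vectors.
* Hold-out precision on real deposited datasets is out of scope here; the
  operations that compute it are tested on synthetic data only.
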