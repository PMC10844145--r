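# bgcausal

Time-series causal discovery for thalamus–basal-ganglia BOLD panels.

Functional MRI yields one blood-oxygenation (BOLD) series per brain region,
and for deep nuclei — the basal ganglia motor circuit and its thalamic
partners — the causal questions (*who drives whom, at what latency, through
what kind of dependence*) cannot be answered by stimulation experiments.
`bgcausal` implements the statistical route end to end for region-of-interest
panels recorded in blocks across subjects and task conditions:

* **Preprocessing** — white-matter/ventricle nuisance regression,
  discrete-cosine high-pass at 0.009 Hz, per-subject mean-centring, and
  concatenation of same-condition blocks with Gaussian smoothing of the
  first/last 5 samples of each block.
* **PCMCI+ causal discovery** — PC-style condition selection followed by
  momentary conditional independence (MCI) tests for every ordered pair at
  lags 0..T (default T = 2, i.e. 3.2 s at TR = 1.6 s), with collider and
  rule phases orienting contemporaneous links. Three conditional-independence
  regimes: linear partial correlation (`parcorr`), Gaussian-process
  regression with distance correlation on residuals (`gpdc`), and
  nearest-neighbour conditional mutual information with a local permutation
  scheme (`cmiknn`). Significance is permutation-based throughout, with
  block shuffling that preserves autocorrelation (two-sided 0.01 for signed
  statistics).
* **Triangulation** — the three per-regime graphs are collapsed into
  relationship records classified by lag class (contemporaneous /
  single-delayed / double-delayed), causal role (causative / response /
  interactive / undefined), and nature: detected by partial correlation →
  *linear*; by GPDC but not PC → *non-linear*; by CMIknn only → *complex*.
* **Synthetic panels** — a seeded generator produces multi-subject
  block-structured panels from known lag-annotated causal graphs (linear,
  quadratic, and multiplicative-noise links, AR(1) hemodynamic smoothing,
  shared sub-0.009 Hz confounds), so every stage is testable without any
  data download.

## Worked example

Simulate a study-shaped panel (20 subjects, 2 conditions × 2 blocks × 100
volumes, 9 ROIs), preprocess the resting condition, and discover the graph
with partial correlation:

```r
library(bgcausal)

graphs <- default_study_graphs()
sim <- simulate_panel(graphs$resting,
                      study_subjects(20, condition_graph_overrides = graphs),
                      seed = 1)
cc <- preprocess(sim$panel, sim$confounds, condition = "resting")
cc
#> <concatenated panel: condition 'resting', 4000 samples x 9 ROIs, 40 blocks>

tg <- discover(cc, discovery_config(tau_max = 2, ci_method = "parcorr",
                                    seed = 1, n_permutations = 199))
dplyr::filter(tidy(tg), i != j)
#> # A tibble: 10 x 7
#>    i     j       lag mark             statistic p_value
#>    <chr> <chr> <int> <chr>                <dbl>   <dbl>
#>  1 Tal   Cau       2 directed            0.418    0.005
#>  2 Tal   Put       1 directed            0.495    0.005
#>  3 Put   GPe       1 directed            0.469    0.005
#>  4 GPe   STN       1 directed            0.389    0.005
#>  5 M1    GPi       2 directed           -0.0736   0.005
#>  6 S1    GPi       2 directed           -0.0804   0.005
#>  7 Tal   GPi       2 directed            0.114    0.005
#>  8 GPe   SN        1 directed            0.0400   0.01
#>  9 Cau   Tal       2 directed            0.335    0.005
#> 10 M1    S1        0 contemp_directed    0.756    0.005
```

The linear skeleton of the generative circuit comes back in full: the
thalamo-caudate reciprocal lag-2 pair, the thalamo-putaminal drive, the
striato-pallido-subthalamic chain, and the contemporaneous cortico-cortical
link oriented M1 → S1 by the collider/rule phases. The weak lag-2 links
into GPi are the linear trace of that node's *quadratic* afferent — partial
correlation alone cannot tell these apart, which is why nature labels come
from triangulating all three regimes — and the remaining small-statistic
link is an α-level false alarm of the kind the calibration tests bound.

The 4000-sample concatenation is the study's arithmetic: 100 volumes × 2
blocks × 20 subjects per condition. Each significant link records its
statistic, permutation p-value, and the conditioning set that produced it;
lagged links are oriented past→present, contemporaneous links by the
collider/rule phases (undirected ties and orientation conflicts are
reported as such — they become "undefined" relationships).

Running all three regimes and collapsing the graphs into the reporting
table for a thalamic seed:

```r
runs <- tidyr::expand_grid(method = c("parcorr", "gpdc", "cmiknn"),
                           task = "resting")
runs$graph <- purrr::pmap(runs, function(method, task)
  discover(cc, discovery_config(ci_method = method, seed = 1,
                                n_permutations = 199)))
rel <- build_relationship_table(runs, seed = "Tal")
rel
#> <relationship table: ...>
glance(rel)     # counts by nature, non-linear fraction
autoplot(rel)   # partner x lag-class map, coloured by nature
```

`run_pipeline(pipeline_config(out_dir = "run1"))` orchestrates the whole
thing (simulation or `read_panel()` input, both conditions, all methods,
per-seed subsetting) and writes graphs, `table.csv`, `summary.json`, and a
provenance file into the run directory.

## Package layout

| module | file(s) |
|---|---|
| synthetic data | `R/ground-truth-graph.R`, `R/simulate.R` |
| preprocessing | `R/preprocess.R` |
| CI tests | `R/ci-tests.R`, `R/gp.R`, `src/kernels.cpp` |
| PCMCI+ | `R/pcmci.R` |
| classification | `R/classify.R` |
| pipeline & plots | `R/pipeline.R`, `R/plots.R` |
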