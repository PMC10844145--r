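---
title: "Methods: causal discovery for thalamus–basal-ganglia BOLD panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: causal discovery for thalamus–basal-ganglia BOLD panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgcausal)
```

## The problem

Functional MRI gives one BOLD time series per region of interest (ROI), here
the nuclei of the basal ganglia motor circuit (M1, S1, Cau, Put, GPe, STN,
GPi, SN) and a thalamic seed. The scientific question is *directional*:
which nucleus drives which, at which latency, and through what kind of
functional dependence — linear, non-linear, or something more complex such
as heteroscedastic coupling. Direct experimental manipulation of deep
nuclei in awake humans is impossible, so the package implements
constraint-based *statistical* causal discovery on the recorded series:
PCMCI+, a two-stage algorithm built from conditional-independence (CI)
tests, run under three CI regimes of increasing generality, followed by a
triangulation step that uses the *pattern of which regimes detect a link*
to label the link's nature.

The package is organised as a pipeline of small tidy functions:

1. `simulate_panel()` / `read_panel()` — data in, as a block-structured
   tibble (subject × condition × block × volume × ROI).
2. `preprocess()` — nuisance regression, high-pass, per-subject centring,
   block concatenation with boundary smoothing.
3. `discover()` — PCMCI+ under a chosen CI regime.
4. `build_relationship_table()` — collapse the per-regime graphs into
   relationship records (lag class, causal role, nature).
5. `run_pipeline()` — the orchestrated end-to-end run with provenance.

## Generative model of the synthetic panels

Real recordings of this design are not redistributable, so the package
ships a generator whose output has the statistical structure the analysis
assumes. Each ROI follows

$$x_j(t) = \phi_j\, x_j(t-1) + \textstyle\sum_{\text{linear}} c\, x_i(t-\lambda)
  + \sum_{\text{quadratic}} c\, x_i(t-\lambda)^2 + \sigma_j\, s_j(t)\,\varepsilon_j(t),$$

with $s_j(t) = \prod_{\text{mult.}} (1 + |c\,x_i(t-\lambda)|)$ for
multiplicative-noise links and $\varepsilon \sim N(0,1)$. The per-node AR(1)
coefficient $\phi_j$ (default 0.4) stands in for hemodynamic smoothness; no
explicit HRF convolution is performed, and nothing is simulated at the
voxel level. Contemporaneous (lag-0) links are generated in topological
order, so the lag-0 subgraph must be acyclic. Construction rejects
non-stationary dynamics: the spectral radius of the companion matrix of the
reduced-form VAR must be below one.

The three link forms were chosen to give each detection regime one
canonical target: a linear link is what partial correlation is built for; a
quadratic link is invisible to correlation (for a symmetric source,
$\mathrm{corr}(x, x^2) = 0$) but an easy target for distance correlation on
GP residuals; a multiplicative-noise link leaves both the mean and the
correlation untouched and is the textbook case for a mutual-information
detector — and is the kind of heteroscedasticity BOLD noise is known for.

Every block additionally receives a shared low-frequency confound — three
sinusoids with frequencies drawn below 0.009 Hz plus a linear drift, with
per-ROI loadings uniform in [0.5, 1.5] — returned separately the way a
white-matter/ventricle mean signal would be, so the preprocessing stage has
something real to remove. Blocks are generated independently (they are
separate recordings), each with a 50-step burn-in, and per-block seeds are
derived from the master seed by a counter, so extending the subject roster
never changes existing subjects' data.

Defaults mirror the study design throughout: 20 subjects, two conditions
(resting, motor), 2 blocks per condition of 100 volumes at a repetition
time of 1.6 s, 9 ROIs — concatenating to 4000 samples per condition.

What the generator does *not* emulate: non-stationarity across the session,
subject-level heterogeneity of coupling strengths, empirical HRF shapes and
their regional variation, and image-space artefacts (motion, registration).
Tests passing on these panels therefore show the *methods* behave as
specified, not that real recordings would yield any particular network.

## Preprocessing

The stages run in a fixed order — confound regression, high-pass,
centring, concatenation — each deterministic and shape-preserving until
concatenation:

* **Nuisance regression** (`regress_confounds()`): per block and ROI, OLS
  residuals on an intercept plus the confound series.
* **High-pass at 0.009 Hz** (`highpass()`): projection onto the complement
  of the discrete-cosine basis functions with frequency below the cutoff,
  per block. On 160-s blocks an IIR filter would spend most of the block in
  its edge transient; the projection is transient-free, exactly linear, and
  bit-reproducible. The constant term is part of the removed subspace, so
  every block/ROI comes out mean-zero, and an explicit linear-drift column
  is part of the removed subspace (the low-order cosines alone leave about
  12% of a ramp's energy behind). One inherent cost: a pass-band signal in
  sine phase relative to the block loses some edge energy to the low-order
  terms (about 17% RMS on a 100-volume block at 0.05 Hz), while
  cosine-phase signals pass exactly.
* **Per-subject centring** (`center_per_subject()`): each subject's
  same-condition samples are centred jointly. "Normalising around the
  mean" is read as centring *without* variance scaling, because the CI
  statistics used downstream are scale-equivariant (partial correlation)
  or rank-based (CMI); a `zscore = TRUE` switch exposes the alternative.
* **Concatenation** (`concatenate_blocks()`): blocks join in lexicographic
  (subject, block) order — recorded in the output so runs are reproducible
  — and only the first and last 5 samples of each block are replaced by a
  Gaussian moving average of window 5 computed on the concatenated series,
  deliberately mixing adjacent blocks to soften the join. The window is
  the conventional size-5 Gaussian kernel with $\sigma = 1$ sample. A
  block contributes at most 10 smoothed samples per ROI.

Lag windows that span a block boundary are *not* excluded by default — the
boundary smoothing exists precisely to make joins benign — but
`mask_boundaries = TRUE` removes them for sensitivity analyses.

## Conditional-independence tests

All three regimes test $x_i(t-\lambda) \perp x_j(t) \mid Z$ on aligned
lagged copies and share one significance scheme: permutation with
autocorrelation-preserving structure, at a two-sided level of 0.01 for the
signed partial correlation and one-sided for the non-negative statistics.

* **parcorr** — Pearson correlation of the OLS residuals of the two targets
  on [intercept, Z]. Null: the residual series is cut into contiguous
  blocks and the blocks reordered uniformly (block shuffle). The block
  length is the smallest lag at which the residual autocorrelation falls
  below $2/\sqrt{n}$, clamped to $[1, n/20]$.
* **gpdc** — each target is regressed on `Z` by a Gaussian process with an
  RBF plus white-noise kernel; the statistic is the distance correlation
  (V-statistic, classical double-centering form) of the residual pair.
  Hyperparameters maximise the marginal likelihood over a deterministic
  grid anchored at the median-heuristic length-scale (factors 1/4–4, noise
  variance 0.01–1 on standardized responses, bounds $[10^{-2}, 10^{2}]$
  and $[10^{-5}, 10]$); grid search keeps the fit at 25 Cholesky
  factorisations, reproducible, and free of restart-to-restart noise. With
  empty `Z` the residuals are the standardized variables themselves.
* **cmiknn** — Frenzel–Pompe nearest-neighbour conditional mutual
  information with maximum-norm balls on rank-transformed (uniform-score)
  columns; the rank transform makes the statistic exactly invariant under
  monotone transforms. The default $k = \max(5, 0.1\,n)$ is the
  variance-reducing testing regime; for *estimation* a small $k$ (5–10) is
  appropriate, and `cmi_knn(..., k = 10)` reproduces
  $-\tfrac12\log(1-\rho^2)$ on Gaussian pairs. The null is the local
  permutation scheme — source values swapped only among samples whose `Z`
  coordinates are mutual nearest neighbours, preserving the X–Z dependence
  — when `Z` is non-empty; with empty `Z` there is no X–Z dependence to
  preserve and an i.i.d. shuffle would ignore autocorrelation, so the null
  block-shuffles the source exactly as the other tests do.

The quadratic-cost statistics (gpdc, cmiknn) subsample a seeded
*contiguous* window of at most `max_samples` rows (default 500); a
contiguous window, unlike random thinning, preserves the autocorrelation
the permutation null must respect.

Analytic p-values (e.g. Student-t for partial correlation) exist for
cross-checks, but the permutation path is the canonical one: BOLD series
are autocorrelated and the i.i.d. assumption behind the analytic forms
demonstrably inflates false positives (the suite measures this directly).

## PCMCI+ discovery

`discover()` runs three stages under one `discovery_config()` (defaults:
maximum lag $T = 2$, i.e. 3.2 s at the study's sampling; $\alpha = 0.01$
for both phases; unlimited conditioning-set size, adequate for 9 nodes):

1. **Condition selection** — a PC-style iterative pruning per target,
   lagged and contemporaneous candidate pools processed separately; at
   iteration $q$ each surviving candidate is tested given the $q$
   strongest other survivors (ties broken by node index and lag, so reruns
   are deterministic). The contemporaneous pass conditions additionally on
   the already-selected lagged parents.
2. **MCI tests** — every ordered pair and lag is tested given the selected
   parents of the target (minus the source) plus the lag-shifted parents
   of the source. Where the pair has selected contemporaneous neighbours
   the test runs under both the lagged-only and the augmented conditioning
   set and keeps the larger p-value. This conservative duplication
   addresses a real dilemma: conditioning on an undirected contemporaneous
   neighbour opens a collider through the target's own autocorrelation
   whenever that neighbour is in truth the target's child, while *not*
   conditioning lets dependence leak through contemporaneous mediators. A
   genuine link is dependent under both sets, so power is barely affected.
3. **Orientation** — lagged links point past→present by time order.
   Contemporaneous links go through a collider phase and a rule phase.
   Whether the middle node of an unshielded triple separates the outer
   pair is decided by explicit CI tests on the data (outer pair tested
   with and without the middle node at lag 0), because the lagged
   selection phase can never place a lag-0 variable in a stored separating
   set — relying on stored sepsets alone would over-fire the collider
   rule. Independence without the middle node ⇒ collider (tie oriented
   into it); independence only with it ⇒ mediator (lagged triples orient
   the tie out of it). Meek-style propagation follows. Contradictory
   demands yield an explicit `contemp_conflict` mark — undirected and
   conflicted links are first-class outcomes, reported as "undefined"
   relationships, never resolved by statistic size.

Every CI test derives its seed from the configuration seed and a test
counter, so a discovery run is bit-reproducible and insensitive to
evaluation order.

## Relationship classification

`build_relationship_table()` restricts each regime's graph to links
incident to the seed ROI and collapses across regimes at the granularity
(seed, partner, task, lag class, direction):

* lag class: 0 → contemporaneous, 1 → single-delayed (1.6 s),
  2 → double-delayed (3.2 s);
* role: undirected/conflicted → *undefined*; directed out of / into the
  seed → *causative* / *response*; delayed links both ways at one lag →
  *interactive* (one record);
* a lag-0 undirected tie is absorbed into a directed contemporaneous
  record of the same pair when one exists — the directed finding is the
  stronger statement, and its detecting methods define the record;
* nature, by the triangulation rule: detected by partial correlation →
  *linear*; by GPDC but not PC → *non-linear*; by CMIknn only → *complex*.

Statistics are normalised per method by the maximum absolute value among
significant links (a `rank` scheme is available for comparison), mapping
into [0, 1]; signed statistics keep their sign in a separate column, since
a signed value cannot live on a [0, 1] scale. The rule is a heuristic:
distance correlation does have some power against heteroscedastic
dependence, and correlation has a little against strong quadratic links
(the sampling variance of the correlation of dependent-but-uncorrelated
pairs exceeds its permutation null), so single-run labels are noisy; the
suite therefore checks *modal* labels across seeded runs.

The packaged fixture `table2_links.csv` is a hand transcription of the
published per-method link lists for the three thalamic seeds; collapsing
it yields 57 relationships, 35 of them non-linear or complex. Cells where
the printed sources disagree were resolved once, against the published
totals, and are commented in the fixture header.

## Benchmark problem sizes

The suite's heavier checks use fixed, documented sizes chosen to finish on
a desk machine:

* size calibration: 500 replicates per regime on AR(1) ($\phi = 0.8$)
  independent pairs, $n = 1200$ with 199 permutations (parcorr), $n = 800$
  with 99 (gpdc), and $n = 300$ with 99 (cmiknn);
* 9-node linear recovery: 20 seeded runs at $n = 4000$, 99 permutations;
* nature triangulation: 20 seeded runs of a 4-node mixed-form graph at
  $n = 4000$, with GP subsamples of 200 (the GP fit is cubic in $n$) and
  CMI subsamples of 400 (quadratic in $n$);
* sensitivity ordering: 200 replicates at $n = 500$ with link strengths
  0.16 (linear) and 0.2 (quadratic), chosen so no regime saturates.

## Known limitations

* Causal sufficiency is assumed; latent contemporaneous confounders
  surface as conflicts or undefined links, not as discoveries.
* The block-shuffle null is slightly liberal when the block count is small
  (short series with long memory); the calibration check bounds this at
  the sizes above.
* GPDC power against pure variance coupling is not zero, so the
  linear/non-linear/complex triangulation is a preponderance-of-evidence
  label, not a partition of mechanism space.
* Orientation of contemporaneous links depends on the presence of lagged
  parents or unshielded triples; a two-node contemporaneous system is
  undecidable by design and stays "undefined".
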