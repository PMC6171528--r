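---
title: "Methods: MIC connectomes, weighted graph topology, and trait association with external validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MIC connectomes, weighted graph topology, and trait association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis in one paragraph

`micnet` implements a four-stage pipeline for relating resting-state
functional connectomes to five-factor-model (FFM) personality traits.
Per participant, the dependence between every pair of network-node time
series is summarised by the maximal information coefficient (MIC), giving a
symmetric connectivity matrix. Each matrix is treated as a fully weighted
graph and reduced to four local measures per node — strength, Onnela
clustering, local efficiency, betweenness centrality — plus three global
node-averages. On a random 70% training split, each graph measure is
regressed on the five trait scores with age and sex as nuisance covariates;
per-trait p values are controlled at a false discovery rate of 1% by the
Benjamini–Hochberg step-up. The fitted models then predict the held-out 30%
of participants' graph measures from covariates alone, and the relative
root-mean-square error (RRMSE) quantifies generalization. A synthetic-cohort
generator reproduces the statistical structure of the inputs so every stage
is testable end to end.

# MIC estimation

For paired samples $(x_i, y_i)_{i=1}^n$, an axis-aligned $n_x \times n_y$
grid induces a discretization whose mutual information is the plug-in
estimate
$$I = \sum_{jk} p_{jk} \log_2 \frac{p_{jk}}{p_{j\cdot}\,p_{\cdot k}}.$$
The characteristic value of a grid dimension is the maximum of
$I / \log_2 \min(n_x, n_y)$ over all cut placements, and
$$\mathrm{MIC}(x, y) = \max_{n_x n_y \le B(n)}
  \frac{\max_G I(G)}{\log_2 \min(n_x, n_y)},$$
with a resolution bound restricting how fine the grids may get. MIC lies in
$[0,1]$, is symmetric, and responds to any functional form of dependence —
the reason it is preferred here over Pearson correlation, which a purely
quadratic or sinusoidal coupling can leave at zero.

Two search modes are implemented natively (C++ via Rcpp):

* **Heuristic** (`mode = "heuristic"`, the default): the MINE-style
  approximation. One axis is mass-equipartitioned into $q$ rows; the other
  axis is optimized by dynamic programming over *clumps* — maximal runs of
  x-consecutive points sharing a row, with tied x-values never split. The
  per-bin contribution to $H(P) - H(P,Q)$ is additive, so the DP is exact
  for the fixed row partition. Both axis orderings are tried and the
  characteristic matrix takes the elementwise maximum. The number of DP
  states is capped at `c` times the allowed column count by merging clumps
  into superclumps.
* **Exhaustive** (`mode = "exhaustive"`): enumerates every admissible cut
  set on both axes. Cost grows combinatorially; it is practical for
  $n \lesssim 20$ and serves as the independent oracle in the test suite.
  By construction the heuristic can never exceed it, and the suite reports
  the realized gap.

Tunable parameters, with defaults and rationale:

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.6 | Resolution bound $B(n) = \max(4, \lfloor n^{\alpha}\rfloor)$; the convention of the original MINE statistic. At the full series length of 4,800 timepoints, $B = 161$. |
| `c` | 15 | Clump factor bounding the DP state count; the original MINE default. Larger values search more grids at higher cost. |
| `mode` | heuristic | Exhaustive search is infeasible beyond tiny $n$. |

Numerical conventions: cuts fall only between distinct consecutive order
statistics, so ties are never split across bins (this also makes both modes
depend on the data only through rank orderings — MIC is exactly invariant
under strictly increasing transforms of either variable). The connectivity
matrix's diagonal is forced to zero: $\mathrm{MIC}(x,x) = 1$, but
self-edges would corrupt strength and clustering downstream. A constant
node series has no defined dependence; its row and column are zeroed with a
warning rather than aborting a whole cohort. Series shorter than 8 points
are rejected. No detrending, filtering, or autocorrelation correction is
applied before MIC; the estimator consumes the node signals as given.
Autocorrelation does inflate the effective dependence between smooth
series, which is one reason absolute MIC values here should be compared
within, not across, acquisition protocols.

# Weighted graph measures

All measures operate on the raw MIC matrix as a complete weighted graph —
no thresholding or binarization, so no arbitrary sparsity parameter enters
the pipeline.

* **Strength**: row sums of the weight matrix.
* **Clustering** (Onnela geometric-mean form): with weights normalized by
  the network maximum, $\hat w = w/\max(w)$,
  $C_i = \sum_{jh}(\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3} / (k_i(k_i-1))$,
  zero for nodes with fewer than two neighbours. Max-normalization keeps
  $C_i$ scale-free: multiplying all weights by a constant leaves it
  unchanged.
* **Path lengths**: $\ell_{ij} = 1/w_{ij}$, the Brain Connectivity Toolbox
  convention — strong coupling reads as a short path; an absent edge is
  infinitely long.
* **Betweenness**: fraction of shortest paths between other node pairs
  passing through a node, computed on $1/w$ lengths with every co-optimal
  path counted (Brandes accumulation via igraph; no tie-breaking).
  Normalized by $(N-1)(N-2)/2$ to a $[0,1]$ fraction; the raw dependency
  sum is emitted alongside (`betweenness_raw`) for transparency.
* **Local efficiency**: the global efficiency (mean inverse shortest-path
  length over ordered pairs) of the subgraph induced by a node's
  neighbours; zero for nodes with fewer than two neighbours. The plain
  inverse-length form is used, not the cube-root variant some toolboxes
  later adopted; the choice is recorded in the run manifest's decision
  flags so results can be regenerated under alternatives.
* **Global measures**: arithmetic node-means of strength, clustering and
  local efficiency. Betweenness has no global counterpart in this set.

Scale behaviour, useful as a quick sanity check: under $w \mapsto \lambda w$,
strength and local efficiency scale by $\lambda$, clustering and
betweenness are invariant. On a complete graph with equal weights,
betweenness is identically zero (the direct edge $1/w$ always beats any
two-hop path $2/w$), which is why meaningful betweenness variation requires
heterogeneous weights.

# Group-level inference and external validation

The cohort is partitioned once into training (70%) and test (30%) sets;
sizes use round-half-up, so 818 participants split 573/245. On the
training sample only, each of the 63 outcomes (15 nodes × 4 local measures
+ 3 global measures) is regressed by OLS on the five trait scores plus age
(z-scored on the training sample; the standardization parameters are
stored) and sex (0/1, unstandardized). Per coefficient, $t = \hat\beta /
\mathrm{SE}$ on $n - p$ degrees of freedom gives a two-sided p value.

**FDR family.** Adjustment is applied within each trait, across that
trait's 63 outcomes. One family per tested predictor keeps the correction
interpretable (each trait's discovery set is controlled at 1% on its own)
and is the package default; pooling all traits into one family would be
more conservative for a single-trait signal.

**External validation.** The fitted coefficients and the *training*
standardization parameters map test-split covariates to predicted graph
measures; test-split imaging-derived data are never read during fitting
(the test suite proves this by poisoning the test rows and asserting
byte-identical fits and predictions). Prediction error per outcome is
$$\mathrm{RRMSE} = \frac{\sqrt{n^{-1}\sum(y_i - \hat y_i)^2}}
 {\sqrt{n^{-1}\sum y_i^2}},$$
the root-mean-square error normalized by the root-mean-square of the
observations, so a predictor that outputs zero scores exactly 1 and a
perfect predictor scores 0. Normalization by the mean or the range is
selectable (`rrmse_norm`); the norm-ratio form is the default because
graph measures are strictly positive with large means, making the ratio
stable. Outcomes whose observed test values are identically zero (possible
for betweenness at short series lengths) have no scale under this
definition and yield `NA` rather than an aborted run.

**Facet analysis.** Post hoc models replace the conscientiousness score
with one of its facets (Order, Dutifulness, Achievement striving,
Self-Discipline), keeping the four other traits, age and sex as nuisance.
The conscientiousness total is excluded from these designs — the facets
are its components, and including both invites exact or near collinearity,
which the fitting routine treats as an error, naming the offending
columns. FDR is applied within each facet family. The graph measure is the
model outcome and the facet a predictor; the symmetric reading (facet as
outcome) is algebraically a different model, and the package exposes the
measure-as-outcome form because it matches the main scan's structure.

**Degenerate fits.** A constant outcome (zero residual variance) carries
no evidence for any association: its zero coefficients are assigned
$p = 1$ and any exact nonzero coefficient $p = 0$, rather than propagating
0/0.

# The synthetic cohort

The generator emulates the statistical structure the analysis assumes, at
configurable scale:

* **Traits, item-first.** Each factor score targets a Gaussian with
  configured mean/SD (defaults: plausible adult questionnaire norms on the
  0–48 sum scale, e.g. conscientiousness 34 ± 6 — deliberately *not*
  claimed to match any particular cohort), rounded and clamped to the
  attainable range, then decomposed into 12 Likert items (levels 0–4)
  that sum to it exactly, with sum-preserving mass shuffling so item
  profiles are non-degenerate. This mirrors how NEO-FFI factor scores are
  assembled and makes item-level invariants (60 items, 12 per factor,
  bounds) testable. A direct-Gaussian mode skips item assembly for speed.
* **Facets** load on the standardized conscientiousness factor at a
  configurable correlation (default 0.7).
* **Covariates.** Age uniform on 22–37; sex Bernoulli(½), independent of
  traits by default, with an optional sex→trait mean shift for exercising
  the nuisance-covariate adjustment.
* **Time series.** Per run, node signals are drawn i.i.d. over time from a
  multivariate normal whose correlation matrix has a common baseline
  (default 0.3) except that each *effect node's* correlations equal
  `base_coupling + effect_size * z`, with `z` the participant's
  standardized effect-trait score; runs (default 4 × 1,200 timepoints) are
  independent and concatenated. Designated node pairs can instead carry a
  quadratic or sinusoidal dependence, which leaves Pearson correlation
  near zero but is visible to MIC — the generator's way of exercising the
  detector beyond linearity.
* **Admissibility.** The implied correlation matrix must be positive
  definite. With three effect nodes out of 15 at baseline 0.3 the
  modulated coupling tolerates increments up to about ±0.18, so
  `effect_size` times the largest trait z-score must stay inside that
  margin; configurations or individual participants violating it raise an
  error naming the participant rather than silently clipping.

What the generator does **not** emulate: temporal autocorrelation and
hemodynamics (signals are white in time), scanner noise structure,
head-motion artefacts, inter-node coupling heterogeneity beyond the single
baseline, and any spatial structure. Consequently, passing tests
demonstrate that the estimator, graph measures and inference machinery are
correct and well-calibrated on data satisfying the model's assumptions —
they do not certify effect sizes or RRMSE magnitudes on real
neuroimaging data, where autocorrelation alone changes MIC's sampling
distribution.

# Statistical design of the test suite

Oracles are independent of the code paths they check: exhaustive grid
enumeration for MIC; depth-first enumeration of all simple paths for
betweenness and local efficiency (all graphs up to 7 nodes, 100 random
draws); a literal step-up implementation for Benjamini–Hochberg; `lm()`
for the OLS fits.

Power analysis for the planted effect, computed with a metric-level
simulation before the tests were frozen: at a partial correlation of .15,
training n = 573, and within-trait BH over 63 outcomes at q < .01, the
probability that one *specific* outcome is flagged is only ~55–60% — a
property of the step-up threshold at this family size, essentially
unchanged by correlation among outcomes. The planted coupling, however,
moves strength, clustering and local efficiency of all three effect nodes
(nine outcomes), and the probability that the scan flags the trait on at
least one of them exceeds 95%. The acceptance check therefore tests
*detection of the planted effect* (any planted outcome flagged), at 200
replicates against a 80% floor; replicate-level simulations are
metric-level because pushing 200 × 573 participants through MIC is
computationally out of scope and adds nothing to the scan's calibration.

Problem sizes in the default test run are deliberately modest — e.g.
MIC matrices on 80–240 timepoints, pipeline runs with 20–40 participants
at 6–15 nodes, 200 power replicates — the package's chosen balance
between suite depth and turnaround; the full 4 × 1,200 geometry is
validated on a single participant where the check concerns shape, not
sampling error.

# Known limitations

* The heuristic MIC can undershoot the exhaustive value noticeably at very
  small n (gaps up to ~0.3–0.5 in the suite's random cases); this is
  inherent to equipartition-based search and shrinks in relative terms as
  n grows. Exhaustive mode exists precisely to quantify it.
* Betweenness on near-homogeneous weight matrices is zero-inflated; at
  short synthetic series lengths some nodes' betweenness is identically
  zero across participants, which the inference stage treats as a no-scale
  outcome rather than a signal.
* OLS with FDR is the inference model by design; no permutation inference,
  mixed models, or family-structure corrections are provided.
* MIC values are not significance-tested individually; the package makes
  no claim about edge-level "significant connections".
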