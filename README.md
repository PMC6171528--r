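# micnet

Connectome-wide association of personality traits with MIC-based
functional connectivity, in R.

`micnet` is for researchers who have per-participant time series of a
modest number of large-scale brain network nodes (e.g. ICA-derived
circuits from resting-state fMRI) together with questionnaire and
demographic covariates, and who want a fully reproducible path from those
inputs to trait–connectome associations with honest external validation.
The package also ships a synthetic-cohort generator that reproduces the
statistical structure of such inputs, so the entire pipeline can be
exercised, tested and calibrated without access to restricted imaging
data.

## What it computes

1. **Connectivity — maximal information coefficient.** For each pair of
   node time series $x, y$, over all axis-aligned $n_x \times n_y$ grids
   with $n_x n_y \le B(n) = \max(4, \lfloor n^{0.6} \rfloor)$,

   $$\mathrm{MIC}(x,y) = \max_{n_x n_y \le B(n)}
     \frac{\max_G I(G)}{\log_2 \min(n_x, n_y)} \in [0, 1],$$

   where $I$ is the plug-in mutual information of the grid's cell counts.
   Unlike Pearson correlation, MIC responds to nonlinear dependence:

   ```r
   x <- seq(-1, 1, length.out = 200)
   cor(x, x^2)   # 0
   mic(x, x^2)   # 1
   ```

   The search uses a native implementation of the MINE
   equipartition-plus-dynamic-programming heuristic (clump factor
   `c = 15`), with an exhaustive small-sample mode that serves as the
   exact oracle in the test suite. The result per participant is a
   symmetric N×N matrix with zero diagonal.

2. **Weighted graph topology.** Each matrix is analysed as a complete
   weighted graph: nodal strength (row sums), Onnela geometric-mean
   clustering (max-normalized weights), local efficiency (global
   efficiency of each node's neighbour subgraph) and betweenness
   centrality (fraction of shortest paths through the node, on `1/w`
   edge lengths, all co-optimal paths counted), plus global measures
   defined as node-averages of strength, clustering and efficiency.

3. **Trait association with external validation.** On a 70% training
   split, each of the 63 graph outcomes is regressed on the five
   five-factor-model trait scores with age and sex as nuisance
   covariates; Benjamini–Hochberg FDR is applied per trait across its 63
   outcomes at q < .01. The fitted models then predict the held-out 30%
   of participants' graph measures from covariates alone, scored by the
   relative root-mean-square error
   $\mathrm{RRMSE} = \mathrm{RMSE}(y, \hat y) / \mathrm{RMS}(y)$.
   A post hoc facet scan repeats the analysis with each
   conscientiousness facet (Order, Dutifulness, Achievement striving,
   Self-Discipline) in place of the conscientiousness total.

## Worked example

Simulate a 60-participant cohort in which conscientiousness modulates the
coupling of the fronto-parietal and default-mode stand-in nodes
(`effect_size = 0.04` coupling increment per trait SD), run the full
pipeline, and inspect the scan:

```r
library(micnet)

cfg <- pipeline_config(
  cohort    = list(n_participants = 60, n_runs = 2,
                   timepoints_per_run = 150,
                   effect_size = 0.04, seed = 42),
  inference = list(seed = 42),
  io        = list(output_dir = "demo_run"))

res <- run_pipeline(cfg)
print(res$scan)
#> Trait-connectome association scan
#>   training n = 42, test n = 18
#>   63 outcomes x 5 families; 19 association(s) significant at q < 0.01
#>   median test-split RRMSE = 0.034 (rms norm)

head(summary(res$scan)$significant[, c("outcome", "family", "beta", "t", "q")])
#>             outcome            family   beta    t        q
#>   left_FPN.strength conscientiousness 0.1607 8.63 1.74e-08
#>        DMN.strength conscientiousness 0.1442 8.55 1.74e-08
#>  right_FPN.strength conscientiousness 0.1781 7.49 2.28e-07
#>  ...
```

The planted effect surfaces exactly where it was injected: the strength
(and, downstream, clustering/efficiency) of the three effect nodes is
positively associated with conscientiousness and with no other trait,
while the median RRMSE of 0.034 says the covariate-only model predicts
test-split graph measures to within ~3% of their root-mean-square scale.
Every stage's tables (`participants.csv`, per-participant connectivity
TSVs, `metrics.tsv`, `associations.tsv`, `validation.tsv`) and a manifest
with config hash, seeds and methodological decision flags are written
under `demo_run/`.

The same stages are scriptable from a shell via the thin CLI in
`inst/cli/micnet.R` (`simulate`, `connectivity`, `metrics`, `scan`,
`run-all`).

## Method vignette

`vignettes/methods.Rmd` documents the estimator, the graph measures, the
inference model, every numerical convention (resolution bound, tie
handling, edge-length map, normalizations, FDR family, RRMSE definition),
the synthetic generator's scope and its limitations.
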