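# shorestab

Stability decomposition and piecewise structural equation modelling for
paired-tile intertidal community experiments.

## What this package is for

Field experiments on rocky shores ask whether substrate heterogeneity
(pitted vs. flat settlement tiles, paired at stations along an
emersion-stress gradient) stabilises the community that assembles on
them.  Answering that requires more than a treatment contrast: temporal
stability has to be decomposed into its mechanisms, and the treatment's
influence traced through the community along competing causal routes
that may cancel.  `shorestab` provides that full workflow for
percent-cover survey data:

* **Per-tile stability decomposition.**  With per-taxon covers
  detrended linearly on the census index (means `mu_i`, residual SDs
  `sigma_i`, total-series SD `sigma_T`):
  temporal stability `TS = mu_T / sigma_T` (the inverse coefficient of
  variation), population stability `PS = sum(mu_i) / sum(sigma_i)`,
  Loreau–de Mazancourt synchrony `phi = sigma_T^2 / (sum sigma_i)^2`
  (asynchrony `1 - phi`), statistical averaging
  `SA = sum(sigma_i) / sqrt(sum(sigma_i^2))`, and compositional
  stability `CS = 1 -` mean consecutive Bray–Curtis dissimilarity.
  The shared detrending makes `TS = PS * phi^(-1/2)` hold exactly.
* **Treatment models.**  `response ~ z(heterogeneity) * z(emersion) +
  (1 | transect/station)` by REML with Satterthwaite p values and
  marginal/conditional R².
* **Multigroup piecewise SEM.**  A DAG over tile-level variables,
  component mixed models per endogenous node, Shipley basis-set
  d-separation tests, Fisher's `C = -2 sum(log p)` with `2k` df,
  standardised path coefficients, and per-shore-zone free/constrained
  paths decided by path-by-zone interaction tests.
* **Cascading effects.**  Net effect of heterogeneity on each
  stability metric as the sum of products of significant standardised
  path coefficients along all causal chains, with cluster-bootstrap
  (station-resampling) percentile intervals.
* **A synthetic community generator** with configurable ground-truth
  pathways (refugia, richness, dominant suppression, consumer
  suppression), so the entire pipeline is testable without any
  download, plus a linear-Gaussian SEM simulator for exact
  coefficient-recovery studies.

## Worked example

```r
library(shorestab)

design <- generate_design(n_transects = 5, stations_per_transect = 7,
                          emersion_range = c(0.1, 0.9), seed = 1)
covers  <- simulate_covers(design, synth_params(seed = 42))
tiles   <- tile_table(design,
                      summarise_tiles(covers, default_group_map()),
                      stability_profiles(covers))

fit <- psem(default_sem_spec(), tiles, group = NULL)
fit
#> Piecewise SEM fit: 11 nodes, 28 edges, global
#> Fisher's C = 246.38, df = 50, p = 0.000 (25 claims)
#> 3 singular component fit(s) retained

cascade_effect(fit, "het", "temp_stability")
#>    group source         target direct indirect      net n_chains n_contributing
#> 1 global    het temp_stability      0 -0.02929 -0.02929       11              5
```

Read: of the eleven heterogeneity-origin causal chains into temporal
stability, five have every edge significant at 0.05, yet their
products nearly cancel — the net standardised effect (-0.03 here,
direct + indirect) is tiny and its bootstrap interval
(`bootstrap_cascades()` attaches `lo95`/`hi95`) covers zero: the
signature of counteracting pathways rather than absence of mechanism.
The rejected Fisher's C is expected on this generator: the simulated
community carries dependencies (saturation, shared variance
decomposition) beyond the compact a priori DAG, just as field data
would.  The multigroup fit by shore zone, `psem(..., group = "zone")`,
is the analysis the pipeline runs by default.

The whole workflow, including stage CSVs and the bootstrap, is one
call:

```r
report <- run_pipeline(run_config(seed = 42, out_dir = "out"))
```

A thin command-line wrapper with `simulate`, `metrics`, `stability`,
`lmm`, `sem`, `cascades` and `run` subcommands is installed at
`inst/cli/shorestab.R` (YAML-configured; see `read_run_config()`).

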