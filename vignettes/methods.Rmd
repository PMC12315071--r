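---
title: "Stability decomposition and causal path analysis for paired-tile intertidal experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability decomposition and causal path analysis for paired-tile intertidal experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Substrate heterogeneity — pits, crevices, textured rock — is widely
assumed to stabilise ecological communities: it shelters stress-
sensitive organisms (refugia), supports more species, and more species
can fluctuate out of phase with one another, buffering the aggregate.
But heterogeneity also suppresses dominant space-holders and impedes
mobile consumers, and where those players are themselves stabilising,
heterogeneity can *destabilise*.  Whether the net effect is positive,
negative or zero is an empirical question that requires (i) a per-unit
decomposition of temporal stability into its mechanisms and (ii) a
causal model that traces treatment effects through the community to
stability.

`shorestab` implements that full analysis for the canonical design in
this literature: paired experimental tiles (one pitted, one flat) at
stations along transects spanning an emersion-stress gradient on a
rocky shore, surveyed repeatedly as percent cover by point-count image
subsampling.

## The stability decomposition

For one tile with taxon covers $x_i(t)$ over censuses $t = 0, \dots,
T-1$ and total cover $x_T(t) = \sum_i x_i(t)$, all metrics are computed
after **linear detrending** of each taxon's series on the census index
(the total's residuals then equal the summed taxon residuals, because
ordinary least squares is linear).  With raw temporal means $\mu_i$ and
residual standard deviations $\sigma_i$ (sample, $n-1$):

* temporal stability $\mathrm{TS} = \mu_T / \sigma_T$ — the inverse
  coefficient of variation of total cover;
* population stability $\mathrm{PS} = \sum_i \mu_i / \sum_i \sigma_i$;
* synchrony $\varphi = \sigma_T^2 / (\sum_i \sigma_i)^2$ (the
  Loreau–de Mazancourt variance ratio), asynchrony $= 1 - \varphi$;
* statistical averaging $\mathrm{SA} = \sum_i \sigma_i /
  \sqrt{\sum_i \sigma_i^2}$, the portfolio effect, in
  $[1, \sqrt{S}]$;
* compositional stability $\mathrm{CS} = 1 - $ mean Bray–Curtis
  dissimilarity between consecutive censuses on raw covers.

Because one shared detrending underlies TS, PS and $\varphi$, the
decomposition

$$\mathrm{TS} = \mathrm{PS} \cdot \varphi^{-1/2}$$

holds *exactly* (to numerical precision), and the test suite asserts it
to $10^{-10}$ on a thousand random matrices.  Design choices worth
stating explicitly:

* **Detrending is linear and per taxon.**  The trend being removed is a
  weak directional drift; the linear model is the minimal choice, and
  applying it per taxon (with the total inheriting the summed
  residuals) is the only choice that preserves the identity above.  The
  mean in TS is the raw mean, so only fluctuations — not the trend —
  enter the denominator.  A total-only variant
  (`stability_profile(detrending = "total_only")`, per-taxon
  variability around each taxon's mean) is provided for comparison;
  under it the identity is only approximate.
* **Degenerate tiles** (zero residual variance) report `NA` with a
  `degenerate` flag, never `Inf`, and are dropped (with a logged count)
  before modelling.
* **Evenness convention.**  Pielou's $J = H'/\ln S$ is computed per
  census and averaged over the censuses where it is defined ($S \ge
  2$).  Substituting 0 or 1 for undefined censuses would bias sparse
  high-shore tiles in opposite directions; exclusion is neutral.  The
  alternative convention (one J on the time-averaged cover vector) is
  available via `summarise_tiles(evenness = "time_averaged")`.
  Richness counts strictly positive covers — point-count zeros already
  encode detectability.
* **Bray–Curtis on raw covers** keeps CS sensitive to seasonal
  composition swings; census pairs in which both censuses are empty are
  skipped.

## Treatment models

Every tile-level response (richness, evenness, group covers, the five
stability metrics) is modelled as

`response ~ z(heterogeneity) * z(emersion) + (1 | transect / station)`

by REML, with Satterthwaite denominator degrees of freedom (the
`lmerTest` default an ecology workflow would produce), z-scored
predictors, marginal/conditional $R^2$ by the variance-partition
formula, and optional `log`/`log1p`/`sqrt` response transforms.
Singular fits — common with five transects — are retained and flagged
rather than refitted with a simplified random structure, keeping the
model formula constant across responses.  The denominator-df method is
switchable (`fit_lmm(df_method = "residual")`) for comparability with
software that does not approximate df.  If the Satterthwaite
approximation fails, residual-df t statistics are used with a logged
warning.  Diagnostics are exposed numerically
(`residual_diagnostics()`: Shapiro–Wilk summary and a scale–location
slope) rather than as an automated model-selection step.

## Piecewise structural equation model

The causal model is a DAG over the tile-level variables; `psem()` fits
one component regression per endogenous node (predictors = its
parents, same mixed-model family and nesting as above) and evaluates
the global structure by tests of **d-separation**: for every unordered
pair of non-adjacent nodes — excluding declared correlated-error pairs
and pairs of exogenous variables — the topologically later node is
regressed on the earlier plus the union of both nodes' parents
(Shipley's basis set), and the focal predictor's p value enters
Fisher's
$C = -2\sum_k \ln p_k \sim \chi^2_{2k}$.  p values are floored at
$10^{-16}$; an empty basis set returns the saturated $C = 0$, $p = 1$.
The basis-set construction is verified against a brute-force
d-separation oracle (moralised ancestral graphs) over *every* labelled
DAG on up to five nodes.

Standardised path coefficients are $\beta \,\mathrm{sd}(x) /
\mathrm{sd}(y)$ on the analysis scale, within the relevant group.

**Multigroup analysis** across shore zones (low/mid/high emersion
terciles with equal station counts) follows the free/constrain
procedure: each path's interaction with zone is tested in the pooled
component model (type-II Wald test at $\alpha = 0.05$); significant
paths are freed (separate per-group estimates), the others constrained
to the pooled estimate from a model that retains the zone main effect,
so group mean differences never masquerade as path differences.  The
per-edge (rather than omnibus) decision rule is the simplest faithful
reading of "a link varied significantly between zones" and is flagged
as switchable in spirit: with ~25 paths and a 5% per-path error rate,
roughly one homogeneous path will be freed by chance per fit, which is
why the operating-characteristic study below reports the *per-path*
false-free rate rather than the probability that no path anywhere is
falsely freed.

The default DAG (`default_sem_spec()`) encodes the a priori structure
for this experiment: heterogeneity and emersion act on community
components (species richness, the dominant non-native barnacle,
consumers, native barnacles, ephemeral algae); components feed the
stability mechanisms (population stability, asynchrony, compositional
stability) — including the offsetting component-to-mechanism routes in
which consumers stabilise populations by removing variable species
while richness destabilises them by adding marginal, volatile
colonisers; mechanisms determine temporal stability.  Heterogeneity
also has a direct refugia path to population stability and a direct
path to temporal stability; emersion has direct paths to the
mechanisms and to temporal stability (the gradient is the dominant
driver in this system, and omitting those links would push every
gradient signal into the d-separation tests).  Population stability
and asynchrony share a correlated error because both derive from the
same per-taxon variability decomposition.

## Cascading effects

A cascading (indirect) effect is the product of standardised path
coefficients along a directed chain; the net effect of heterogeneity
on a stability metric is the direct path (if present and significant)
plus the sum over all multi-edge chains whose edges are *all*
significant at $\alpha$ (chains with any non-significant edge
contribute zero, matching the convention of greying-out
non-significant paths).  Because hard masking makes the estimate
discontinuous, an `alpha = 1` mode computes the unmasked sum, which on
any DAG equals the source–target entry of $(I - B)^{-1} - I$ for the
SPC matrix $B$ — a property the tests exploit as an oracle.
Uncertainty comes from a nonparametric cluster bootstrap that
resamples whole stations (keeping tile pairs together; within zone
strata for multigroup fits), refits the pSEM and recomputes the masked
net effect; 95% percentile intervals are reported.  The interval
therefore reflects both coefficient noise and masking flips.

## The synthetic community generator

`simulate_covers()` emulates the study conditions: 5 transects × 7
stations × 2 paired tiles, 11 quarterly censuses (~2.5 years), ~20
taxa in five functional groups, an emersion gradient spanning 0.1–0.9,
and point-count observation with 500 grid points (binomial sampling of
expected cover; canopy and understorey strata are summed, so total
cover may exceed 100%).  Per taxon and tile, a latent Gaussian state
combines:

* a logistic-in-emersion group baseline (barnacles increase with
  emersion, consumers and algae decrease);
* treatment effects per the ground-truth path coefficients;
* a group-phased seasonal sinusoid (ephemeral algae peak opposite
  barnacle recruitment; the marginal "other" taxa get staggered
  phenologies evenly spaced around the year, so every additional
  coloniser actively compensates community fluctuations);
* stationary AR(1) noise with group-specific persistence (barnacles
  slow, ephemerals fast), initialised at the stationary distribution
  so early censuses are not systematically calmer.

The latent state maps to expected percent cover through a logistic
link (covers stay bounded without truncation), and taxa whose
tile-level suitability falls below a presence threshold record zero
cover — richness is therefore *emergent*, and the heterogeneity →
richness path operates through per-taxon suitability, mirroring
pit colonisation.  Mechanisms are implemented where they act:

* **refugia** damp the latent fluctuation scale (noise and seasonal
  forcing) on pitted tiles;
* **dominant suppression** and **consumer suppression** shift the
  latent means of those groups on pitted tiles;
* **consumer filtering** suppresses ephemeral-algal expected cover
  multiplicatively and raises ephemeral persistence (grazing clips
  bloom–crash cycles), which lowers census-to-census compositional
  turnover without changing marginal variances — this is what lets
  consumers stabilise composition over and above population stability.

The default `path_coefficients` encode the counteracting-pathways
scenario: positive refugia (`het_popstab = 0.3`) and richness
(`het_richness = 0.3`) routes balanced against suppression of the
stabilising dominant (`het_dominant = -0.7`) and of consumers
(`het_consumer = -0.4`, `consumer_ephemeral = -0.45`).  The paper-free
internal constants (latent shift per unit coefficient, filter
exponents, group persistence offsets, amplitude and noise multipliers)
were calibrated once, by simulation at the design scale, so that (i)
realised standardised tile-level effects land near the configured
targets and (ii) the positive and negative pathway bundles
approximately cancel — cancellation *is* the scenario, not a tuning
target discovered afterwards.  No field estimates of per-taxon
variances or autocorrelations exist for calibration; all generator
defaults are assumptions, not estimates, and are documented here as
such.

What the generator deliberately omits: within-tile spatial structure
(pits are represented only by their statistical consequences), calendar
irregularity of real censuses (all downstream metrics use the census
index), species interactions beyond the consumer–ephemeral link,
observation error beyond binomial point counts, and any mechanistic
hydrodynamics or thermal physics.  Passing tests therefore demonstrate
that the *pipeline* recovers known structure from data shaped like the
study's — not that the generator reproduces any particular shore.

A second generator, `simulate_sem()`, draws tile-level variables
directly from a linear-Gaussian SEM with unit marginal variances and
the experiment's nesting, so generating coefficients *are*
standardised path coefficients.  It is the oracle for calibration,
recovery and multigroup studies, where exact ground truth at the SEM
scale is required.

## Operating characteristics

`R/calibration.R` packages the simulation studies the test suite runs
(sizes chosen as the package's standard study sizes):

* `stability_identity_study()` — 1000 random tile matrices (5–20 taxa
  × 11 censuses): identity, bounds, invariances.
* `fisherc_calibration()` — 160 datasets simulated from the default
  DAG with `default_sem_coefs()` at the study scale (70 tiles);
  Fisher's C should reject at ~5%, and a rotating per-replicate claim
  p value should be uniform.
* `spc_recovery()` — 120 replicates; sign recovery and RMSE of
  standardised coefficients with generating magnitude ≥ 0.3.
* `multigroup_specificity()` — 80 replicates with only the
  heterogeneity → richness path varying across zones (0.7 / 0.35 / 0,
  the increasingly-positive-downshore pattern); detection of that path
  and the per-path false-free rate on the 24 homogeneous paths.  Note
  the deliberate reading: with ~24 homogeneous paths at a nominal 5%
  per-path rate, the probability that *no* other path is ever freed is
  about $0.95^{24} \approx 0.29$ per fit, so specificity is assessed
  per path, not as "nothing else freed anywhere".
* `counteracting_study()` — full pipeline runs of the default scenario
  across seeds: the number of significant heterogeneity-origin causal
  chains into temporal stability (expected ≥ 4: refugia, richness →
  asynchrony, dominant suppression, consumer suppression routes) while
  the station-bootstrap interval for the net effect covers zero.

## Numerical conventions and edge cases

Sample standard deviations use $n-1$ throughout.  Detrending requires
≥ 3 censuses; synchrony is clipped into $[0, 1]$ against floating-point
spill; claim p values are floored at $10^{-16}$; asynchrony is
logit-transformed (and TS/PS log-transformed) before z-scoring in the
analysis table, standard variance-stabilising choices for bounded and
ratio-scale quantities.  All randomness flows through a single seed:
each pipeline stage derives a child seed from the master, and reruns
with an identical configuration are bit-identical.

## Known limitations

* The pSEM's Fisher's C treats claim p values as independent; with
  correlated claims from one dataset the $\chi^2$ reference is
  approximate (the calibration study quantifies how close it is at the
  study's scale).
* With five transects, variance components are often estimated at
  zero; singular fits are retained by design, which slightly biases
  Satterthwaite df towards the residual-df limit.
* Cascading effects are linear path-tracing quantities, not
  interventional (do-calculus) estimates.
* The bootstrap intervals quantify sampling uncertainty under the
  cluster design; they are not a reconstruction of any specific
  published error bar whose construction is unknown.
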