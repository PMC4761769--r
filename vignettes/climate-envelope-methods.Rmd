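---
title: "Methods: climate-envelope modelling of wild yeast distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climate-envelope modelling of wild yeast distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yeastclim)
```

## The scientific problem

Wild *Saccharomyces* yeasts live on oak bark, but the geographic range of
*S. cerevisiae* — the model eukaryote — is poorly known because wild
populations are hard to find. `yeastclim` implements a climate-envelope
approach built on a survey of European oaks: model the per-tree isolation
frequency of the abundant sister species *S. paradoxus* as a function of
tree and climate covariates, read an optimum summer-temperature interval
off the fitted response, shift that interval by the laboratory-measured
difference in optimal growth temperature between the two species (+7 °C),
and test the shifted envelope against the worldwide locations of strain
collections.

The response variable is grouped binomial: for tree $i$, $y_i$ of $n_i$
bark samples yield the target species after enrichment culture. The model
is a logistic regression

$$\operatorname{logit}(p_i) = \beta_0 + \beta_g\,\mathrm{girth}_i +
  \beta_t\,T_i + \beta_s\,S_i + \beta_{gs}\,\mathrm{girth}_i S_i +
  \beta_{ts}\, T_i S_i,$$

where girth is trunk circumference in meters (a proxy for tree age), $T$
is Tmax — the daily maximum temperature averaged over the hottest month,
in °C — and $S$ indicates a southern site. Tmax enters in plain °C
everywhere in the package; the tenths-of-a-degree storage convention of
WorldClim v1.4-style rasters is confined to the raster layer and undone
exactly once at extraction.

## Fitting: IRLS, deviance, and inference

`binom_glm()` maximises the grouped binomial likelihood by iteratively
reweighted least squares with working weights $n_i p_i (1-p_i)$ and
working response $\eta_i + (y_i/n_i - p_i)/(p_i(1-p_i))$. Numerical
choices:

* **Start values.** Slopes at zero, intercept at the logit of the pooled
  positive rate — a stable start for grouped binomial IRLS.
* **Convergence.** Relative deviance change below $10^{-8}$ or 25
  iterations, whichever first; the result records the iteration count and
  a convergence flag.
* **Boundary guard.** Fitted probabilities are clamped to
  $[10^{-10}, 1-10^{-10}]$ inside the loop so that quasi-separated data
  (easy to produce with a handful of small sites) cannot generate
  non-finite working responses; a warning is raised when any coefficient
  exceeds 10 in absolute value on the logit scale. Note that with Tmax in
  °C the southern intercept offset is legitimately large, so this warning
  is informational on survey-scale fits.
* **Deviance.** Twice the log-likelihood gap to the saturated model with
  the $0\log 0 = 0$ convention. The null deviance is evaluated at the
  pooled rate (the intercept-only MLE).
* **Rank checks.** A rank-deficient design is an error naming the aliased
  column, not a silent drop.
* **Missing girth.** Trees without a girth measurement are excluded from
  any model containing girth and retained otherwise, which mirrors the
  survey's analysis (104 of 126 trees enter girth models). During
  stepwise search the row set is fixed once, from the complete cases of
  the *initial* formula, so every deviance comparison is between models
  fitted to identical rows.

Nested models are compared by `binom_lrt()`: the deviance difference
referred to $\chi^2$ with the difference in residual degrees of freedom.
Term contributions are reported as percentages of the null deviance, the
scale used in the original analysis.

`stepwise_simplify()` deletes terms starting from the highest order,
respecting marginality (an interaction must go before its main effects
become candidates). At each step every removable term is tested; the
deletion with the largest p-value is accepted if $p > \alpha$, with
higher-order terms preferred and equal-order ties going to the largest p.
Every tested deletion — accepted or not — lands in the deletion log, so
the simplification path is fully auditable. With $\alpha = 0$ every
deletion is accepted and the model collapses to the intercept, a useful
degenerate check.

`collapse_factor()` refits a model with a factor replaced everywhere
(main effect and interactions) by a coarser grouping and reports the
induced likelihood-ratio test. The degrees of freedom reported are those
actually freed in the supplied model, which depends on how many
interactions involve the factor — a collapse of a three-level host-type
factor to a two-level north/south factor in a model with two interactions
frees more than the bare level difference.

`cooks_distance()` gives the standard one-step influence approximation
$D_i = r_i^2 h_i / (p (1-h_i)^2)$ from Pearson residuals and the hat
values of the final weighted least-squares step; `refit_without()` does
the exact leave-one-out refit for sensitivity checks on the
highest-influence trees.

## Envelopes

The survey analysis read its optimum (22–28 °C) and occurrence
(18–31 °C) intervals off the fitted response curves by inspection; no
algorithm was stated. `derive_ranges()` therefore defaults to the
`"fixed"` policy — explicitly configured bounds — rather than pretending
a rule existed. A reproducible alternative, `"threshold"`, returns the
Tmax interval where the predicted response is at least $\theta$ times its
maximum, with endpoints interpolated linearly between grid points and
rounded outward to whole degrees (matching the integer reporting
convention); the occurrence interval defaults to the sampled Tmax span
rounded outward. Raising $\theta$ can only narrow the interval.

`shift_envelope()` translates both intervals by a fixed offset, +7 °C by
default — the laboratory difference in optimal growth temperature between
oak-strain *S. cerevisiae* and *S. paradoxus*:

```{r envelope}
sp <- derive_ranges(policy = "fixed")
sc <- shift_envelope(sp, 7)
sc
overlap_range(sp$occurrence, sc$occurrence)
```

## Rasters and distances

Rasters are regular WGS84 lat/lon grids stored as integer tenths of a
degree (`NA` = nodata), read and written in the plain-text ESRI ASCII
grid dialect. Extraction is deliberately single-pixel — no interpolation
— at the raster's native resolution.

* **Cell membership.** `row = floor((lat_NW − lat)/cell) + 1`,
  `col = floor((lon − lon_NW)/cell) + 1`: a half-open convention under
  which a boundary point belongs to the cell south/east of the line, so
  every interior point belongs to exactly one cell. The original analysis
  does not state its convention; this one is declared and tested.
* **Distances.** Great-circle (haversine) on a sphere of radius
  6371.0088 km (the IUGG mean radius, pinned for reproducibility).
  `distance_to_range()` returns 0 when the query point's own cell is
  inside the interval and otherwise the minimum distance to the *center*
  of any in-range cell. Centers, not polygon edges, match the resolution
  of the data; the choice is declared so replication differences are
  explainable.

## Range validation

`classify_strains()` attaches to each strain its single-pixel Tmax, an
in/out-of-range flag and the distance to range; strains on nodata cells
(or off the raster) are flagged unclassifiable and counted, never
silently dropped. Strains from wine or vineyard-grape substrates should
be excluded before validation — their locations reflect human transport
(sink populations), not climate. Whether vineyard *soil* counts as
vineyard-associated is genuinely ambiguous; `filter_vineyard_strains()`
therefore matches configurable substrate substrings, defaulting to
`"wine"` and `"grape"` (soil retained).

The two significance tests are the field-standard ones and are delegated
to base R: `fisher_exact()` wraps `stats::fisher.test()` (two-sided
probability-mass convention — the convention of the implementation used
in the original analysis, which reproduces its printed p-values at
printed precision), and `wilcoxon_rank_sum()` wraps
`stats::wilcox.test()`, exact for small untied samples
(min(n) ≤ 10) and otherwise the normal approximation with tie and
continuity corrections. The test suite checks both against brute-force
enumeration oracles rather than trusting the delegation.

## The synthetic-data generator

`simulate_survey()` is first-class, tested code that defines the study
conditions for every stochastic check in the package:

* 13 sites (9 northern, 4 southern) with the study's per-site tree
  counts, 126 trees, 4 bark samples per tree;
* trunk girth lognormal with median 1.3 m and sdlog calibrated to the
  0.8/1.9 m quartiles. A lognormal cannot match all three quartiles
  exactly (the printed quartiles are slightly right-skewed even on the
  log scale); the median is matched exactly and the interquartile spread
  on average. The within-site girth distribution was never published, so
  this is a modelling choice;
* site-level Tmax spread evenly across 19.6–21.6 °C (north) and
  27.3–30.9 °C (south). An earlier design drew site temperatures
  uniformly at random within each range, but with only four southern
  sites the draws frequently cluster, collapsing the between-site
  temperature contrast that identifies the Tmax-by-region effect — a
  situation the real survey, whose southern sites sit at 27.3, 28.0,
  29.7 and 30.9 °C, does not exhibit. The even spread mirrors the actual
  design;
* girth missing completely at random for 22/126 trees (no missingness
  mechanism was reported; MCAR is the neutral choice). The true girth
  still acts in the linear predictor — only the recorded value is
  blanked;
* an other-yeast frequency column generated independently of the
  response, so stepwise selection should drop it;
* default coefficients `(-2.65, 0.30, 0, 42.7, 1.30, -1.55)` calibrated
  at study size so that regional isolation rates match the surveyed ones
  (≈0.10 in the north; ≈0.45 falling below 0.01 across the southern Tmax
  span) and both interactions are recoverable by stepwise selection in
  over 90% of replicates. Full fidelity to every published deviance
  partition simultaneously is not attainable in this model family at
  n = 126 — the published interaction p-values (0.004 and 0.0006) imply
  roughly 80–85% recovery power at their partition sizes — so the
  calibration favours recoverability while keeping the girth share the
  largest, as reported.

What the generator does **not** emulate: within-site spatial structure,
seasonal variation, enrichment-culture competition between yeasts,
non-bark substrates, overdispersion beyond binomial, and the north–south
difference in girth distributions present in the real survey (northern
trees were larger). Passing tests therefore demonstrate that the
machinery recovers the structure it assumes, not that the real data are
free of these complications.

`simulate_raster()` produces a linear latitudinal temperature field with
bounded uniform noise, stored in integer tenths like its real
counterpart; `simulate_strains()` seeds wild-genotype strains at in-range
cells with small exponential displacements (median 1 km by default, the
observed median for out-of-range wild strains) and human-associated
strains at arbitrary cells with large displacements, emulating
human-transported sink populations hundreds of kilometres from suitable
climate.

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely on synthetic data
at deliberately modest sizes: 100-replicate stepwise-recovery studies at
the survey's 126-tree size, 500-replicate Wald-coverage studies at 200
grouped observations, 50 random rasters of a few hundred to a few
thousand cells for the distance engine, and 120-strain validation
tables. All randomness flows from explicit integer seeds; a fixed seed
reproduces every table, raster, and report byte for byte.

## Known limitations

* The envelope's default bounds are configured, not derived — faithfully
  reflecting that the original optimum was read off a figure. The
  threshold policy is offered for fully reproducible derivations but will
  not reproduce 22–28 °C exactly from refitted data.
* Single-variable envelopes: summer temperature is correlated with
  rainfall and winter temperature across Europe, and the survey design
  cannot separate them. The package deliberately does not model
  multivariate climate.
* Distances are to cell centers on a spherical Earth; differences from
  ellipsoidal or edge-based distances are sub-resolution at the rasters'
  scale but nonzero.
* The GLM layer offers no overdispersion or random-effect structure;
  site-level clustering beyond the region factor is unmodelled, as in
  the original analysis.
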