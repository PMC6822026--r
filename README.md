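# srpdrivers

Do **rare** (small-range) or **common** (large-range) species drive spatial
patterns of species richness? `srpdrivers` implements, as a reusable R
pipeline, the standard macroecological toolkit for answering that question
with grid-mapped point-occurrence data — the setting typical of subterranean
faunas, where up to a third of species are single-site endemics and range
sizes are strongly right-skewed.

## What it computes

Given occurrence records (species, locality, projected planar x/y in km,
positional accuracy, in-study-area flag), the pipeline:

1. **Range metrics.** Per-species range size as the *maximum linear extent*
   (MLE): the largest Euclidean distance between any two occurrence points
   (0 km for single-site endemics). Species are split into four rarity
   quartiles by MLE — quartile 1 is "rare", quartile 4 "common" — with tied
   species always kept in the same quartile.
2. **Richness surface.** A square grid (20 × 20 km by default) is overlaid;
   per-cell richness *S(c)* is counted over occupied cells and mapped into
   five classes relative to the richest cell's richness `r_max`
   (class 1: > 85% of `r_max`, class 2: 60–85%, then 40–<60%, 20–<40%,
   < 20%). Class 1 cells are *hotspots*; classes 1–2 are *species-rich
   cells* (SRCs). Two taxa's surfaces are compared with Kendall's tau-b,
   the rank correlation built for heavily tied integer data.
3. **Stepwise reconstruction.** Species are added one at a time in range
   *ascending* (rarest first) and *descending* (commonest first) order; at
   each step k the subset's per-cell richness is correlated (tau-b) with the
   overall pattern. Ties in MLE — notably the single-site block — are
   randomized and the median over replicates reported. A null model of fully
   random addition orders gives a central 95% envelope and two-sided
   empirical p-values
   `p = (1 + #{|tau_null − m| ≥ |tau_obs − m|}) / (R + 1)`.
   Curves are read against %-of-species and against cumulative information
   content `CI_k = Σ_{i≤k} p_i (1 − p_i)`, the expected binomial variance of
   the subset's occupancy pattern.
4. **Richness regressions.** Overall richness per cell regressed on rare- or
   common-species richness with log-link GLMs (negative binomial for the
   rare predictor, Poisson for the common one), reported with
   explained-deviance pseudo R² = (D₀ − D)/D₀ and small-sample AICc.
   Residual spatial autocorrelation is diagnosed with a Moran's I
   correlogram (14 equal-pair-count distance classes, permutation tests) and
   removed with PCNM spatial eigenvector filters (59 km truncation) selected
   forward until no correlogram class stays significant.
5. **SRC composition.** Per species-rich cell, the percentage of its species
   in each rarity quartile, summarized as mean and range across SRCs.

A seedable synthetic-assemblage generator (`scenario_config()` +
`generate_assemblage()`) produces datasets with the right structure —
lognormal range-size body, single-site endemics, clustered localities — in
three scenarios: `common_driven` (richness peaks formed by overlapping
common species), `rare_driven` (rare species aggregated at focal points) and
`neutral`. It makes every stage testable without any external data.

## Worked example

```r
library(srpdrivers)

cfg <- scenario_config(n_species = 120, region_width_km = 400,
                       region_height_km = 260, scenario = "common_driven",
                       seed = 11)
records <- generate_assemblage(cfg)
result  <- run_pipeline(records,
                        pipeline_config(R_median = 50, R_null = 200,
                                        R_perm = 500, seed = 1))
print(result)
#> Rare-vs-common species richness pipeline
#>   99 species over 127 occupied cells (r_max = 4)
#> Stepwise species-addition reconstruction
#>   descending: tau-b exceeds 0.5 after 47% of species (69% of information)
#>   ascending: tau-b exceeds 0.5 after 81% of species (61% of information)
#>   GLM pseudo R2: common 0.21, rare 0.15 (nonspatial)

print(result$summary)
#> Range-size frequency distribution: 99 species
#>   skewness 4.71; 51 single-site endemics (52%)
#>  quartile  n share_pct max_mle_km
#>         1 51        52    0.00000
#>         2 16        16   20.77448
#>         3 16        16   77.51553
#>         4 16        16 1004.91576
```

Reading the output: 120 generated species leave 99 after the 6-km accuracy
filter (species whose every record has worse accuracy drop out, and some
two-locality species collapse to single-site status, which is why the
single-site share exceeds the generated 23%). In this common-driven
assemblage the descending (commonest-first) curve reconstructs the overall
richness pattern far sooner than the ascending one — tau-b passes 0.5 after
47% vs. 81% of species — and the common-species GLM explains more deviance
than the rare-species GLM: the signature that common species shape the
richness pattern. `result$reconstruction`, `result$glm` and
`result$composition` hold the full per-step curves with null envelopes and
empirical p-values, the fitted models with correlograms and spatial filters,
and the SRC quartile composition; `run_pipeline(..., out_dir = "out")`
writes everything as CSV plus a JSON run manifest.

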