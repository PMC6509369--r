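# oppsel

Spatially explicit opportunity for sexual selection from mark–resight
surveys of a polygynous breeder.

## What it does

In harem-forming species like feral horses, only some adult males ever hold
mates, and how unequal mating success is — the **opportunity for sexual
selection**, Crow's index

```
I = variance(mating success) / mean(mating success)^2
```

— bounds how strong sexual selection can be. `oppsel` computes this index
*locally*, for every harem-holding male, over the buffer-overlap
neighborhood of his band (all animals whose sighting locations fall within
2.06 km — the median maximum seasonal movement — of the band's locations),
and partitions it into sequential episodes:

* `I_harem` — among all qualified males (dominant, tag, bachelor, ≥ 4 y),
  success 0/1 at holding a harem; equals `(1 − p)/p` for harem-holder
  fraction `p`;
* `I_mares_given_harem` — among dominant males only, success = qualified
  mares (females ≥ 2 y) in the harem.

It then runs the two-stage mixed-model inference around those statistics:
maximum-likelihood LMMs of local adult sex ratio (ASR) on each index with
male identity as a random intercept, followed by AICc competition of
environmental/demographic predictors (distance to permanent freshwater,
unpaired-male density, total density, each × year) fitted to the
standardized *marginal* residuals, a Gaussian spatial-correlation check,
and a post hoc polynomial regression of the year-specific
distance-from-water slopes on summer precipitation. A seeded synthetic
island generator with planted, known effects makes the whole chain
testable end to end.

Intended users: behavioral and evolutionary ecologists analysing
individual-based resighting data from spatially structured populations,
and anyone needing a reproducible harness for episode-partitioned
selection metrics.

## Worked example

```r
library(oppsel)

run <- run_pipeline(run_config(seed = 1))
print(run)
#> Pipeline run 13ff571b: 5653 records, 335 male-year rows (0 dropped), 114 males
#>   I                      best: year x total_density         (w = 0.80, R2m = 0.07)
#>   I_harem                best: year x unpaired_male_density (w = 1.00, R2m = 0.57)
#>   I_mares_given_harem    best: year x dist_water_km         (w = 1.00, R2m = 0.46)
#>   climate winner: winter_precipitation

run$competitions$I_harem
#> AICc competition for resid_I_harem (n candidates = 5)
#>                          model  k  dAICc weight logLik marginal_r2
#> 1 year x unpaired_male_density 12   0.00      1 -322.3        0.57
#> 2         year x dist_water_km 12  66.07      0 -355.4        0.47
#> 3         year x total_density 12 113.93      0 -379.3        0.32
#> 4                         year  7 154.09      0 -404.7        0.15
#> 5                         null  3 226.95      0 -445.3        0.00
```

Reading this: 335 rows are male-years (114 distinct males across five
seasons). For the harem-acquisition episode, the unpaired-male-density
model takes all the Akaike weight and explains 57% of the residual
variance after ASR — the structure the generator plants by default. (The
total-`I` response carries no planted covariate link, so its winner at any
single seed is noise; the two episode responses are the planted ones.)
The year-specific distance-from-water slopes of the mate-acquisition
episode are positive in average-precipitation years and negative in the
extreme ones (2009, 2010):

```r
year_slopes(best_model(run$competitions$I_mares_given_harem))
#>   year        beta
#> 1 2008  0.03190732
#> 2 2009 -0.14824146
#> 3 2010 -0.12925184
#> 4 2011  0.04992074
#> 5 2012  0.08029679
```

Island-wide descriptive statistics are one call each:

```r
harems_population_lm(census_reference)
#> harems ~ population linear model: statistic = 20.7, df = (1, 3), p = 0.0199
saturation_occasion(saturation_reference[["a"]], saturation_reference[["b"]])
#> [1] 8
```

`report_tables(run, "out/")` writes the census summary, competition
tables, climate table, selection table and saturation curve as CSV with
seed-stamped headers, and echoes the truth parameters to YAML. A thin
command-line wrapper lives at `inst/scripts/run-pipeline.R`.

## Package layout

| Area | Functions |
| --- | --- |
| Selection metrics | `opportunity`, `i_total`, `i_harem`, `i_mares_given_harem`, `local_asr` |
| Neighborhoods | `overlaps`, `buffered_area`, `build_neighborhood`, `dist_to_water`, `selection_table` |
| Survey IO | `load_sightings`, `write_sightings`, `build_band_seasons`, `saturation_analysis` |
| Island-wide tests | `brown_forsythe`, `kruskal_wallis`, `harems_population_lm`, `islandwide_tests`, `annual_summary` |
| Mixed models | `fit_lmm` (+ `print`/`summary`/`coef`/`predict`/`residuals`/`simulate`), `marginal_r2`, `satterthwaite_f`, `extract_marginal_residuals`, `compete_models`, `best_model`, `aicc`, `akaike_weights`, `gaussian_correlation_check` |
| Post hoc climate | `year_slopes`, `climate_fit`, `synth_climate` |
| Synthetic data | `island_config`, `generate_island`, `truth_params`, `generate_population`, `simulate_surveys`, `plant_effects`, `resight_pmf` |
| Pipeline | `run_config`, `read_run_config`, `run_pipeline`, `report_tables` |

The methods vignette (`vignettes/opportunity-for-selection.Rmd`) documents
the model, the generator's calibration and its deliberate limitations.
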