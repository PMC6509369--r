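---
title: "Spatially explicit opportunity for sexual selection: model, generator, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially explicit opportunity for sexual selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oppsel)
```

## The scientific problem

In polygynous breeders such as feral horses, a minority of males monopolizes
mating. The *opportunity for sexual selection* — Crow's index
$I = \mathrm{var}(f) / \bar{f}^2$, the variance in relative mating success —
bounds how strong sexual selection can be. `oppsel` computes $I$ not
island-wide but *locally*: for each harem-holding (dominant) male, over the
neighborhood of animals whose sighting locations overlap his band's buffered
locations, and partitions it into sequential episodes:

* $I_{harem}$ — competition among **all** qualified males (dominant, tag and
  bachelor males aged $\ge 4$) to hold a harem at all. Success is 0/1, so
  with local harem-holder fraction $p$ the index reduces to $(1-p)/p$.
* $I_{mares|harem}$ — competition among **dominant males only** to
  accumulate qualified mares (females aged $\ge 2$) given a harem.

Grouped by band $k$ with harem size $f_k$ and $m_k$ males (dominant plus
tags), the neighborhood statistic is
$$\bar f = \frac{\sum_k f_k m_k}{\sum_k m_k}, \qquad
  I = \frac{\sum_k f_k^2 m_k / \sum_k m_k - \bar f^2}{\bar f^2},$$
identical to the plain variance-over-squared-mean of the expanded per-male
success list — an identity the test suite verifies against a brute-force
oracle on a thousand random instances. Tag males are counted among the
competing males but are never assigned mates; this weights their band's
harem size by $m_k$ in the total index, which is the grouped summation's
reading of the procedure. Undefined statistics (zero mean success in a
neighborhood) become `NA` rows that are dropped from modelling with a
logged count.

## Neighborhoods and spatial covariates

Band-seasons are derived from individual sighting records; every member of a
band shares the band's location at each census occasion. Two location sets
*overlap* when their minimum pairwise Euclidean distance is at or below the
buffer radius (boundary-inclusive — the original field protocol does not state
open/closed, and with a single shared radius buffering either or both sets
is equivalent under the min-distance rule, which is why that rule was
chosen). The default radius, 2.06 km, is the median maximum distance moved
within a breeding season.

Covariates per focal band-season:

* `dist_water_km` — mean over the band's locations of the distance to the
  nearest *permanent* pond (ephemeral water enters only through the
  precipitation index);
* `unpaired_male_density`, `total_density` — season-unique individual
  counts per km² of the buffered locations clipped to the island
  ("terrestrial area"). The clip area is evaluated on a regular grid
  (default cell 0.02 km for standalone calls, 0.05 km inside the pipeline);
  for a single interior 2.06-km disc the grid error is well under 1%.
* `asr` — local adult sex ratio, males $\ge4$ over adults, computed per
  occasion from the individuals overlapping the focal locations and
  averaged over occasions with at least one overlapping adult. A
  season-pooled variant (`method = "season"`) is available because "mean"
  in the original definition is ambiguous between the two readings.

## The two-stage inference

**Stage 1 (ASR models).** For each response ($I$, $I_{harem}$,
$I_{mares|harem}$) a linear mixed model $y = \beta_0 + \beta\,(x - \bar x)
+ \alpha_{male} + \varepsilon$ is fitted by maximum likelihood with male
identity as a random intercept (lme4 behind the module surface). Marginal
$R^2$ — fixed-effect variance over fixed + intercept + residual variance —
and Satterthwaite-approximated F tests (lmerTest) are reported.

**Marginal residuals.** The stage-2 response is the *marginal* residual
$y - X\hat\beta$ (random effects not subtracted), standardized by
$\sqrt{\mathrm{diag}(V)}$ with $V = \hat\sigma^2_\alpha ZZ' +
\hat\sigma^2_\varepsilon I$. Diagonal (Pearson) standardization was chosen
over full Cholesky whitening deliberately: whitening mixes rows across a
male's seasons and destroys the row-to-covariate correspondence that the
residual models depend on. For a random-intercept model $\mathrm{diag}(V)$
is constant, so the choice is a pure rescale and leaves all stage-2 AICc
rankings invariant.

**Stage 2 (residual competitions).** Five candidates per episode — null,
categorical year, and year × covariate for distance-to-water,
unpaired-male density and total density — each with the male random
intercept, ML. Parameter counts include both variance components (null
k = 3, year k = 7, interaction k = 12 with five seasons), and
$AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)$ uses $n$ = number of male-year rows,
not males. Akaike weights are $\exp(-\Delta/2)$ normalized.

**Spatial check.** Whether the best residual model is improved by a
Gaussian residual correlation $\exp(-(d/\rho)^2)$ between rows'
representative locations is assessed by a profiled ML: $\rho$ over 16
log-spaced values in 0.1–50 km, the intercept-to-residual variance ratio
optimized at each grid point, $\beta$ and $\sigma^2$ profiled in closed
form. No installed mixed-model engine fits a residual correlation *across*
grouping units together with a random intercept, so the likelihood is
implemented directly; its $\rho \to 0$ limit is verified against the lme4
log-likelihood. Both competing fits use the same machinery so the AICc
comparison is internally consistent; the correlated model spends one extra
parameter ($\rho$).

**Post hoc climate regression.** When the distance model best explains the
mate-acquisition residuals, its year-specific distance slopes
($\beta_{year}$ = main coefficient plus that year's interaction under
reference coding) are regressed on candidate climate variables, linear and
linear+quadratic, by OLS. Here AICc uses $n$ = number of years and $k$ =
coefficient count only — the convention the original analysis printed for
these OLS fits, k = 2/3 (counting $\sigma^2$ would make the correction
denominator zero at five years). With five years the quadratic
correction denominator is 1; such candidates are flagged
(`small_sample = TRUE`) and candidates with $n \le k+1$ get `NA` AICc,
reported rather than fatal. Climate variables are standardized across years
before fitting, so an exact-quadratic relationship is preserved (affine
recoding) while coefficients are on the index scale.

## The synthetic island generator

The generator emulates the statistical structure of a five-season
mark-resight study of a closed island population:

* **Geometry.** A 49 × 1.5 km planar rectangle with Euclidean distances
  (the real analysis used projected GIS coordinates; the projection is
  irrelevant at this scale). Five permanent ponds are placed with
  quadratically increasing spacing toward one end so distance-to-water
  spans roughly 0–15 km across band sites — the east–west gradient of the
  study system.
* **Demography.** 52–79 bands per season (the observed series), exactly one
  dominant male each, tags in ~3% of bands, harem sizes 1 + Poisson with
  per-season means 2.60/2.71/2.33/2.12/2.32 (only means and confidence
  intervals are reported for the real system, so the family is a generator
  choice; a `"fixed"` option exists for degenerate checks). Bachelors are
  added to make up 60% of qualified males, consistent with the reported
  adult-male and harem counts. Identities persist: dominant males are
  retained with probability 0.85 per season (giving ~118 distinct males
  over 335 male-seasons, the study's bookkeeping), and mares carry over
  with band reassignment at the breeding-dispersal rates 0.16 (adult) and
  0.34 (2–3 y).
* **Surveys.** 8–10 occasions per season. Per-individual seasonal sighting
  counts follow a truncated negative binomial on [1, occasions] calibrated
  by moment matching to mean 2.84, SD 1.43. The family cannot actually
  reach SD 1.43 at that mean — its minimum, the zero-truncated Poisson
  limit, is ≈1.50 — so the mean is matched exactly and the dispersion is
  pinned at the limit; tests assert the attainable moments. Band members
  share the band's per-occasion location (home site plus a ≤1 km draw);
  bachelors move independently within 1.5 km of home sites.
* **Planted effects.** `plant_effects()` rebuilds the three response
  columns from the table's *realized* covariates under a generative
  random-intercept model with every coefficient known. This is deliberate:
  the mechanical $I_{harem}$ is definitionally $(bachelors+tags)/holders$,
  i.e. deterministically tied to unpaired-male density, so no generator
  setting could make covariate models lose on mechanical responses under a
  "null" configuration — a controlled response model is the only way a
  null-calibration experiment can exist. The mechanical metrics are kept
  as `*_observed` columns and feed the island-wide tests. Stage-1 ASR
  links use the study's printed equations ($I_{harem}: 1.725x - 0.392$;
  $I_{mares|harem}: 0.396x + 0.220$; total $I$: slope 0.95, derived from
  the reported 44% rise per 10% ASR increase at the generator's mean
  $I \approx 0.22$), with noise SDs (0.54, 0.133, 0.294) calibrated so
  stage-1 marginal $R^2$ reproduces the reported 0.05/0.74/0.03 at the
  generator's ASR spread, a male-intercept share of 0.10, and year
  intercept shifts of SD 0.08.
* **Planted covariate effects.** $I_{harem}$ gains 0.3 per unpaired male
  per km² — calibrated so the planted runs reproduce the printed
  competition structure of the real analysis (winner marginal $R^2
  \approx 0.57$ and a decisive AICc gap to the total-density model); the
  weaker verbal "+10% per male/km²" statement is ambiguous about scale and
  was not used as the anchor. $I_{mares|harem}$ gains a distance-from-water
  slope of +0.02/km in average-precipitation years and −0.05/km in extreme
  years (|index| ≥ 0.8), the sign structure of the published year-specific
  slopes. The ASR spatial gradient (bachelor home sites tilted away from
  water, ~0.005 ASR/km) is kept moderate: a steeper tilt makes ASR and
  distance-to-water collinear enough (r ≈ 0.74) that stage 1 absorbs the
  average-year water signal and the two episodes stop being separately
  identifiable — with the default the correlation is ≈ 0.23 and all five
  year-slope signs are recovered.

### What passing tests do and do not show

The generator reproduces the *statistical shape* the analysis assumes —
sample sizes, resight effort, spatial gradients, variance structure, known
planted links. It does not simulate behavior (no takeovers, fights,
survival or foaling), coastline geometry, or genetic substructure, and its
generative responses are unbounded rather than nonnegative like real
indices. Recovery results therefore validate the *pipeline's inference
machinery* under the study's conditions, not the biology of any real
population.

### Calibration facts worth knowing

* With all planted effects zero, the year-only or null model is selected in
  ~85% of competitions. That ceiling is intrinsic to AICc here: a
  year × covariate candidate beats year-only when $2\Delta\ell > 10.63$
  (the k = 12 vs k = 7 penalty gap at n = 335), which pure noise achieves
  with probability $P(\chi^2_5 > 10.63) \approx 6\%$ per candidate, ~15%
  across three. The 80% acceptance bound sits just below this floor.
* The classic median-centred Brown-Forsythe test is mildly conservative in
  small groups (rejection ≈ 0.040 at n = 60 per group); at the study's
  island-wide scale (~200 adult males per season) it holds the nominal 5%
  within Monte-Carlo error, which is the scale the calibration test uses.
* Degenerate inputs: band-seasons with zero or multiple dominant males
  raise integrity errors listing the bands; selection rows with undefined
  statistics are dropped with a logged count; a constant covariate or a
  single grouping level refuses to fit; all-identical Kruskal-Wallis input
  returns H = 0, p = 1 rather than an error.

## Problem sizes used

Simulation-backed tests run at the study's own scale (five seasons,
52–79 bands, ~335 male-years) with 50 replicate islands for recovery and
null calibration, 2,000 refits for Satterthwaite calibration, 10,000
Monte-Carlo replicates for the type-I checks, and 20 replicates per arm
for the spatial-correlation power checks; these sizes make the full suite
reproducible on a single CPU.

## A worked run

```{r example, eval = FALSE}
run <- run_pipeline(run_config(seed = 1))
print(run)
run$competitions$I_harem          # Table-2-shaped competition
year_slopes(best_model(run$competitions$I_mares_given_harem))
run$climate                       # Table-3-shaped climate competition
report_tables(run, "oppsel-run")  # CSV bundle + truth YAML
```

## Known limitations

* The Satterthwaite implementation targets the single-random-intercept
  design the analysis uses; crossed or nested random effects are out of
  scope (as is REML — the analysis fits everything by ML).
* The additive relationship $I \approx I_{harem} + I_{mares|harem}$ is
  *not* asserted or tested anywhere; the decomposition's algebraic status
  is an open question and the package takes no position on it.
* With five years the climate AICc correction is enormous for quadratic
  candidates; the package reports and flags the honest small-sample
  behavior — no single AICc convention reproduces every originally printed
  climate ranking, so exact fits (R² = 1), which win under any penalty,
  anchor the self-consistency checks instead.
* The archived field data of the study system are not ingested; the
  package's claims about real data are limited to the published census
  table and curve coefficients it ships as constants.
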