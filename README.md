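# phenowin

Temperature windows, phenological sensitivity and climate-change exposure
for breeding-phenology time series.

## The problem

Many organisms time reproduction using temperature cues, and populations of
the same species can differ both in *how strongly* they respond to
temperature (phenological sensitivity, days advanced per °C) and in *how
fast* their local climate is changing (climate-change exposure, °C per
year). The phenological advancement a population is expected to show is the
product of the two, so neither quantity alone predicts it — and if
sensitivity and exposure covary negatively across a species' range (for
example because highly sensitive deciduous-habitat populations sit at
mid-latitudes while rapidly warming northern sites are evergreen), the most
sensitive populations need not be the fastest-advancing ones.

Estimating any of this from long-term nest-record data requires first
answering *when* temperature matters. phenowin implements the full
inference chain for multi-population studies of cavity-nesting birds (great
and blue tits are the motivating system), from raw clutch records and daily
mean temperatures to:

1. **Annual phenology** — laying dates back-calculated at one egg per day,
   first clutches only (within 30 days of the year's earliest), reduced to
   annual means ± SE (`annual_phenology()`).
2. **Temperature-window search** — every window of 1–365 days within the
   365 days before June 1 (66,795 candidates), scored by inverse-SE-weighted
   Gaussian regression of laying date on window-mean temperature and
   compared by AICc against an intercept-only baseline, with prefix-sum
   aggregation so the full grid costs three matrix products
   (`search_best_window()`).
3. **Randomization control** — P_ΔAICc, the add-one percentile of the
   observed best ΔAICc within 100 re-searches of phenology-permuted data; a
   cue needs P_ΔAICc ≤ 0.05 and duration > 14 days
   (`randomization_test()`).
4. **Sensitivity** — the temperature path coefficient of the recursive
   system `Temp ~ Year; Laying ~ Temp + Year`, which separates
   temperature-mediated from direct temporal trends, with 1000-iteration
   bootstrap SEs (`fit_path_model()`, `bootstrap_sensitivity()`).
5. **Exposure and advancement** — the 1950–2017 OLS trend of window-mean
   temperature; advancement = sensitivity × exposure with a delta-method SE
   (`compute_exposure()`, `compute_advancement()`).
6. **Covariance and drivers** — bootstrapped Pearson correlation between
   sensitivity and exposure across populations (`covariance_bootstrap()`),
   and mixed-model comparative analyses of window descriptors and
   sensitivity against latitude, longitude, species, habitat and
   precipitation, with parametric-bootstrap CIs, GVIF collinearity
   screening and a Matérn spatial residual diagnostic
   (`fit_window_trait_model()`, `fit_sensitivity_model()`).

A synthetic-data module (`simulate_metapopulation()` and friends) generates
multi-population datasets with known ground truth — seasonal AR(1) daily
temperature with a warming trend, laying dates driven by a hidden window,
habitat-dependent sensitivity and latitude-dependent exposure — so every
stage is testable by parameter recovery. See
`vignettes/phenowin-methods.Rmd` for the statistical details.

## Worked example

One synthetic population with a planted cue window 120–61 days before
June 1 (midpoint day-of-year 61.5), sensitivity 4 days/°C, warming
0.03 °C/yr:

```r
library(phenowin)

truth <- synthetic_truth(sensitivity = 4, warming_trend = 0.03,
                         series_start_year = 1949)
temps <- simulate_temperature(truth, seed = 1)
clutches <- simulate_clutches(truth, temps, seed = 1)
phen <- annual_phenology(clutches)

result <- randomization_test(phen, temps, window_config(),
                             n_rand = 100, seed = 1)
print(result)
#> Sliding-window search (40 years, max span 365 days before doy 152)
#>   best window: open 120, close 61 (duration 60 d, midpoint doy 61.5)
#>   slope -4.499 days/C, deltaAICc -122.31
#>   P_deltaAICc = 0.0099 (100 randomizations) -> temperature cue

sens <- population_sensitivity(result, temps, n_boot = 1000, seed = 1)
exposure <- compute_exposure(temps, result$best$open, result$best$close)
adv <- compute_advancement(sens$sensitivity, exposure$exposure,
                           sens$se_sensitivity, exposure$se_exposure)
```

which prints (`sensitivity: 3.90 ± 0.06 days advanced/C`,
`exposure 1950-2017: 0.0400 ± 0.0053 C/yr`,
`expected advancement: 0.156 ± 0.021 days/yr`): the search recovers the
planted window exactly; the raw window slope (−4.50 days/°C) overstates the
temperature effect because warming and a direct year trend are confounded
in it, while the path model's detrended sensitivity (3.90 days/°C) is
within noise of the planted 4; and this population is expected to advance
about 1.6 days per decade.

## The analysis workflow

`analysis/01_simulate.R` … `analysis/05_drivers.R` run the whole study on a
20-population synthetic metapopulation (deterministic given the master seed
in `analysis/00_config.R`) and write their tables under `results/`:
simulation and reduction, per-population window search with randomization,
path-model sensitivities, exposure/advancement/covariance, and the
mixed-model driver analyses with spatial diagnostics. Each script prints a
short narrative of what it found; run them in order from the repository
root:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_find_windows.R
# ...
```

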