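---
title: "Temperature windows, phenological sensitivity and climate-change exposure: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature windows, phenological sensitivity and climate-change exposure: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

phenowin implements the inference chain from raw nest records and daily
temperatures to population-level phenological sensitivity, climate-change
exposure, expected phenological advancement, and the covariance between
sensitivity and exposure across populations. This vignette is the package's
account of the statistical machinery: the models, the conventions, the
tunable parameters, and what the synthetic tests do and do not demonstrate.

## From nest checks to annual phenology

The unit of analysis is a population (a study site by species combination)
observed over many breeding seasons. Nest boxes are checked at least weekly,
so the day the first egg was laid is usually not observed directly; when a
nest is first found with $k$ eggs on day $d$, laying is back-calculated as
$d - (k - 1)$, one egg per day (`back_calculate_laying()`). Second and
replacement clutches are excluded by keeping only clutches laid within 30
days of the year's earliest clutch (`first_clutch_filter()`); we read
"within 30 days" as the closed interval (earliest + 30 is retained), and the
cut-off is configurable. A population-year is reduced to the mean laying
day-of-year of first clutches with its standard error, $s/\sqrt{n}$
(`reduce_annual()`, `annual_phenology()`).

Two conventions matter downstream:

* **365-day calendar.** Feb 29 is dropped from every daily series, so "d
  days before June 1" addresses the same calendar day in every year and
  window geometry never depends on leap years.
* **SE floor.** Years with one clutch (or zero variance) have no usable SE;
  they receive the population's median positive annual SE (fallback 1 day)
  so inverse-SE weights stay defined. This only up-weights such years to a
  typical precision, never to infinite weight.

## The sliding-window cue search

The scientific question is *when* temperature matters. A candidate window is
a contiguous run of days, `open` to `close` days before a reference date
(June 1, day-of-year 152, configurable), with
$365 \ge \mathrm{open} \ge \mathrm{close} \ge 1$: 66,795 candidates in all.
For each window, the per-year mean temperature $\bar T_w(y)$ enters a
weighted Gaussian regression

$$\mathrm{laying}_y = \alpha + \beta\, \bar T_w(y) + \varepsilon_y, \qquad
  \varepsilon_y \sim N(0, \sigma^2 / w_y),$$

with weights $w_y = 1/\mathrm{SE}_y$ on the annual means (a `weight_power`
switch offers $1/\mathrm{SE}^2$ for sensitivity analysis). Each window model
is compared with the intercept-only baseline through the small-sample AIC,

$$\mathrm{AICc} = -2\ell + 2k + \frac{2k(k+1)}{n-k-1},$$

with $k = 2$ (intercept, $\sigma$) for the baseline and $k = 3$ for the
window model, and $\ell$ the weighted-least-squares Gaussian log-likelihood
in the convention of standard WLS software (weights scale the error
precision; the same convention in both models, so AICc values are
comparable). The best window minimizes AICc, i.e. the most negative
$\Delta\mathrm{AICc}$ relative to the baseline.

Implementation: per-year prefix sums over days-before-reference make every
window mean an $O(1)$ difference, and the weighted regression statistics for
the entire grid reduce to three matrix-vector products, so a full 66,795
window search over 40 years runs in well under a second. The engine is
checked against a naive one-`lm()`-per-window oracle to $10^{-8}$ on
randomized instances. Exact AICc ties are broken deterministically toward
the shorter window, then the one closest to laying (smallest `open`) —
parsimony and proximity to the response. Windows with zero temperature
variance across years are marked degenerate ($\Delta\mathrm{AICc} = \infty$)
and can never be selected.

### False-positive control

Testing tens of thousands of windows invites false positives, so the
observed $\Delta\mathrm{AICc}$ is referred to a randomization null: the
assignment of annual phenology records (mean and SE together) to years is
permuted, destroying any phenology-temperature link while preserving both
marginals, and the full search is re-run; 100 permutations by default. The
probability of obtaining the observed support by chance is the add-one
empirical percentile

$$P_{\Delta\mathrm{AICc}} =
  \frac{1 + \#\{\Delta\mathrm{AICc}^{\mathrm{rand}}_b \le
  \Delta\mathrm{AICc}^{\mathrm{obs}}\}}{n_{\mathrm{rand}} + 1},$$

which is never exactly zero and is exact at small $n_{\mathrm{rand}}$; other
estimators of the same null distribution could be plugged in, but the
empirical percentile is transparent and assumption-free. A window is
accepted as a temperature cue when $P_{\Delta\mathrm{AICc}} \le 0.05$
*and* its duration exceeds 14 days; the duration rule is a deliberately
post-hoc biological filter (very short windows are implausible as cues and
behave like statistical artefacts), so it makes the realized cue-acceptance
rate conservative — under a true null the $P \le 0.05$ event alone occurs at
the nominal ~5%, and the type-I calibration test measures exactly that
event. Because permutations re-use the precomputed window-mean matrix, the
randomization adds only matrix-vector products per replicate; the full
randomization test runs in a couple of seconds per population.

## Sensitivity via the path model

The raw window slope conflates two routes by which calendar time reaches
laying date: through temperature (climate change) and around it (any other
directional change — observer effects, density, habitat succession). The
package separates them with a recursive two-equation system,

$$T_y = a_0 + a_1\,\mathrm{year}_y + e_{1y}, \qquad
  L_y = b_0 + b_1\,T_y + b_2\,\mathrm{year}_y + e_{2y},$$

fit by equation-wise least squares, which is the exact estimator for a
recursive system with uncorrelated errors — no latent-variable machinery is
needed. Phenological sensitivity is $-b_1$ (days advanced per °C), the
direct year path is $b_2$, and the temperature-mediated (indirect) path is
$a_1 b_1$; when both equations share the same weights, $b_2 + a_1 b_1$
reproduces the marginal laying-on-year slope exactly, which the tests assert
to $10^{-10}$. By default the laying equation uses the same $1/\mathrm{SE}$
weights as the window search and the temperature equation is unweighted
(the temperature trend is a property of the climate series, not of how
precisely laying was measured); a same-weights mode is available. Years are
centered before fitting, which stabilizes intercepts and leaves slopes
untouched. Standard errors come from a nonparametric bootstrap over years
(1000 iterations), with degenerate resamples (no temperature variance)
redrawn and counted.

If temperature is numerically an exact linear function of year the two
paths are not separately identifiable and the fit aborts with a
`degenerate path model` error rather than returning arbitrary coefficients.

## Exposure, advancement, covariance

Climate-change exposure is the OLS slope of the per-year window-mean
temperature on calendar year over a standard period, 1950-2017 by default,
so that populations with different study spans are comparable. Years whose
window is not fully covered by the temperature series are dropped and
counted, never imputed. Expected phenological advancement is the product
sensitivity × exposure (days advanced per year) — "expected" because
sensitivity is estimated on the study years and exposure on the standard
period, i.e. it assumes sensitivity has been stable over that period. The
advancement SE reported alongside is a first-order delta-method propagation,
$\sqrt{E^2\sigma_S^2 + S^2\sigma_E^2}$; the underlying method defines no
advancement SE, so this quantity is clearly labelled an addition and is
never used for weighting.

The cross-population association between sensitivity and exposure is a
Pearson correlation with a nonparametric bootstrap over populations (5000
iterations, percentile 95% interval, degenerate resamples redrawn). Species
are pooled in the headline figure; a per-species split is a one-line
subset.

## Drivers of windows and sensitivity

Window descriptors (midpoint, duration, delay) and sensitivity are related
to population characteristics with Gaussian linear mixed models, site as a
random intercept (both species can share a site), REML, treatment contrasts
with deciduous habitat and great tit as reference levels so habitat
contrasts carry the expected signs. Window-descriptor models use latitude,
longitude, species, habitat, and species-by-latitude/longitude
interactions; the sensitivity model uses habitat, an annual-precipitation
principal-component score, species, and species interactions. Confidence
intervals come from a parametric bootstrap (simulate from the fitted model,
refit, percentile bounds; 1000 iterations), whose coverage the acceptance
tests check against exact binomial bounds at the 95% level. Collinearity is
screened with generalized variance inflation factors via the
determinant-ratio formula on the fixed-effects design correlation matrix,
cutoff 3 on the $\mathrm{GVIF}^{1/2\mathrm{df}}$ scale; in models with
interactions the interaction terms are inherently correlated with their
main effects, so the screen is most informative for the main-effect terms.

Spatial structure is handled diagnostically rather than in the likelihood:
after fitting, standardized residuals are examined with a binned
correlogram (pairwise residual products by Euclidean distance in degrees,
1-degree-compatible bins, one-sided permutation p-values for positive
correlation, 999 permutations). The Matérn kernel
($\nu = 0.5$ default, i.e. exponential decay) is provided for reference and
for generating spatially structured test data. Estimating Matérn parameters
jointly inside the mixed model was deliberately left out: the substantive
claim a reader needs is whether residual correlation persists beyond a few
degrees, which the diagnostic answers directly; a geodesic distance option
exists but Euclidean degrees are the default to match common practice in
this literature. For standardized residuals the all-pairs mean product is
identically $-1/n$, so the global (single-bin) statistic is uninformative
by construction; the signal lives in the near-vs-far contrast.

## The synthetic-data generator

Every stage is tested by parameter recovery on synthetic data with known
truth, generated by `synthetic_truth()` / `simulate_temperature()` /
`simulate_clutches()` and, across populations,
`simulate_metapopulation()`:

* **Daily temperature**: mean level (8 °C default) + seasonal cosine
  (amplitude 8 °C, peak mid-July, day 196) + linear warming trend + AR(1)
  daily noise (coefficient 0.7, innovation SD 2 °C) — the minimal
  autocorrelated weather model. The series runs from 1949 (configurable) so
  exposure can use the standard period.
* **Laying dates**: annual mean = baseline − sensitivity × (true-window
  mean temperature) + direct year trend; clutch-level dates add Gaussian
  noise (SD 2 days, 20 clutches/year) and are rounded to whole days, as in
  real daily-resolution records; records are emitted as
  observation-day/egg-count pairs so the reduction pipeline is exercised
  end-to-end.
* **Metapopulation structure**: habitat ordered along latitude (deciduous
  low, mixed middle, evergreen high), sensitivity means 4.8 / 3.4 / 2.9
  days/°C by habitat (SD 0.5), warming trend rising with latitude
  (0.0009 °C yr⁻¹ per degree plus site noise), and window midpoints 1.7
  days later per degree latitude. Jointly these make the generating
  sensitivity-exposure correlation ≈ −0.6; each finite draw of populations
  realizes its own correlation around that value (SD ≈ 0.08 at 60
  populations), which matters when interpreting recovery tests.

What passing tests show: the engine finds planted windows (midpoint MAE
well under a day at 40 years), the path model recovers planted
sensitivities to a few percent, exposure is exact on noiseless warming, the
randomization test is calibrated on null data, and the design's negative
covariance is recovered. What they do not show: realism of absolute dates
(the generator is not calibrated to any real population's phenology; no
claim of realism is tested), biological sources of misspecification (
nonlinear temperature responses, non-mean aggregates, relative windows are
all out of scope), or gridded-climate extraction issues — users supply a
per-population daily series.

## Numerical and design choices

* Residual sums of squares are floored at $10^{-300}$ before the
  log-likelihood so exact interpolation yields a huge but finite model
  support instead of NaN.
* Window degeneracy is declared at relative temperature variance
  $\le 10^{-12}$.
* At least 9 years of annual phenology are required before a search runs
  (configurable), matching the shortest series in which windows of this
  kind have been reliably quantified.
* The randomization re-uses the full window grid (no thinning); with the
  prefix-sum engine there is no computational reason to thin.
* `sample.int()` under a caller-supplied seed drives every stochastic
  stage; identical seeds give byte-identical results, which the tests
  assert stage by stage.
* Problem sizes in the bundled tests and the acceptance script (20
  populations, 40 years, 100 randomizations, 250-1000 bootstrap iterations)
  were chosen as the smallest sizes at which the recovery properties are
  stable; all scale linearly if increased.

## Known limitations

* The ≤ 14-day exclusion is applied to the single best window only; a
  population whose best window is short is flagged rather than re-searched
  among longer windows.
* The path model is population-level: it cannot separate individual
  plasticity from compositional change, and its "direct year" path absorbs
  every non-temperature trend without naming it.
* The advancement SE ignores sensitivity-exposure estimation covariance
  (they are estimated from overlapping data), so it is a lower bound in
  principle.
* REML fixed effects are only approximately invariant to balanced
  duplication of groups (the REML penalty does not scale); exact invariance
  holds under ML, and both are exercised in the tests.
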