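# Shared fixtures and independent oracles.

# AICc straight from the literal formula applied to an lm fit
aicc_lm <- function(m) {
  k <- attr(stats::logLik(m), "df")
  n <- stats::nobs(m)
  -2 * as.numeric(stats::logLik(m)) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Naive sliding-window search: one lm() per candidate window. Independent of
# the prefix-sum engine; used as the brute-force oracle.
brute_force_search <- function(phenology, temps, config) {
  specs <- enumerate_windows(config$max_span)
  w <- 1 / phenology$se_laying_doy^config$weight_power
  base <- stats::lm(mean_laying_doy ~ 1, data = phenology, weights = w)
  a0 <- aicc_lm(base)
  delta <- vapply(seq_len(nrow(specs)), function(i) {
    x <- window_mean_series(temps, specs$open[i], specs$close[i],
                            phenology$year, ref_doy = config$ref_doy)
    if (stats::var(x) <= 1e-12) return(Inf)
    aicc_lm(stats::lm(phenology$mean_laying_doy ~ x, weights = w)) - a0
  }, numeric(1))
  list(specs = specs, delta = delta, baseline_aicc = a0,
       best = order(delta, specs$duration, specs$open)[1L])
}

# One simulated population reduced to its annual phenology table
make_population <- function(seed = 1, years = 1978:2017, open = 120,
                            close = 61, sensitivity = 4, ...) {
  tr <- synthetic_truth(years = years, open = open, close = close,
                        sensitivity = sensitivity, ...)
  temps <- simulate_temperature(tr, seed = seed)
  clutches <- simulate_clutches(tr, temps, seed = seed)
  phen <- suppressWarnings(annual_phenology(clutches))
  list(truth = tr, temps = temps, clutches = clutches, phen = phen)
}

# Daily series whose temperature equals the non-leap day-of-year (calendar
# oracle for window means)
doy_valued_temps <- function(years) {
  dates <- seq(as.Date(paste0(min(years) - 1, "-01-01")),
               as.Date(paste0(max(years), "-12-31")), by = "day")
  lt <- as.POSIXlt(dates)
  dates <- dates[!(lt$mon == 1 & lt$mday == 29)]
  data.frame(population_id = "oracle", date = dates,
             tmean_c = as.numeric(doy_nonleap(dates)))
}
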