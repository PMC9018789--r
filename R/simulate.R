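# Synthetic multi-population generator with known ground truth.
#
# Daily temperature: mean level + seasonal cosine + linear warming trend +
# AR(1) noise. Laying dates: annual mean = baseline - sensitivity * (mean
# temperature in a hidden window) + direct year trend; clutch-level dates are
# the annual mean plus Gaussian noise, rounded to whole days, and emitted as
# (observation day, egg count) pairs consistent with one-egg-per-day
# back-calculation. Populations in a metapopulation get habitat-dependent
# sensitivity and latitude-dependent warming and window midpoint, inducing a
# negative sensitivity-exposure covariance across the range.

#' Ground-truth parameter set for one synthetic population
#'
#' @param population_id population identifier.
#' @param species species label (`"great_tit"` or `"blue_tit"`).
#' @param open,close true cue window, days before June 1 (inclusive).
#' @param sensitivity days laying advances per degree C of window-mean
#'   temperature (positive = earlier when warmer).
#' @param direct_year_trend direct change in laying date, days per year,
#'   not mediated by temperature.
#' @param warming_trend linear temperature trend, degrees C per year.
#' @param mean_level annual mean temperature level, degrees C.
#' @param seasonal_amplitude amplitude of the seasonal cycle, degrees C.
#' @param peak_doy day-of-year of the seasonal temperature peak.
#' @param ar_coefficient AR(1) coefficient of daily noise, |phi| < 1.
#' @param temp_noise_sd innovation SD of daily noise, degrees C.
#' @param baseline_doy laying-date intercept at window temperature 0 in the
#'   base year, day-of-year.
#' @param clutch_noise_sd clutch-level laying-date SD, days.
#' @param clutches_per_year clutches observed per year.
#' @param years inclusive range of study years (integer vector; only the
#'   range is used).
#' @param series_start_year first calendar year of the simulated temperature
#'   series; `NULL` (default) starts the year before the first study year.
#'   Set earlier (e.g. 1949) so climate-change exposure can be computed over
#'   the standard 1950-2017 period.
#' @param latitude,longitude,habitat,precipitation_pc population metadata
#'   carried along for downstream stages.
#' @return a `synthetic_truth` list.
#' @export
synthetic_truth <- function(population_id = "pop_01",
                            species = "great_tit",
                            open = 120L, close = 61L,
                            sensitivity = 4,
                            direct_year_trend = -0.1,
                            warming_trend = 0.03,
                            mean_level = 8,
                            seasonal_amplitude = 8,
                            peak_doy = 196,
                            ar_coefficient = 0.7,
                            temp_noise_sd = 2,
                            baseline_doy = 160,
                            clutch_noise_sd = 2,
                            clutches_per_year = 20L,
                            years = 1978:2017,
                            series_start_year = NULL,
                            latitude = 52, longitude = 5,
                            habitat = "deciduous",
                            precipitation_pc = 0) {
  check_window_spec(open, close)
  stopifnot(abs(ar_coefficient) < 1, temp_noise_sd >= 0, clutch_noise_sd >= 0,
            clutches_per_year >= 1, length(years) >= 2)
  structure(list(population_id = population_id, species = species,
                 open = as.integer(open), close = as.integer(close),
                 sensitivity = sensitivity,
                 direct_year_trend = direct_year_trend,
                 warming_trend = warming_trend,
                 mean_level = mean_level,
                 seasonal_amplitude = seasonal_amplitude,
                 peak_doy = peak_doy,
                 ar_coefficient = ar_coefficient,
                 temp_noise_sd = temp_noise_sd,
                 baseline_doy = baseline_doy,
                 clutch_noise_sd = clutch_noise_sd,
                 clutches_per_year = as.integer(clutches_per_year),
                 years = as.integer(range(years)),
                 series_start_year =
                   if (is.null(series_start_year)) NULL
                   else as.integer(series_start_year),
                 latitude = latitude, longitude = longitude,
                 habitat = habitat, precipitation_pc = precipitation_pc),
            class = "synthetic_truth")
}

# all calendar dates of [y0, y1] with Feb 29 removed
.nonleap_dates <- function(y0, y1) {
  d <- seq(as.Date(sprintf("%04d-01-01", y0)),
           as.Date(sprintf("%04d-12-31", y1)), by = "day")
  lt <- as.POSIXlt(d)
  d[!(lt$mon == 1L & lt$mday == 29L)]
}

#' Simulate a daily mean-temperature series
#'
#' Covers calendar years `min(years) - 1` to `max(years)` (the extra year
#' ahead of the study supports windows reaching into the previous year) on
#' the 365-day calendar. The warming trend is indexed on the calendar year
#' relative to the first study year.
#'
#' @param truth a [synthetic_truth()] object.
#' @param seed integer seed; the series is a deterministic function of it.
#' @return data frame `population_id`, `date`, `tmean_c`.
#' @export
simulate_temperature <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  y0 <- truth$years[1] - 1L
  if (!is.null(truth$series_start_year)) {
    y0 <- min(y0, truth$series_start_year)
  }
  y1 <- truth$years[2]
  dates <- .nonleap_dates(y0, y1)
  yr <- as.integer(format(dates, "%Y"))
  doy <- doy_nonleap(dates)
  det <- truth$mean_level +
    truth$seasonal_amplitude * cos(2 * pi * (doy - truth$peak_doy) / 365) +
    truth$warming_trend * (yr - truth$years[1])
  n <- length(dates)
  if (truth$temp_noise_sd > 0) {
    innov <- stats::rnorm(n, 0, truth$temp_noise_sd)
    phi <- truth$ar_coefficient
    init <- stats::rnorm(1, 0, truth$temp_noise_sd /
                              sqrt(max(1 - phi^2, .Machine$double.eps)))
    noise <- as.numeric(stats::filter(innov, phi, method = "recursive",
                                      init = init))
  } else {
    noise <- numeric(n)
  }
  data.frame(population_id = truth$population_id,
             date = dates, tmean_c = det + noise)
}

#' Simulate clutch records driven by a hidden temperature window
#'
#' For each study year the expected mean laying date is
#' `baseline_doy - sensitivity * mean(window temperature) +
#' direct_year_trend * (year - first year)`; individual clutches add
#' Gaussian noise and are rounded to whole days. Each record is emitted as a
#' first observation `eggs_at_observation - 1` days after laying so that
#' one-egg-per-day back-calculation recovers the laying date exactly.
#'
#' @param truth a [synthetic_truth()] object.
#' @param temps daily temperature series covering the true window in every
#'   study year (e.g. from [simulate_temperature()]).
#' @param seed integer seed.
#' @return data frame of clutch records (`population_id`, `species`, `year`,
#'   `nest_id`, `observation_doy`, `eggs_at_observation`).
#' @export
simulate_clutches <- function(truth, temps, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed + 1L)
  years <- seq.int(truth$years[1], truth$years[2])
  tw <- window_mean_series(temps, truth$open, truth$close, years)
  mu <- truth$baseline_doy - truth$sensitivity * tw +
    truth$direct_year_trend * (years - truth$years[1])
  nc <- truth$clutches_per_year
  rows <- lapply(seq_along(years), function(i) {
    laying <- round(mu[i] + stats::rnorm(nc, 0, truth$clutch_noise_sd))
    eggs <- sample.int(5L, nc, replace = TRUE)
    data.frame(population_id = truth$population_id,
               species = truth$species,
               year = years[i],
               nest_id = sprintf("%s_%d_%02d", truth$population_id,
                                 years[i], seq_len(nc)),
               observation_doy = laying + eggs - 1L,
               eggs_at_observation = eggs)
  })
  do.call(rbind, rows)
}

#' Metapopulation design parameters
#'
#' Encodes the cross-population structure the generator emulates: deciduous
#' habitats more temperature-sensitive than mixed/evergreen, warming
#' (exposure) increasing with latitude, evergreen habitat more probable at
#' high latitude, and window midpoints later at high latitude. The joint
#' effect is a negative correlation between generating sensitivity and
#' warming trend across populations (about -0.6 under the defaults).
#'
#' @param lat_range latitude range populations are drawn from (degrees N).
#' @param sens_mean named mean sensitivity (days/C) per habitat.
#' @param sens_sd between-population SD of sensitivity within habitat.
#' @param warming_base warming trend (C/yr) at the low end of `lat_range`.
#' @param warming_per_degree increase in warming trend per degree latitude.
#' @param warming_sd population-level noise on the warming trend.
#' @param deciduous_logit_center latitude (degrees) below which sites are
#'   predominantly deciduous.
#' @param evergreen_logit_center latitude (degrees) above which sites are
#'   predominantly evergreen; mixed habitat dominates in between.
#' @param habitat_logit_scale logistic scale (degrees) of both transitions.
#' @param midpoint_per_degree shift of the true window midpoint, days later
#'   per degree latitude.
#' @param duration true window duration in days (fixed across populations).
#' @param prop_both_species fraction of sites holding both tit species.
#' @param sensitivity_range admissible sensitivity values; draws are clamped
#'   to it (days/C).
#' @param years study years for every population.
#' @param series_start_year first year of each simulated temperature series
#'   (default 1949, supporting exposure over the standard 1950-2017 period).
#' @param clutches_per_year,clutch_noise_sd observation design per year.
#' @return a list of design parameters for [simulate_metapopulation()].
#' @export
metapop_design <- function(lat_range = c(40, 68),
                           sens_mean = c(deciduous = 4.8, mixed = 3.4,
                                         evergreen = 2.9),
                           sens_sd = 0.5,
                           warming_base = 0.015,
                           warming_per_degree = 0.0009,
                           warming_sd = 0.003,
                           deciduous_logit_center = 50,
                           evergreen_logit_center = 60,
                           habitat_logit_scale = 3,
                           midpoint_per_degree = 1.7,
                           duration = 60L,
                           prop_both_species = 0.4,
                           sensitivity_range = c(1.5, 7.5),
                           years = 1978:2017,
                           series_start_year = 1949L,
                           clutches_per_year = 20L,
                           clutch_noise_sd = 2) {
  as.list(environment())
}

#' Simulate a metapopulation with known ground truth
#'
#' Draws `n_pops` site-by-species populations under a [metapop_design()],
#' returning metadata, the generating truth per population, and (optionally)
#' the full clutch and daily-temperature tables.
#'
#' @param n_pops number of populations (site x species units).
#' @param design a [metapop_design()] list.
#' @param seed integer seed controlling every draw.
#' @param clutch_data if `FALSE`, skip simulating daily temperatures and
#'   clutches and return parameters only (fast; useful when only the
#'   generating sensitivity/exposure values are needed).
#' @return list with `meta` (population metadata), `truth` (one row per
#'   population: generating window, sensitivity, warming trend, ...),
#'   `clutches` and `temperature` (NULL when `clutch_data = FALSE`), and
#'   `truths` (the underlying `synthetic_truth` objects).
#' @export
simulate_metapopulation <- function(n_pops, design = metapop_design(),
                                    seed = 1L, clutch_data = TRUE) {
  stopifnot(n_pops >= 0)
  empty <- list(meta = data.frame(), truth = data.frame(),
                clutches = NULL, temperature = NULL, truths = list())
  if (n_pops == 0L) return(empty)
  set.seed(seed)
  d <- design

  # one unit per site guaranteed, so n_pops sites always yield enough
  # site x species units after truncation
  n_sites <- n_pops
  lat <- stats::runif(n_sites, d$lat_range[1], d$lat_range[2])
  lon <- stats::runif(n_sites, -4, 30)
  # ordered habitat gradient: deciduous at low, mixed at intermediate,
  # evergreen at high latitude
  p_ever <- stats::plogis((lat - d$evergreen_logit_center) /
                            d$habitat_logit_scale)
  p_decid <- (1 - p_ever) * stats::plogis((d$deciduous_logit_center - lat) /
                                            d$habitat_logit_scale)
  u <- stats::runif(n_sites)
  habitat <- ifelse(u < p_ever, "evergreen",
                    ifelse(u < p_ever + p_decid, "deciduous", "mixed"))
  both <- stats::runif(n_sites) < d$prop_both_species
  site_warming <- d$warming_base +
    d$warming_per_degree * (lat - d$lat_range[1]) +
    stats::rnorm(n_sites, 0, d$warming_sd)

  # expand sites to site x species units, truncated to n_pops
  sp <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    sp[[i]] <- if (both[i]) c("great_tit", "blue_tit") else
      sample(c("great_tit", "blue_tit"), 1L)
  }
  site_idx <- rep(seq_len(n_sites), lengths(sp))[seq_len(n_pops)]
  species <- unlist(sp)[seq_len(n_pops)]

  y0 <- min(d$years)
  truths <- vector("list", n_pops)
  for (j in seq_len(n_pops)) {
    i <- site_idx[j]
    hb <- habitat[i]
    sens <- stats::rnorm(1, d$sens_mean[[hb]], d$sens_sd)
    sens <- min(max(sens, d$sensitivity_range[1]), d$sensitivity_range[2])
    warming <- site_warming[i]
    midpoint <- 61 + d$midpoint_per_degree * (lat[i] - 54)
    oc_sum <- round(2 * (152 - midpoint))            # open + close
    close <- max(1L, as.integer(round((oc_sum - d$duration + 1) / 2)))
    open <- as.integer(close + d$duration - 1L)
    if (open > 365L) { open <- 365L; close <- open - d$duration + 1L }
    truths[[j]] <- synthetic_truth(
      population_id = sprintf("site_%02d", i),
      species = species[j],
      open = open, close = close,
      sensitivity = sens,
      direct_year_trend = stats::rnorm(1, -0.05, 0.05),
      warming_trend = warming,
      mean_level = 8 - 0.25 * (lat[i] - 54),
      habitat = hb, latitude = lat[i], longitude = lon[i],
      precipitation_pc = stats::rnorm(1),
      years = d$years,
      series_start_year = d$series_start_year,
      clutches_per_year = d$clutches_per_year,
      clutch_noise_sd = d$clutch_noise_sd)
  }

  truth_df <- do.call(rbind, lapply(truths, function(tr) {
    data.frame(population_id = tr$population_id, species = tr$species,
               open = tr$open, close = tr$close,
               midpoint_doy = 152 - (tr$open + tr$close) / 2,
               sensitivity = tr$sensitivity,
               direct_year_trend = tr$direct_year_trend,
               warming_trend = tr$warming_trend,
               latitude = tr$latitude, longitude = tr$longitude,
               habitat = tr$habitat,
               precipitation_pc = tr$precipitation_pc)
  }))
  meta <- truth_df[c("population_id", "species", "latitude", "longitude",
                     "habitat", "precipitation_pc")]

  clutches <- temperature <- NULL
  if (clutch_data) {
    seeds <- sample.int(.Machine$integer.max %/% 4L, n_pops)
    # one daily series per site (shared by both species at a site)
    first_at_site <- !duplicated(site_idx)
    temp_list <- list()
    for (j in which(first_at_site)) {
      temp_list[[as.character(site_idx[j])]] <-
        simulate_temperature(truths[[j]], seed = seeds[j])
    }
    temperature <- do.call(rbind, temp_list)
    rownames(temperature) <- NULL
    clutches <- do.call(rbind, lapply(seq_len(n_pops), function(j) {
      simulate_clutches(truths[[j]],
                        temp_list[[as.character(site_idx[j])]],
                        seed = seeds[j])
    }))
  }
  list(meta = meta, truth = truth_df, clutches = clutches,
       temperature = temperature, truths = truths)
}
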