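# Trait-level generator for the comparative (drivers) stage: per-population
# window descriptors and sensitivities drawn directly from a linear
# mixed-model truth, bypassing the clutch-level pipeline. Used to score
# driver-model recovery and bootstrap coverage where clutch-level detail is
# irrelevant.

#' Truth coefficients for the driver-stage trait generator
#'
#' Defaults mirror the magnitudes the comparative models are designed to
#' detect: window midpoints 1.7 days later per degree latitude and ~9.6 days
#' later in evergreen habitat; sensitivity lower by ~0.9 days/C in evergreen
#' and ~0.74 in mixed habitat relative to deciduous, rising with the annual
#' precipitation score.
#'
#' @param midpoint_intercept midpoint (day-of-year) of a deciduous great-tit
#'   population at `lat_center`.
#' @param beta_latitude days later per degree latitude.
#' @param beta_evergreen_midpoint,beta_mixed_midpoint habitat offsets, days.
#' @param sens_intercept deciduous great-tit sensitivity, days/C.
#' @param beta_evergreen_sens,beta_mixed_sens habitat offsets, days/C.
#' @param beta_precip_sens days/C per unit precipitation score.
#' @param beta_species_sens blue-tit offset, days/C.
#' @param site_sd random site-intercept SD (same units as each response).
#' @param resid_midpoint_sd,resid_sens_sd residual SDs.
#' @param lat_range,lat_center latitude span and centering constant.
#' @param prop_both_species fraction of sites with both species.
#' @return list of truth parameters for [simulate_driver_traits()].
#' @export
driver_truth <- function(midpoint_intercept = 61,
                         beta_latitude = 1.7,
                         beta_evergreen_midpoint = 9.56,
                         beta_mixed_midpoint = 4,
                         sens_intercept = 4.5,
                         beta_evergreen_sens = -0.9,
                         beta_mixed_sens = -0.74,
                         beta_precip_sens = 0.3,
                         beta_species_sens = -0.2,
                         site_sd = 1,
                         resid_midpoint_sd = 2,
                         resid_sens_sd = 0.5,
                         lat_range = c(40, 68),
                         lat_center = 54,
                         prop_both_species = 0.4) {
  as.list(environment())
}

#' Simulate driver-stage traits with known coefficients
#'
#' @param n_sites number of study sites (each contributing one or two
#'   species rows).
#' @param truth a [driver_truth()] list.
#' @param seed integer seed.
#' @return list with `data` (one row per population x species:
#'   `population_id`, `species`, `latitude`, `longitude`, `habitat`,
#'   `precipitation_pc`, `midpoint_doy`, `sensitivity`) and `truth`.
#' @export
simulate_driver_traits <- function(n_sites, truth = driver_truth(),
                                   seed = 1L) {
  set.seed(seed)
  tr <- truth
  lat <- stats::runif(n_sites, tr$lat_range[1], tr$lat_range[2])
  lon <- stats::runif(n_sites, -4, 30)
  p_ever <- stats::plogis((lat - 60) / 3)
  p_decid <- (1 - p_ever) * stats::plogis((50 - lat) / 3)
  u <- stats::runif(n_sites)
  habitat <- ifelse(u < p_ever, "evergreen",
                    ifelse(u < p_ever + p_decid, "deciduous", "mixed"))
  precip <- stats::rnorm(n_sites)
  site_mid <- stats::rnorm(n_sites, 0, tr$site_sd)
  site_sens <- stats::rnorm(n_sites, 0, tr$site_sd * tr$resid_sens_sd /
                              max(tr$resid_midpoint_sd, 1e-12))
  both <- stats::runif(n_sites) < tr$prop_both_species

  rows <- lapply(seq_len(n_sites), function(i) {
    species <- if (both[i]) c("great_tit", "blue_tit") else
      sample(c("great_tit", "blue_tit"), 1L)
    hb <- habitat[i]
    mid_fix <- tr$midpoint_intercept +
      tr$beta_latitude * (lat[i] - tr$lat_center) +
      (hb == "evergreen") * tr$beta_evergreen_midpoint +
      (hb == "mixed") * tr$beta_mixed_midpoint
    sens_fix <- tr$sens_intercept +
      (hb == "evergreen") * tr$beta_evergreen_sens +
      (hb == "mixed") * tr$beta_mixed_sens +
      tr$beta_precip_sens * precip[i] +
      (species == "blue_tit") * tr$beta_species_sens
    data.frame(population_id = sprintf("site_%03d", i),
               species = species,
               latitude = lat[i], longitude = lon[i],
               habitat = hb, precipitation_pc = precip[i],
               midpoint_doy = mid_fix + site_mid[i] +
                 stats::rnorm(length(species), 0, tr$resid_midpoint_sd),
               sensitivity = sens_fix + site_sens[i] +
                 stats::rnorm(length(species), 0, tr$resid_sens_sd))
  })
  list(data = do.call(rbind, rows), truth = tr)
}
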