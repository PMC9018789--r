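# Climate-change exposure, expected advancement, and the cross-population
# sensitivity-exposure covariance.
#
# Exposure is the OLS slope of per-year window-mean temperature on calendar
# year over a standard period (default 1950-2017) so that populations with
# different study spans are comparable. Expected advancement is
# sensitivity x exposure (days advanced per year), "expected" because
# sensitivity is estimated on the study years while exposure uses the
# standard period.

#' Climate-change exposure of one population
#'
#' @param temps daily temperature data frame (`date`, `tmean_c`).
#' @param open,close the population's cue window (days before reference).
#' @param period inclusive year range (default `c(1950, 2017)`).
#' @param ref_doy reference day-of-year.
#' @param min_years_used minimum usable years in the period (default 10).
#' @return one-row data frame: `exposure` (degrees C per year),
#'   `se_exposure`, `period_start`, `period_end`, `n_years_used`,
#'   `n_years_dropped` (years whose window lacked full coverage).
#' @export
compute_exposure <- function(temps, open, close, period = c(1950, 2017),
                             ref_doy = .ref_doy_default,
                             min_years_used = 10L) {
  check_window_spec(open, close)
  years <- seq.int(period[1], period[2])
  tw <- rep(NA_real_, length(years))
  for (i in seq_along(years)) {
    tw[i] <- tryCatch(
      window_mean_series(temps, open, close, years[i], ref_doy = ref_doy),
      error = function(e) NA_real_)
  }
  ok <- !is.na(tw)
  n_drop <- sum(!ok)
  if (n_drop > 0L) {
    message(n_drop, " year(s) in ", period[1], "-", period[2],
            " dropped: window not fully covered by the temperature series")
  }
  if (sum(ok) < min_years_used) {
    stop("insufficient period coverage: only ", sum(ok),
         " usable year(s) in ", period[1], "-", period[2], call. = FALSE)
  }
  fit <- stats::lm(tw[ok] ~ years[ok])
  sm <- summary(fit)$coefficients
  data.frame(exposure = unname(sm[2L, 1L]),
             se_exposure = unname(sm[2L, 2L]),
             period_start = period[1], period_end = period[2],
             n_years_used = sum(ok), n_years_dropped = n_drop)
}

#' Expected phenological advancement
#'
#' Advancement = sensitivity x exposure (days advanced per year); its SE is
#' propagated to first order by the delta method,
#' `sqrt(E^2 SE_S^2 + S^2 SE_E^2)` (reported alongside, not used for
#' weighting).
#'
#' @param sensitivity days advanced per degree C.
#' @param exposure degrees C per year.
#' @param se_sensitivity,se_exposure standard errors of the two inputs.
#' @return one-row data frame: `advancement`, `se_advancement`.
#' @export
compute_advancement <- function(sensitivity, exposure,
                                se_sensitivity = NA_real_,
                                se_exposure = NA_real_) {
  data.frame(advancement = sensitivity * exposure,
             se_advancement = sqrt(exposure^2 * se_sensitivity^2 +
                                     sensitivity^2 * se_exposure^2))
}

#' Bootstrapped sensitivity-exposure correlation across populations
#'
#' Pearson correlation between per-population sensitivity and exposure with
#' a nonparametric bootstrap (populations resampled with replacement)
#' percentile confidence interval. Degenerate resamples (zero variance on
#' either axis) are redrawn.
#'
#' @param sensitivity,exposure aligned per-population vectors.
#' @param n_boot bootstrap iterations (default 5000).
#' @param seed integer seed.
#' @param conf confidence level of the percentile interval (default 0.95).
#' @return list of class `covariance_result`: `pearson_r`, `boot_ci_low`,
#'   `boot_ci_high`, `boot_r` (all draws), `n_boot`, `n_populations`.
#' @export
covariance_bootstrap <- function(sensitivity, exposure, n_boot = 5000L,
                                 seed = 1L, conf = 0.95) {
  n <- length(sensitivity)
  stopifnot(length(exposure) == n)
  if (n < 3L) {
    stop("need at least 3 populations for the correlation", call. = FALSE)
  }
  r_hat <- stats::cor(sensitivity, exposure)
  set.seed(seed)
  rs <- numeric(n_boot)
  b <- 1L
  tries <- 0L
  while (b <= n_boot) {
    tries <- tries + 1L
    if (tries > 4L * n_boot) {
      stop("bootstrap unstable: too many degenerate resamples", call. = FALSE)
    }
    idx <- sample.int(n, replace = TRUE)
    if (stats::var(sensitivity[idx]) <= 0 || stats::var(exposure[idx]) <= 0) {
      next
    }
    rs[b] <- stats::cor(sensitivity[idx], exposure[idx])
    b <- b + 1L
  }
  qs <- stats::quantile(rs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  structure(list(pearson_r = r_hat,
                 boot_ci_low = min(qs[1L], r_hat),
                 boot_ci_high = max(qs[2L], r_hat),
                 boot_r = rs, n_boot = as.integer(n_boot),
                 n_populations = n),
            class = "covariance_result")
}

#' @export
print.covariance_result <- function(x, ...) {
  cat(sprintf(
    "Sensitivity-exposure correlation: r = %.3f (95%% bootstrap CI %.3f / %.3f; %d populations, %d iterations)\n",
    x$pearson_r, x$boot_ci_low, x$boot_ci_high, x$n_populations, x$n_boot))
  invisible(x)
}
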