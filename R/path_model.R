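# Phenological sensitivity via a recursive two-equation path model.
#
#   Temperature = a0 + a1 * Year + e1
#   Laying      = b0 + b1 * Temperature + b2 * Year + e2
#
# With uncorrelated errors, equation-wise least squares is the exact
# estimator of this recursive system, so no SEM machinery is needed. b1 is
# the temperature path (slope_raw); sensitivity = -b1 (days advanced per C);
# b2 the direct year path; a1*b1 the indirect (temperature-mediated) year
# path. Direct + indirect reproduce the marginal laying~year slope exactly
# when both equations share the same weights.

#' Fit the temperature/year path model for one population
#'
#' @param year calendar years (centered internally; slopes unaffected).
#' @param temperature per-year window-mean temperature (degrees C).
#' @param laying per-year mean laying day-of-year.
#' @param weights optional observation weights for the laying equation
#'   (e.g. `1/SE`); `NULL` for unweighted.
#' @param weight_temperature apply the same weights to the temperature
#'   equation (makes the direct + indirect decomposition exact under
#'   weighting); default `FALSE`, the temperature trend being a property of
#'   the climate series alone.
#' @return object of class `path_fit`: `slope_raw` (b1, days per C),
#'   `sensitivity` (= -b1), `direct_year_effect` (b2, days/yr),
#'   `year_temp_slope` (a1, C/yr), `indirect_year_effect` (a1*b1),
#'   `n_years`.
#' @export
fit_path_model <- function(year, temperature, laying, weights = NULL,
                           weight_temperature = FALSE) {
  n <- length(year)
  stopifnot(length(temperature) == n, length(laying) == n)
  if (n < 4L) stop("need at least 4 years for the path model", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  yc <- year - mean(year)

  wt <- if (weight_temperature) weights else rep(1, n)
  f1 <- stats::lm.wfit(cbind(1, yc), temperature, wt)
  a1 <- f1$coefficients[2L]
  resid_var <- sum(wt * f1$residuals^2) / sum(wt)
  if (resid_var <= 1e-10 * max(1, mean(temperature)^2)) {
    stop("degenerate path model: temperature is (numerically) an exact ",
         "linear function of year, so the temperature and year paths are ",
         "not separately identifiable", call. = FALSE)
  }
  f2 <- stats::lm.wfit(cbind(1, temperature, yc), laying, weights)
  b1 <- f2$coefficients[2L]
  b2 <- f2$coefficients[3L]
  structure(list(slope_raw = unname(b1), sensitivity = -unname(b1),
                 direct_year_effect = unname(b2),
                 year_temp_slope = unname(a1),
                 indirect_year_effect = unname(a1 * b1),
                 n_years = n),
            class = "path_fit")
}

#' Nonparametric bootstrap SE for the path-model sensitivity
#'
#' Resamples years with replacement, refits the path model, and reports the
#' SD of the temperature-path coefficient. Degenerate resamples (no
#' temperature or year variance) are redrawn; more than 50% degenerate draws
#' aborts with an error.
#'
#' @inheritParams fit_path_model
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @return a `path_fit` augmented with `se_sensitivity`, `n_boot`, and
#'   `n_degenerate_redrawn`.
#' @export
bootstrap_sensitivity <- function(year, temperature, laying, weights = NULL,
                                  weight_temperature = FALSE,
                                  n_boot = 1000L, seed = 1L) {
  fit <- fit_path_model(year, temperature, laying, weights,
                        weight_temperature)
  n <- length(year)
  if (is.null(weights)) weights <- rep(1, n)
  yc <- year - mean(year)
  set.seed(seed)
  b1s <- numeric(n_boot)
  n_degen <- 0L
  max_tries <- 2L * n_boot
  tries <- 0L
  r <- 1L
  while (r <= n_boot) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("unstable bootstrap: more than 50% of resamples were degenerate",
           call. = FALSE)
    }
    idx <- sample.int(n, replace = TRUE)
    tv <- stats::var(temperature[idx])
    yv <- stats::var(yc[idx])
    if (!is.finite(tv) || tv <= 1e-12 || yv <= 1e-12) {
      n_degen <- n_degen + 1L
      next
    }
    wts <- weights[idx]
    f2 <- stats::lm.wfit(cbind(1, temperature[idx], yc[idx]), laying[idx],
                         wts)
    b1 <- f2$coefficients[2L]
    if (!is.finite(b1)) { n_degen <- n_degen + 1L; next }
    b1s[r] <- b1
    r <- r + 1L
  }
  if (n_degen > 0L) {
    message(n_degen, " degenerate bootstrap resample(s) redrawn")
  }
  fit$se_sensitivity <- stats::sd(b1s)
  fit$n_boot <- as.integer(n_boot)
  fit$n_degenerate_redrawn <- n_degen
  fit
}

#' Sensitivity estimate for one population from its search result
#'
#' Convenience wrapper: extracts the best window from a
#' [randomization_test()] / [search_best_window()] result, builds the
#' per-year window-mean temperature, and runs the path model with
#' bootstrap SE using the same inverse-SE weights as the search.
#'
#' @param result a `window_search` object with a non-null best window.
#' @param temps the daily temperature series used for the search.
#' @param n_boot,seed passed to [bootstrap_sensitivity()].
#' @return one-row data frame: `sensitivity`, `se_sensitivity`,
#'   `slope_raw`, `direct_year_effect`, `indirect_year_effect`, `n_years`.
#' @export
population_sensitivity <- function(result, temps, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(result, "window_search"), !is.null(result$best))
  phen <- result$phenology
  tw <- window_mean_series(temps, result$best$open, result$best$close,
                           phen$year, ref_doy = result$config$ref_doy)
  w <- .weights_from_se(phen$se_laying_doy, result$config$weight_power)
  fit <- bootstrap_sensitivity(phen$year, tw, phen$mean_laying_doy,
                               weights = w, n_boot = n_boot, seed = seed)
  data.frame(sensitivity = fit$sensitivity,
             se_sensitivity = fit$se_sensitivity,
             slope_raw = fit$slope_raw,
             direct_year_effect = fit$direct_year_effect,
             indirect_year_effect = fit$indirect_year_effect,
             n_years = fit$n_years)
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("Path model (%d years)\n", x$n_years))
  cat(sprintf("  sensitivity: %.3f days advanced/C%s\n", x$sensitivity,
              if (!is.null(x$se_sensitivity))
                sprintf(" (bootstrap SE %.3f, n_boot %d)",
                        x$se_sensitivity, x$n_boot) else ""))
  cat(sprintf("  direct year effect:   %+.4f days/yr\n",
              x$direct_year_effect))
  cat(sprintf("  indirect year effect: %+.4f days/yr (via %.4f C/yr)\n",
              x$indirect_year_effect, x$year_temp_slope))
  invisible(x)
}
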