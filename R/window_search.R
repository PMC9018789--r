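# Exhaustive absolute sliding-window search.
#
# Every contiguous window of 1..max_span days before the reference date
# (June 1 by default) is scored by a weighted Gaussian linear regression of
# annual mean laying date on window-mean temperature, compared via AICc to an
# intercept-only baseline. Window means for the full grid are obtained from
# per-year prefix sums, so each candidate costs O(1) and the full 66,795-
# window grid is a handful of matrix products. False-positive control:
# phenology-to-year assignment is permuted n_rand times, the search re-run,
# and P_deltaAICc is the add-one empirical percentile of the observed best
# deltaAICc within the randomized best deltaAICc distribution.

#' Enumerate all candidate windows
#'
#' All integer pairs `(open, close)` with `max_span >= open >= close >= 1`,
#' ordered by `open` then `close` ascending; there are
#' `max_span * (max_span + 1) / 2` of them.
#'
#' @param max_span maximum days before the reference date (default 365).
#' @return data frame with columns `open`, `close`, `duration`.
#' @export
enumerate_windows <- function(max_span = 365L) {
  if (length(max_span) != 1L || !is.finite(max_span) || max_span < 1) {
    stop("max_span must be a single integer >= 1", call. = FALSE)
  }
  max_span <- as.integer(max_span)
  open <- rep.int(seq_len(max_span), seq_len(max_span))
  close <- sequence(seq_len(max_span))
  data.frame(open = open, close = close, duration = open - close + 1L)
}

#' Search configuration
#'
#' @param max_span largest window extent in days before the reference date.
#' @param ref_doy reference day-of-year (June 1 = 152, non-leap).
#' @param min_years minimum number of phenology years required.
#' @param weight_power inverse-SE weight exponent: 1 gives `w = 1/SE`
#'   (default), 2 gives `w = 1/SE^2`.
#' @param alpha P_deltaAICc threshold for accepting a cue.
#' @param min_cue_duration best windows at or below this duration (days) are
#'   excluded as biologically implausible statistical artefacts.
#' @return a list of configuration values.
#' @export
window_config <- function(max_span = 365L, ref_doy = .ref_doy_default,
                          min_years = 9L, weight_power = 1,
                          alpha = 0.05, min_cue_duration = 14L) {
  stopifnot(weight_power %in% c(1, 2))
  list(max_span = as.integer(max_span), ref_doy = as.integer(ref_doy),
       min_years = as.integer(min_years), weight_power = weight_power,
       alpha = alpha, min_cue_duration = as.integer(min_cue_duration))
}

# Matrix of daily temperatures addressed as days-before-reference:
# element [i, d] is the temperature d days before the reference date of
# years[i]. Errors if any required day is missing from the series.
.temp_matrix <- function(temps, years, max_span, ref_doy) {
  stopifnot(is.data.frame(temps), all(c("date", "tmean_c") %in% names(temps)))
  yr <- as.integer(format(temps$date, "%Y"))
  doy <- doy_nonleap(temps$date)
  y_min <- min(yr)
  key <- (yr - y_min) * 365L + doy
  if (anyDuplicated(key)) {
    stop("temperature series has duplicate days", call. = FALSE)
  }
  lookup <- rep(NA_real_, (max(yr) - y_min + 1L) * 365L)
  lookup[key] <- temps$tmean_c

  d <- seq_len(max_span)
  raw <- ref_doy - d                       # may be <= 0: previous year
  prev <- raw < 1L
  doy_d <- raw + 365L * prev
  m <- matrix(NA_real_, length(years), max_span)
  for (i in seq_along(years)) {
    y_d <- years[i] - as.integer(prev)
    idx <- (y_d - y_min) * 365L + doy_d
    bad <- y_d < y_min | y_d > max(yr)
    vals <- rep(NA_real_, max_span)
    vals[!bad] <- lookup[idx[!bad]]
    if (anyNA(vals)) {
      stop("missing temperature coverage for year ", years[i],
           " (days ", min(d[is.na(vals)]), "-", max(d[is.na(vals)]),
           " before the reference date)", call. = FALSE)
    }
    m[i, ] <- vals
  }
  m
}

#' Per-year mean temperature within one window
#'
#' @param temps daily temperature data frame (`date`, `tmean_c`).
#' @param open,close window boundaries in days before the reference date.
#' @param years focal years.
#' @param ref_doy reference day-of-year.
#' @return numeric vector of window-mean temperatures, one per year.
#' @export
window_mean_series <- function(temps, open, close, years,
                               ref_doy = .ref_doy_default) {
  check_window_spec(open, close)
  m <- .temp_matrix(temps, years, max_span = open, ref_doy = ref_doy)
  rowMeans(m[, close:open, drop = FALSE])
}

# Precomputed grid: window-mean matrix X (years x windows) and its square,
# from per-year prefix sums over days-before-reference.
.window_grid <- function(temps, years, config) {
  tm <- .temp_matrix(temps, years, config$max_span, config$ref_doy)
  P <- cbind(0, t(apply(tm, 1L, cumsum)))          # P[, d+1] = sum over 1..d
  specs <- enumerate_windows(config$max_span)
  X <- (P[, specs$open + 1L, drop = FALSE] -
          P[, specs$close, drop = FALSE]) /
    rep(specs$duration, each = length(years))
  list(X = X, X2 = X * X, specs = specs, years = years)
}

# log-likelihood of a weighted Gaussian least-squares fit at its MLE
# (the convention of standard WLS fitting software: weights scale the
# error precision, sigma^2 profiled out).
.wls_loglik <- function(rss, w, n) {
  0.5 * (sum(log(w)) - n * (log(2 * pi) + 1 - log(n) + log(rss)))
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)` with `k` the number of
#' estimated parameters including the residual variance.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of parameters (intercept-only Gaussian fit: 2).
#' @param n number of observations; requires `n - k - 1 > 0`.
#' @return the AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) {
    stop("insufficient data for AICc: need n > k + 1 (n = ", n,
         ", k = ", k, ")", call. = FALSE)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

.weights_from_se <- function(se, weight_power) 1 / se^weight_power

#' Intercept-only weighted baseline fit
#'
#' Gaussian fit of annual mean laying date with inverse-SE weights; the
#' comparison point for every candidate window model.
#'
#' @param phenology annual phenology data frame (`mean_laying_doy`,
#'   `se_laying_doy`).
#' @param config a [window_config()].
#' @return list with `intercept`, `loglik`, `aicc`, `n`.
#' @export
fit_baseline <- function(phenology, config = window_config()) {
  y <- phenology$mean_laying_doy
  w <- .weights_from_se(phenology$se_laying_doy, config$weight_power)
  n <- length(y)
  mu <- sum(w * y) / sum(w)
  rss <- sum(w * (y - mu)^2)
  ll <- .wls_loglik(max(rss, 1e-300), w, n)
  list(intercept = mu, loglik = ll, aicc = aicc(ll, 2L, n), n = n)
}

#' Weighted linear fit of laying date on one window's temperature
#'
#' @param phenology annual phenology data frame (`mean_laying_doy`,
#'   `se_laying_doy`), aligned with `window_means`.
#' @param window_means per-year mean temperature of the candidate window.
#' @param config a [window_config()].
#' @param baseline optional precomputed [fit_baseline()] result.
#' @return list with `slope` (days per degree C), `intercept`, `aicc`,
#'   `delta_aicc` (window AICc minus baseline AICc), `degenerate` (zero
#'   temperature variance; `delta_aicc = Inf`).
#' @export
fit_window_model <- function(phenology, window_means,
                             config = window_config(), baseline = NULL) {
  y <- phenology$mean_laying_doy
  w <- .weights_from_se(phenology$se_laying_doy, config$weight_power)
  n <- length(y)
  stopifnot(length(window_means) == n)
  if (is.null(baseline)) baseline <- fit_baseline(phenology, config)
  x <- window_means
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  sxx <- sum(w * x^2) - swx^2 / sw
  sxy <- sum(w * x * y) - swx * swy / sw
  syy <- sum(w * y^2) - swy^2 / sw
  if (sxx <= 1e-12 * max(1, mean(x)^2)) {
    return(list(slope = NA_real_, intercept = NA_real_, aicc = Inf,
                delta_aicc = Inf, degenerate = TRUE))
  }
  b <- sxy / sxx
  a <- (swy - b * swx) / sw
  rss <- max(syy - sxy^2 / sxx, 1e-300)
  ll <- .wls_loglik(rss, w, n)
  ac <- aicc(ll, 3L, n)
  list(slope = b, intercept = a, aicc = ac,
       delta_aicc = ac - baseline$aicc, degenerate = FALSE)
}

# Vectorized deltaAICc (+ slope) across the whole grid for response y and
# weights w. Degenerate windows (no temperature variance) get +Inf.
.grid_delta_aicc <- function(grid, y, w, with_slope = TRUE) {
  n <- length(y)
  sw <- sum(w); swy <- sum(w * y)
  syy <- sum(w * y^2) - swy^2 / sw
  swx <- drop(crossprod(grid$X, w))
  swx2 <- drop(crossprod(grid$X2, w))
  swxy <- drop(crossprod(grid$X, w * y))
  sxx <- swx2 - swx^2 / sw
  sxy <- swxy - swx * swy / sw
  ok <- sxx > 1e-12 * pmax(1, (swx / sw)^2)
  rss1 <- rep(NA_real_, length(sxx))
  rss1[ok] <- pmax(syy - sxy[ok]^2 / sxx[ok], 1e-300)
  sumlogw <- sum(log(w))
  ll0 <- 0.5 * (sumlogw - n * (log(2 * pi) + 1 - log(n) + log(max(syy, 1e-300))))
  aicc0 <- aicc(ll0, 2L, n)
  ll1 <- 0.5 * (sumlogw - n * (log(2 * pi) + 1 - log(n) + log(rss1)))
  delta <- aicc(ll1, 3L, n) - aicc0
  delta[!ok] <- Inf
  out <- list(delta = delta, baseline_aicc = aicc0)
  if (with_slope) {
    slope <- sxy / sxx
    slope[!ok] <- NA_real_
    out$slope <- slope
    out$intercept <- (swy - slope * swx) / sw
  }
  out
}

# deterministic argmin with ties broken by shorter duration, then smaller
# open (window closest to laying)
.best_index <- function(delta, specs) {
  if (all(!is.finite(delta))) return(NA_integer_)
  order(delta, specs$duration, specs$open)[1L]
}

#' Exhaustive sliding-window search
#'
#' Evaluates every window enumerated under `config` and returns the best
#' (minimum AICc) fit; ties are broken towards shorter, later windows.
#'
#' @param phenology annual phenology for one population (`year`,
#'   `mean_laying_doy`, `se_laying_doy`), one row per year.
#' @param temps daily temperature data frame covering every window day of
#'   every phenology year.
#' @param config a [window_config()].
#' @param keep_fits retain the full per-window grid (`open`, `close`,
#'   `duration`, `slope`, `delta_aicc`) in the result.
#' @param keep_grid retain the internal window-mean matrix (needed by
#'   [randomization_test()]; large for the full grid).
#' @return an object of class `window_search` with elements `best` (one-row
#'   data frame: `open`, `close`, `duration`, `midpoint_doy`, `slope`,
#'   `intercept`, `aicc`, `delta_aicc`), `baseline_aicc`, `n_years`,
#'   `all_fits` (if kept), `degenerate` (TRUE when every window lacked
#'   temperature variance), and the `config`.
#' @export
search_best_window <- function(phenology, temps, config = window_config(),
                               keep_fits = FALSE, keep_grid = FALSE) {
  stopifnot(all(c("year", "mean_laying_doy", "se_laying_doy") %in%
                  names(phenology)))
  phenology <- phenology[order(phenology$year), , drop = FALSE]
  n <- nrow(phenology)
  if (n < config$min_years) {
    stop("need at least ", config$min_years, " years of phenology; got ", n,
         call. = FALSE)
  }
  if (anyDuplicated(phenology$year)) {
    stop("duplicate phenology years", call. = FALSE)
  }
  grid <- .window_grid(temps, phenology$year, config)
  res <- .search_on_grid(grid, phenology, config, keep_fits)
  res$phenology <- phenology
  if (!keep_grid) res$grid <- NULL
  res
}

# search given a prebuilt grid (shared by the randomization test)
.search_on_grid <- function(grid, phenology, config, keep_fits = FALSE) {
  y <- phenology$mean_laying_doy
  w <- .weights_from_se(phenology$se_laying_doy, config$weight_power)
  g <- .grid_delta_aicc(grid, y, w)
  i <- .best_index(g$delta, grid$specs)
  if (is.na(i)) {
    message("no usable window: every candidate had zero temperature ",
            "variance across years")
    best <- NULL
  } else {
    sp <- grid$specs[i, ]
    best <- data.frame(
      open = sp$open, close = sp$close, duration = sp$duration,
      midpoint_doy = config$ref_doy - (sp$open + sp$close) / 2,
      slope = g$slope[i], intercept = g$intercept[i],
      aicc = g$baseline_aicc + g$delta[i], delta_aicc = g$delta[i])
  }
  out <- list(best = best, baseline_aicc = g$baseline_aicc,
              n_years = length(y), degenerate = is.na(i), config = config,
              grid = grid)
  if (keep_fits) {
    out$all_fits <- cbind(grid$specs,
                          data.frame(slope = g$slope,
                                     delta_aicc = g$delta))
  }
  class(out) <- "window_search"
  out
}

#' Randomization-based false-positive control for the window search
#'
#' Permutes the assignment of annual phenology records (laying mean and SE)
#' to years `n_rand` times, re-runs the full search on each permuted dataset,
#' and computes `P_deltaAICc = (1 + #{randomized best deltaAICc <= observed
#' best deltaAICc}) / (n_rand + 1)`. A window is accepted as a temperature
#' cue when `P_deltaAICc <= alpha` and its duration exceeds
#' `min_cue_duration` days.
#'
#' @inheritParams search_best_window
#' @param n_rand number of randomizations (default 100).
#' @param seed integer seed controlling the permutations.
#' @return a `window_search` object additionally carrying
#'   `randomized_best_deltas`, `p_delta_aicc`, and `is_cue`.
#' @export
randomization_test <- function(phenology, temps, config = window_config(),
                               n_rand = 100L, seed = 1L, keep_fits = FALSE) {
  if (n_rand < 1) stop("n_rand must be >= 1", call. = FALSE)
  obs <- search_best_window(phenology, temps, config, keep_fits = keep_fits,
                            keep_grid = TRUE)
  if (obs$degenerate) {
    obs$randomized_best_deltas <- rep(NA_real_, n_rand)
    obs$p_delta_aicc <- NA_real_
    obs$is_cue <- FALSE
    obs$grid <- NULL
    return(obs)
  }
  grid <- obs$grid
  phen <- obs$phenology
  y <- phen$mean_laying_doy
  w <- .weights_from_se(phen$se_laying_doy, config$weight_power)
  n <- length(y)
  set.seed(seed)
  rand_best <- numeric(n_rand)
  for (r in seq_len(n_rand)) {
    p <- sample.int(n)
    g <- .grid_delta_aicc(grid, y[p], w[p], with_slope = FALSE)
    rand_best[r] <- min(g$delta)
  }
  obs$randomized_best_deltas <- rand_best
  obs$p_delta_aicc <- (1 + sum(rand_best <= obs$best$delta_aicc)) /
    (n_rand + 1)
  obs$is_cue <- obs$p_delta_aicc <= config$alpha &&
    obs$best$duration > config$min_cue_duration
  obs$n_rand <- n_rand
  obs$grid <- NULL       # drop the large window-mean matrix from the result
  obs
}

#' @export
print.window_search <- function(x, ...) {
  cat("Sliding-window search (", x$n_years, " years, max span ",
      x$config$max_span, " days before doy ", x$config$ref_doy, ")\n",
      sep = "")
  if (x$degenerate) {
    cat("  no usable window (degenerate temperature series)\n")
    return(invisible(x))
  }
  b <- x$best
  cat(sprintf("  best window: open %d, close %d (duration %d d, midpoint doy %.1f)\n",
              b$open, b$close, b$duration, b$midpoint_doy))
  cat(sprintf("  slope %.3f days/C, deltaAICc %.2f\n", b$slope, b$delta_aicc))
  if (!is.null(x$p_delta_aicc)) {
    cat(sprintf("  P_deltaAICc = %.4f (%d randomizations) -> %s\n",
                x$p_delta_aicc, x$n_rand,
                if (isTRUE(x$is_cue)) "temperature cue" else "no cue"))
  }
  invisible(x)
}
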