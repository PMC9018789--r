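# Comparative stage: what drives window placement and sensitivity across
# populations.
#
# Gaussian mixed models with a site-level random intercept (both species can
# share a site), REML, treatment contrasts with deciduous / great_tit as
# reference levels. Confidence intervals by parametric bootstrap
# (simulate + refit). Collinearity screened with generalized variance
# inflation factors (determinant-ratio formula, cutoff 3). Spatial structure
# is not modelled; instead residuals are checked post hoc with a binned
# Matern-style correlogram and permutation p-values.

.prep_driver_data <- function(data) {
  data$species <- stats::relevel(factor(data$species), ref = "great_tit")
  data$habitat <- factor(data$habitat,
                         levels = c("deciduous", "mixed", "evergreen"))
  data$habitat <- droplevels(data$habitat)
  data
}

.lmm_fit_summary <- function(model, response, data) {
  vc <- lme4::VarCorr(model)
  fe <- lme4::fixef(model)
  gv <- tryCatch(generalized_vif(model), error = function(e) NULL)
  structure(list(
    response = response,
    model = model,
    fixed_effects = data.frame(term = names(fe), estimate = unname(fe),
                               ci_low = NA_real_, ci_high = NA_real_),
    random_intercept_sd = attr(vc$population_id, "stddev")[[1L]],
    residual_sd = stats::sigma(model),
    n_obs = nrow(data),
    n_groups = length(unique(data$population_id)),
    gvif = gv), class = "driver_fit")
}

#' Mixed model for a temperature-window descriptor
#'
#' Fits `response ~ latitude * species + longitude * species + habitat +
#' (1 | population_id)` by REML, where `response` is the window midpoint,
#' duration, or delay. Single-level factors are dropped with a warning.
#'
#' @param data one row per population x species, with the response column,
#'   `latitude`, `longitude`, `species`, `habitat`, `population_id`.
#' @param response name of the response column (`"midpoint_doy"`,
#'   `"duration"`, or `"delay"`).
#' @param REML fit by REML (default) or maximum likelihood.
#' @return object of class `driver_fit` (fixed-effect table, variance
#'   components, GVIFs, and the underlying `lmerMod`).
#' @export
fit_window_trait_model <- function(data, response = "midpoint_doy",
                                   REML = TRUE) {
  stopifnot(response %in% names(data))
  data <- .prep_driver_data(data)
  rhs <- "latitude * species + longitude * species + habitat"
  if (nlevels(data$habitat) < 2L) {
    warning("habitat has a single level; term dropped", call. = FALSE)
    rhs <- "latitude * species + longitude * species"
  }
  if (nlevels(droplevels(data$species)) < 2L) {
    warning("species has a single level; interactions dropped",
            call. = FALSE)
    rhs <- gsub(" \\* species", "", rhs)
  }
  form <- stats::as.formula(paste(response, "~", rhs, "+ (1 | population_id)"))
  model <- lme4::lmer(form, data = data, REML = REML)
  .lmm_fit_summary(model, response, data)
}

#' Mixed model for phenological sensitivity
#'
#' Fits `sensitivity ~ species * (habitat + precipitation_pc) +
#' (1 | population_id)` by REML: habitat and annual-precipitation score as
#' drivers, each interacted with species, site as random intercept.
#'
#' @param data one row per population x species with `sensitivity`,
#'   `habitat`, `precipitation_pc`, `species`, `population_id`.
#' @param REML fit by REML (default) or maximum likelihood.
#' @return a `driver_fit`.
#' @export
fit_sensitivity_model <- function(data, REML = TRUE) {
  stopifnot("sensitivity" %in% names(data))
  data <- .prep_driver_data(data)
  rhs <- "species * (habitat + precipitation_pc)"
  if (nlevels(data$habitat) < 2L) {
    warning("habitat has a single level; term dropped", call. = FALSE)
    rhs <- "species * precipitation_pc"
  }
  if (nlevels(droplevels(data$species)) < 2L) {
    warning("species has a single level; interactions dropped",
            call. = FALSE)
    rhs <- gsub("species \\* \\(?", "", rhs)
    rhs <- gsub("\\)$", "", rhs)
  }
  form <- stats::as.formula(paste("sensitivity ~", rhs,
                                  "+ (1 | population_id)"))
  model <- lme4::lmer(form, data = data, REML = REML)
  .lmm_fit_summary(model, "sensitivity", data)
}

#' Parametric-bootstrap confidence intervals for a mixed-model fit
#'
#' Simulates responses from the fitted model (fixed effects + normal random
#' intercepts + normal residuals), refits, and takes percentile 2.5/97.5
#' bounds per fixed effect.
#'
#' @param fit a `driver_fit` from [fit_window_trait_model()] or
#'   [fit_sensitivity_model()].
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return the `driver_fit` with `ci_low`/`ci_high` filled in, plus
#'   `boot_estimates` (iterations x effects matrix) and `n_boot_failed`.
#' @export
parametric_bootstrap_ci <- function(fit, n_boot = 1000L, seed = 1L,
                                    conf = 0.95) {
  stopifnot(inherits(fit, "driver_fit"))
  model <- fit$model
  set.seed(seed)
  sims <- stats::simulate(model, nsim = n_boot)
  k <- nrow(fit$fixed_effects)
  est <- matrix(NA_real_, n_boot, k,
                dimnames = list(NULL, fit$fixed_effects$term))
  failed <- 0L
  for (b in seq_len(n_boot)) {
    fe <- tryCatch(
      lme4::fixef(suppressMessages(suppressWarnings(
        lme4::refit(model, newresp = sims[[b]])))),
      error = function(e) NULL)
    if (is.null(fe) || length(fe) != k) {
      failed <- failed + 1L
    } else {
      est[b, ] <- fe
    }
  }
  if (failed > 0.1 * n_boot) {
    warning("unstable bootstrap: ", failed, "/", n_boot,
            " refits failed to converge", call. = FALSE)
  }
  a <- (1 - conf) / 2
  qs <- apply(est, 2L, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  fit$fixed_effects$ci_low <- pmin(qs[1L, ], fit$fixed_effects$estimate)
  fit$fixed_effects$ci_high <- pmax(qs[2L, ], fit$fixed_effects$estimate)
  fit$boot_estimates <- est
  fit$n_boot_failed <- failed
  fit$n_boot <- as.integer(n_boot)
  fit
}

#' Generalized variance inflation factors
#'
#' Per-term GVIF by the determinant-ratio formula on the correlation matrix
#' of the fixed-effects design columns (intercept excluded), grouping the
#' columns of multi-level factor terms. For a single-column term this is the
#' ordinary VIF, `1/(1 - R^2)`. Values above `cutoff` are flagged in the
#' `flagged` attribute.
#'
#' @param model an `lm` or `merMod` fit, or a design matrix with an
#'   `assign` attribute.
#' @param cutoff collinearity flag threshold (default 3, applied to
#'   `GVIF^(1/(2 df))` for multi-column terms and to GVIF otherwise).
#' @return named numeric vector of GVIFs with a logical `flagged` attribute.
#' @export
generalized_vif <- function(model, cutoff = 3) {
  if (is.matrix(model)) {
    mm <- model
    assign <- attr(mm, "assign")
    labels <- attr(mm, "term.labels")
    if (is.null(labels)) labels <- as.character(sort(unique(assign[assign > 0])))
  } else if (inherits(model, "merMod")) {
    mm <- lme4::getME(model, "X")
    assign <- attr(mm, "assign")
    labels <- attr(stats::terms(model), "term.labels")
  } else {
    mm <- stats::model.matrix(model)
    assign <- attr(mm, "assign")
    labels <- attr(stats::terms(model), "term.labels")
  }
  keep <- assign > 0L
  mm <- mm[, keep, drop = FALSE]
  assign <- assign[keep]
  terms_present <- sort(unique(assign))
  if (length(terms_present) < 2L) {
    out <- rep(1, length(terms_present))
    names(out) <- labels[terms_present]
    attr(out, "flagged") <- out > cutoff
    return(out)
  }
  R <- stats::cor(mm)
  detR <- det(R)
  if (detR < 1e-12) {
    stop("singular fixed-effects design: aliased term(s) among ",
         paste(labels[terms_present], collapse = ", "), call. = FALSE)
  }
  gvif <- numeric(length(terms_present))
  df <- integer(length(terms_present))
  for (i in seq_along(terms_present)) {
    cols <- which(assign == terms_present[i])
    df[i] <- length(cols)
    gvif[i] <- det(R[cols, cols, drop = FALSE]) *
      det(R[-cols, -cols, drop = FALSE]) / detR
  }
  names(gvif) <- labels[terms_present]
  attr(gvif, "flagged") <- gvif^(1 / (2 * df)) > cutoff^(1 / 2)
  gvif
}

#' Matern correlation kernel
#'
#' `C(d) = 2^(1-nu)/Gamma(nu) * (sqrt(2 nu) d / rho)^nu *
#' K_nu(sqrt(2 nu) d / rho)`, with `C(0) = 1`. For `nu = 0.5` this is
#' `exp(-d/rho)`; for `nu = 1.5` it is `(1 + sqrt(3) d/rho)
#' exp(-sqrt(3) d/rho)`.
#'
#' @param d distances (>= 0), vectorized.
#' @param nu smoothness (> 0; default 0.5, the exponential kernel).
#' @param range_parameter length scale rho (> 0), same units as `d`.
#' @return correlations in `[0, 1]`.
#' @export
matern_correlation <- function(d, nu = 0.5, range_parameter = 1) {
  if (!is.numeric(nu) || length(nu) != 1L || nu <= 0) {
    stop("nu must be a positive scalar", call. = FALSE)
  }
  if (!is.numeric(range_parameter) || length(range_parameter) != 1L ||
      range_parameter <= 0) {
    stop("range_parameter must be a positive scalar", call. = FALSE)
  }
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  x <- sqrt(2 * nu) * d / range_parameter
  out <- numeric(length(d))
  zero <- x < 1e-12
  out[zero] <- 1
  xs <- x[!zero]
  out[!zero] <- 2^(1 - nu) / gamma(nu) * xs^nu * besselK(xs, nu)
  # besselK underflows for very large arguments; the limit is 0
  out[!is.finite(out) | out < 0] <- 0
  out <- pmin(out, 1)
  dim(out) <- dim(d)
  dimnames(out) <- dimnames(d)
  out
}

#' Binned spatial correlogram of model residuals with permutation test
#'
#' Bins pairwise products of standardized residuals by Euclidean distance in
#' degrees and reports the mean standardized cross-product per bin (a
#' Moran-type correlation estimate) with a one-sided permutation p-value for
#' positive spatial correlation (residuals shuffled over locations,
#' add-one rule).
#'
#' @param residuals per-population residuals (one per location).
#' @param coordinates data frame or matrix with columns
#'   `longitude`, `latitude` (degrees).
#' @param breaks distance-bin breakpoints in degrees (default `0:10`).
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @param nu Matern smoothness recorded with the diagnostic (default 0.5).
#' @return object of class `matern_diagnostic`: data frame `bins`
#'   (`dist_low`, `dist_high`, `n_pairs`, `mean_correlation`, `p_value`;
#'   empty bins reported with `NA`), plus `n_perm` and `nu`.
#' @export
spatial_autocorrelation_diagnostic <- function(residuals, coordinates,
                                               breaks = 0:10, n_perm = 999L,
                                               seed = 1L, nu = 0.5) {
  n <- length(residuals)
  if (n < 10L) {
    stop("need at least 10 populations with coordinates", call. = FALSE)
  }
  coordinates <- as.data.frame(coordinates)
  stopifnot(all(c("longitude", "latitude") %in% names(coordinates)),
            nrow(coordinates) == n)
  z <- as.numeric(scale(residuals))
  D <- as.matrix(stats::dist(coordinates[, c("longitude", "latitude")]))
  iu <- which(upper.tri(D))
  dists <- D[iu]
  bin <- cut(dists, breaks = breaks, include.lowest = TRUE, right = FALSE)
  pair_i <- row(D)[iu]
  pair_j <- col(D)[iu]

  bin_mean <- function(zz) {
    prods <- zz[pair_i] * zz[pair_j]
    tapply(prods, bin, mean)
  }
  obs <- bin_mean(z)
  set.seed(seed)
  exceed <- rep(0L, nlevels(bin))
  for (p in seq_len(n_perm)) {
    pm <- bin_mean(z[sample.int(n)])
    exceed <- exceed + as.integer(!is.na(pm) & !is.na(obs) & pm >= obs)
  }
  pval <- (1 + exceed) / (n_perm + 1)
  pval[is.na(obs)] <- NA_real_
  counts <- as.integer(table(bin))
  structure(list(
    bins = data.frame(dist_low = breaks[-length(breaks)],
                      dist_high = breaks[-1L],
                      n_pairs = counts,
                      mean_correlation = as.numeric(obs),
                      p_value = pval),
    n_perm = as.integer(n_perm), nu = nu), class = "matern_diagnostic")
}

#' @export
print.driver_fit <- function(x, ...) {
  cat("Mixed-model driver fit: response =", x$response, "\n")
  cat(sprintf("  %d obs, %d sites; random-intercept SD %.3f, residual SD %.3f\n",
              x$n_obs, x$n_groups, x$random_intercept_sd, x$residual_sd))
  fe <- x$fixed_effects
  for (i in seq_len(nrow(fe))) {
    cat(sprintf("  %-35s %8.3f", fe$term[i], fe$estimate[i]))
    if (!is.na(fe$ci_low[i])) {
      cat(sprintf("  [%7.3f, %7.3f]", fe$ci_low[i], fe$ci_high[i]))
    }
    cat("\n")
  }
  invisible(x)
}
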