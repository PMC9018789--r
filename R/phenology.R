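# Phenology reduction: clutch records -> annual population phenology.
#
# Laying dates are back-calculated from the first observation of an active
# nest assuming one egg laid per day; first clutches are those laid within
# 30 days (inclusive) of the year's earliest clutch; a population-year is
# summarized by the mean laying day-of-year of first clutches with its
# standard error.

#' Back-calculate laying date from an egg count
#'
#' If a nest is first seen with `eggs` eggs on day `observation_doy`, the
#' first egg was laid `eggs - 1` days earlier (one egg per day).
#'
#' @param observation_doy day-of-year of the first observation with eggs.
#' @param eggs number of eggs at that observation (>= 1). Vectorized.
#' @return day-of-year on which the first egg was laid.
#' @export
back_calculate_laying <- function(observation_doy, eggs) {
  if (any(!is.finite(eggs)) || any(eggs < 1) || any(eggs != round(eggs))) {
    stop("invalid record: eggs_at_observation must be a whole number >= 1",
         call. = FALSE)
  }
  observation_doy - (eggs - 1)
}

#' Restrict a year's clutches to first clutches
#'
#' Keeps clutches laid within `within_days` days of the earliest clutch of the
#' year (inclusive: `laying <= earliest + within_days`), dropping presumed
#' second and replacement clutches. Input order is preserved.
#'
#' @param laying_doys laying days-of-year for one population-year.
#' @param within_days window after the earliest clutch (default 30 days).
#' @return the retained laying days-of-year.
#' @export
first_clutch_filter <- function(laying_doys, within_days = 30) {
  if (length(laying_doys) == 0L) {
    stop("empty year: no clutches to filter", call. = FALSE)
  }
  laying_doys[laying_doys <= min(laying_doys) + within_days]
}

#' Reduce one population-year to mean laying date and SE
#'
#' @param laying_doys first-clutch laying days-of-year (already filtered).
#' @return a one-row data frame: `mean_laying_doy`, `se_laying_doy`
#'   (sample SD / sqrt(n); `NA` when n = 1), `n_clutches`.
#' @export
reduce_annual <- function(laying_doys) {
  if (length(laying_doys) == 0L) {
    stop("empty year: no clutches to reduce", call. = FALSE)
  }
  n <- length(laying_doys)
  se <- if (n > 1L) stats::sd(laying_doys) / sqrt(n) else NA_real_
  data.frame(mean_laying_doy = mean(laying_doys),
             se_laying_doy = se,
             n_clutches = n)
}

#' Build the annual phenology table from clutch records
#'
#' Applies, per (population, species, year): laying-date back-calculation
#' where `laying_doy` is absent, the first-clutch filter, and the annual
#' reduction.  Years whose SE is undefined (single clutch) or zero get a
#' floor: by default the median of that population's positive annual SEs,
#' falling back to 1 day, so that inverse-SE weights stay defined.
#'
#' @param clutches data frame with columns `population_id`, `species`,
#'   `year`, and either `laying_doy` or both `observation_doy` and
#'   `eggs_at_observation`.
#' @param within_days first-clutch window (default 30 days).
#' @param se_floor fixed SE floor in days, or `NULL` (default) for the
#'   per-population median rule.
#' @return data frame with one row per population-species-year:
#'   `population_id`, `species`, `year`, `mean_laying_doy`, `se_laying_doy`,
#'   `n_clutches`.
#' @export
annual_phenology <- function(clutches, within_days = 30, se_floor = NULL) {
  stopifnot(is.data.frame(clutches))
  need <- c("population_id", "species", "year")
  miss <- setdiff(need, names(clutches))
  if (length(miss)) {
    stop("clutch table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(clutches$laying_doy)) {
    if (is.null(clutches$observation_doy) ||
        is.null(clutches$eggs_at_observation)) {
      stop("need laying_doy or observation_doy + eggs_at_observation",
           call. = FALSE)
    }
    clutches$laying_doy <- back_calculate_laying(clutches$observation_doy,
                                                 clutches$eggs_at_observation)
  }
  key <- interaction(clutches$population_id, clutches$species, clutches$year,
                     drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(clutches, key), function(g) {
    kept <- first_clutch_filter(g$laying_doy, within_days = within_days)
    cbind(g[1L, c("population_id", "species", "year")],
          reduce_annual(kept))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$population_id, out$species, out$year), ]

  # SE floor per population x species
  pkey <- interaction(out$population_id, out$species, drop = TRUE)
  n_floored <- 0L
  for (k in levels(pkey)) {
    i <- pkey == k
    se <- out$se_laying_doy[i]
    bad <- is.na(se) | se <= 0
    if (any(bad)) {
      floor_val <- if (!is.null(se_floor)) {
        se_floor
      } else if (any(!bad)) {
        stats::median(se[!bad])
      } else {
        1.0
      }
      se[bad] <- floor_val
      out$se_laying_doy[i] <- se
      n_floored <- n_floored + sum(bad)
    }
  }
  if (n_floored > 0L) {
    warning(n_floored, " population-year(s) had undefined or zero SE; ",
            "floored for inverse-SE weighting", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}
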