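# Calendar conventions.
#
# All window geometry runs on a fixed 365-day calendar: Feb 29 is dropped from
# every daily series so that "d days before the reference date" addresses the
# same calendar day in every year, and day-of-year arithmetic is year-invariant.
# The reference date defaults to June 1 (day-of-year 152 on a non-leap year).

#' Default reference day-of-year (June 1, non-leap calendar)
#' @keywords internal
.ref_doy_default <- 152L

# cumulative days before each month on a non-leap calendar
.cum_month_days <- c(0L, 31L, 59L, 90L, 120L, 151L, 181L, 212L, 243L,
                     273L, 304L, 334L)

#' Day of year on the 365-day (non-leap) calendar
#'
#' Maps calendar dates to day-of-year with Feb 29 disallowed, so that e.g.
#' March 1 is day 60 in every year.
#'
#' @param dates a `Date` vector (no Feb 29 entries).
#' @return integer day-of-year in 1..365.
#' @export
doy_nonleap <- function(dates) {
  dates <- as.Date(dates)
  lt <- as.POSIXlt(dates)
  mon <- lt$mon + 1L
  mday <- lt$mday
  if (any(mon == 2L & mday == 29L, na.rm = TRUE)) {
    stop("doy_nonleap(): Feb 29 present; strip leap days first ",
         "(see strip_leap_days())", call. = FALSE)
  }
  .cum_month_days[mon] + mday
}

#' Drop Feb 29 rows from a dated table
#'
#' @param x a data frame with a `date` column of class `Date`.
#' @param quiet suppress the message reporting how many rows were dropped.
#' @return `x` without Feb 29 rows.
#' @export
strip_leap_days <- function(x, quiet = FALSE) {
  lt <- as.POSIXlt(x$date)
  leap <- lt$mon == 1L & lt$mday == 29L
  if (any(leap) && !quiet) {
    message("Dropped ", sum(leap), " Feb 29 row(s) (365-day calendar)")
  }
  x[!leap, , drop = FALSE]
}

#' Validate a candidate window
#'
#' A window is parameterized by its `open` and `close` boundaries in whole
#' days before the reference date, inclusive on both ends, with
#' `365 >= open >= close >= 1` and duration `open - close + 1`.
#'
#' @param open,close integer days before the reference date.
#' @keywords internal
check_window_spec <- function(open, close) {
  if (length(open) != 1L || length(close) != 1L ||
      !is.finite(open) || !is.finite(close)) {
    stop("window spec must be two finite scalars", call. = FALSE)
  }
  if (open != round(open) || close != round(close)) {
    stop("window boundaries must be whole days", call. = FALSE)
  }
  if (!(365 >= open && open >= close && close >= 1)) {
    stop("invalid window: need 365 >= open >= close >= 1, got open=", open,
         ", close=", close, call. = FALSE)
  }
  invisible(TRUE)
}

#' Calendar days covered by a window in a given year
#'
#' Returns the inclusive run of calendar days `[reference - open,
#' reference - close]` for one focal year, in chronological order.  Windows
#' with `open >= reference doy` extend into the previous calendar year.
#'
#' @param open,close window boundaries in days before the reference date.
#' @param year focal calendar year.
#' @param ref_doy reference day-of-year (default 152 = June 1, non-leap).
#' @return a data frame with columns `year` and `doy` (non-leap day-of-year),
#'   one row per day, `open - close + 1` rows.
#' @export
window_days <- function(open, close, year, ref_doy = .ref_doy_default) {
  check_window_spec(open, close)
  d <- seq.int(open, close)              # open >= close: chronological
  raw <- ref_doy - d
  prev <- raw < 1L
  data.frame(year = as.integer(year) - as.integer(prev),
             doy  = as.integer(raw + 365L * prev))
}

#' Window descriptors: midpoint, duration, delay
#'
#' The midpoint is the day-of-year at the centre of the window
#' (`ref_doy - (open + close)/2`); the delay is the gap between the
#' population's long-term mean laying date and the window midpoint,
#' i.e. how long after the cue the response is expressed.
#'
#' @inheritParams window_days
#' @param mean_laying_doy overall mean laying day-of-year of the population.
#' @return a one-row data frame with `midpoint_doy`, `duration`, `delay`.
#' @export
window_descriptors <- function(open, close, mean_laying_doy,
                               ref_doy = .ref_doy_default) {
  check_window_spec(open, close)
  midpoint <- ref_doy - (open + close) / 2
  data.frame(midpoint_doy = midpoint,
             duration = open - close + 1,
             delay = mean_laying_doy - midpoint)
}
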