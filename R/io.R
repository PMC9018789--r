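# CSV readers/writers for the three standard input tables and the derived
# annual phenology table. Plain headered CSV, ISO 8601 dates. Unknown columns
# are preserved.

.check_columns <- function(df, required, path, any_of = NULL) {
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("'", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!is.null(any_of) && !any(any_of %in% names(df))) {
    stop("'", path, "' needs one of: ", paste(any_of, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

.parse_iso_dates <- function(x, path, column) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & nzchar(x))
  if (length(bad)) {
    stop("'", path, "', column '", column, "': unparseable date at data row",
         if (length(bad) > 1L) "s " else " ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) ", ..." else "", call. = FALSE)
  }
  d
}

#' Read a clutch-record table
#'
#' Expects `population_id`, `species`, `year`, `nest_id`,
#' `eggs_at_observation`, and either `observation_date` or `laying_date`
#' (ISO 8601); dates are converted to non-leap day-of-year columns
#' (`observation_doy` / `laying_doy`). Already-numeric `observation_doy` /
#' `laying_doy` columns are accepted as-is.
#'
#' @param path CSV file path.
#' @return data frame of clutch records.
#' @export
read_phenology_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("population_id", "species", "year"), path,
                 any_of = c("observation_date", "laying_date",
                            "observation_doy", "laying_doy"))
  if ("observation_date" %in% names(df) && is.null(df$observation_doy)) {
    df$observation_doy <- doy_nonleap(
      .parse_iso_dates(df$observation_date, path, "observation_date"))
  }
  if ("laying_date" %in% names(df) && is.null(df$laying_doy)) {
    df$laying_doy <- doy_nonleap(
      .parse_iso_dates(df$laying_date, path, "laying_date"))
  }
  df
}

#' Read a daily mean-temperature table
#'
#' Expects `population_id`, `date` (ISO 8601), `tmean_c`. Feb 29 rows are
#' dropped (365-day calendar) with a message reporting the count.
#'
#' @param path CSV file path.
#' @param quiet suppress the Feb 29 message.
#' @return data frame with `population_id`, `date` (Date), `tmean_c`.
#' @export
read_temperature_csv <- function(path, quiet = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("population_id", "date", "tmean_c"), path)
  df$date <- .parse_iso_dates(df$date, path, "date")
  strip_leap_days(df, quiet = quiet)
}

#' Read a population metadata table
#'
#' Expects `population_id`, `species`, `latitude`, `longitude`, `habitat`
#' (one of deciduous / evergreen / mixed), `precipitation_pc`.
#'
#' @param path CSV file path.
#' @return data frame of population metadata.
#' @export
read_populations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("population_id", "species", "latitude", "longitude",
                       "habitat", "precipitation_pc"), path)
  if (any(abs(df$latitude) > 90, na.rm = TRUE)) {
    stop("'", path, "': latitude outside [-90, 90]", call. = FALSE)
  }
  if (any(abs(df$longitude) > 180, na.rm = TRUE)) {
    stop("'", path, "': longitude outside [-180, 180]", call. = FALSE)
  }
  bad_hab <- setdiff(unique(df$habitat), c("deciduous", "evergreen", "mixed"))
  if (length(bad_hab)) {
    stop("'", path, "': unknown habitat level(s): ",
         paste(bad_hab, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read an annual phenology table
#'
#' @param path CSV file path with `population_id`, `species`, `year`,
#'   `mean_laying_doy`, `se_laying_doy`, `n_clutches`.
#' @return data frame of annual phenology.
#' @export
read_annual_phenology_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("population_id", "species", "year", "mean_laying_doy",
                       "se_laying_doy", "n_clutches"), path)
  df
}

#' Write a table to CSV with full numeric precision
#'
#' Values round-trip through [utils::read.csv()] to at least 1e-9; `Date`
#' columns are written as ISO 8601.
#'
#' @param df data frame to write.
#' @param path destination CSV path.
#' @export
write_csv_table <- function(df, path) {
  for (j in seq_along(df)) {
    if (inherits(df[[j]], "Date")) df[[j]] <- format(df[[j]], "%Y-%m-%d")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
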