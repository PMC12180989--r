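#' Linearly scale record weights in 2-year increments
#'
#' Incremental-learning scheme for secular drift: records are upweighted
#' linearly with recency in fixed-width calendar bins. With the default
#' 2-year bins and an origin at the technique's first year of use, records
#' in the first bin keep weight x1, the next bin is doubled (x2), and so on
#' through the latest year, so the effective database emphasises current
#' practice while retaining all history.
#'
#' @param cohort An engineered cohort tibble.
#' @param bin_years Bin width in calendar years (default 2).
#' @param origin_year First year of the scheme (multiplier 1); defaults to
#'   the earliest record year in the cohort. Records predating an explicit
#'   origin are an error.
#' @param max_multiplier Optional cap on the bin multiplier.
#' @return The cohort with `replication_weight` multiplied by the 1-based
#'   bin index. All distance statistics treat weight `w` as `w` identical
#'   copies, so this equals materially duplicating recent records.
#' @export
linear_scale <- function(cohort, bin_years = 2, origin_year = NULL,
                         max_multiplier = NULL) {
  stopifnot(bin_years >= 1)
  year <- as.integer(format(cohort$start_date, "%Y"))
  if (is.null(origin_year)) {
    origin_year <- min(year)
  } else if (any(year < origin_year)) {
    abort("records predate origin_year; omit origin_year to derive it from the data")
  }
  bin <- (year - origin_year) %/% bin_years + 1L
  if (!is.null(max_multiplier)) bin <- pmin(bin, as.integer(max_multiplier))
  cohort$replication_weight <- cohort$replication_weight * bin
  cohort
}

#' Keep only the most recent window of records
#'
#' Sliding-window retraining alternative: keeps records whose calendar year
#' lies in `(as_of_year - window_years, as_of_year]` and retires everything
#' older.
#'
#' @param cohort A cohort tibble.
#' @param window_years Window width in years.
#' @param as_of_year Reference year (default: latest year in the cohort).
#' @return The cohort subset (possibly empty, with a warning).
#' @export
sliding_window <- function(cohort, window_years, as_of_year = NULL) {
  stopifnot(window_years >= 1)
  year <- as.integer(format(cohort$start_date, "%Y"))
  if (is.null(as_of_year)) as_of_year <- max(year)
  keep <- year > as_of_year - window_years & year <= as_of_year
  if (!any(keep)) warn("sliding window retains no records")
  cohort[keep, , drop = FALSE]
}

#' Secular usage trends of techniques and regimens
#'
#' Tidy per-year counts of technique use and of exact prescription use,
#' the raw material of secular-trend plots (3D conformal declining, IMRT
#' and stereotactic treatments rising, regimens appearing and retiring).
#'
#' @param cohort A cohort tibble.
#' @return A list of two tibbles: `technique` (`year, technique, n`) and
#'   `regimen` (`year, dose_per_fraction_cgy, n_fractions, n`). Counts in
#'   each conserve the total record count.
#' @export
usage_trends <- function(cohort) {
  year <- as.integer(format(cohort$start_date, "%Y"))
  tech <- cohort %>%
    mutate(year = year) %>%
    count(.data$year, .data$technique, name = "n") %>%
    arrange(.data$year, .data$technique)
  regimen <- cohort %>%
    mutate(year = year) %>%
    count(.data$year, .data$dose_per_fraction_cgy, .data$n_fractions,
          name = "n") %>%
    arrange(.data$year)
  list(technique = as_tibble(tech), regimen = as_tibble(regimen))
}
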