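#' Read a cohort of treatment records from CSV
#'
#' Ingests a historical database export: one row per prescription (Rx) with
#' the nine clinical features used by the detector plus a record identifier
#' and treatment start date. Unparseable *optional* fields (intent, Rx
#' isodose line, age) become `NA` and are resolved later by
#' [impute_most_often()]; unparseable *required* fields (dose per fraction,
#' number of fractions) raise a row-level error.
#'
#' Doses are in cGy throughout. Rows whose dose per fraction is below 10 cGy
#' look like Gy-scale input and are kept but flagged with a warning rather
#' than silently rescaled.
#'
#' @param path Path to a CSV file with header columns
#'   `record_id, site, technique, dose_per_fraction_cgy, n_fractions, energy,
#'   rx_isodose_line_pct, intent, diagnostic_code, age_years, age_group,
#'   start_date, replication_weight`. Missing optional values are empty
#'   strings; `start_date` is ISO-8601.
#' @param site Treatment site the cohort belongs to: `"brain"`, `"thoracic"`
#'   or `"other"`. Rows carrying a different site are rejected.
#' @return A tibble with one row per record (a *cohort*), columns as above
#'   with parsed types. Absent `record_id`s are generated deterministically
#'   from the row index.
#' @seealso [write_cohort_csv()], [partition_by_technique()]
#' @export
read_cohort_csv <- function(path, site = c("brain", "thoracic", "other")) {
  site <- arg_match(site)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  required <- setdiff(.cohort_cols, c("record_id", "age_group", "replication_weight"))
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort CSV is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(raw)
  blank <- function(x) is.na(x) | trimws(x) == ""
  num <- function(x) suppressWarnings(as.numeric(x))

  dose <- num(raw$dose_per_fraction_cgy)
  frac <- num(raw$n_fractions)
  bad <- which(blank(raw$dose_per_fraction_cgy) | is.na(dose) |
                 blank(raw$n_fractions) | is.na(frac))
  if (length(bad) > 0) {
    abort(paste0("non-numeric dose_per_fraction_cgy/n_fractions in row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (any(dose <= 0) || any(frac < 1)) {
    abort("dose_per_fraction_cgy must be > 0 and n_fractions >= 1")
  }
  if (any(dose < 10)) {
    warn(paste0(sum(dose < 10), " record(s) have dose_per_fraction_cgy < 10; ",
                "values look Gy-scale, expected cGy"))
  }

  id <- if ("record_id" %in% names(raw)) raw$record_id else rep(NA_character_, n)
  id[blank(id)] <- sprintf("R%05d", which(blank(id)))

  row_site <- tolower(trimws(raw$site))
  if (any(!blank(raw$site) & row_site != site)) {
    abort(paste0("cohort contains rows whose site differs from '", site, "'"))
  }

  tech <- canonical_technique(raw$technique)
  if (anyNA(tech)) {
    abort(paste0("unrecognised technique in row(s): ",
                 paste(head(which(is.na(tech)), 5), collapse = ", ")))
  }

  isodose <- num(raw$rx_isodose_line_pct)
  isodose[blank(raw$rx_isodose_line_pct)] <- NA_real_
  if (any(!is.na(isodose) & (isodose <= 0 | isodose > 100))) {
    abort("rx_isodose_line_pct must lie in (0, 100]")
  }
  intent <- tolower(trimws(raw$intent))
  intent[blank(raw$intent)] <- NA_character_
  if (any(!is.na(intent) & !intent %in% c("curative", "palliative"))) {
    abort("intent must be 'curative' or 'palliative' (or empty)")
  }
  age <- num(raw$age_years)
  age[blank(raw$age_years)] <- NA_real_
  if (any(!is.na(age) & age < 0)) abort("age_years must be non-negative")
  age_group <- if ("age_group" %in% names(raw)) tolower(trimws(raw$age_group)) else rep("", n)
  age_group[blank(age_group)] <- NA_character_
  if (any(!is.na(age_group) & !age_group %in% c("pediatric", "adult"))) {
    abort("age_group must be 'pediatric' or 'adult' (or empty)")
  }
  if (any(is.na(age) & is.na(age_group))) {
    abort("each record needs age_years or age_group")
  }
  date <- as.Date(raw$start_date, format = "%Y-%m-%d")
  if (anyNA(date)) abort("start_date must be ISO-8601 (YYYY-MM-DD)")
  yr <- as.integer(format(date, "%Y"))
  if (any(yr < 1995 | yr > 2021)) {
    warn("start_date outside 1995-2021; accepted, but check the export")
  }
  wt <- if ("replication_weight" %in% names(raw)) num(raw$replication_weight) else rep(1, n)
  wt[is.na(wt)] <- 1
  if (any(wt < 1 | wt != round_half_up(wt))) {
    abort("replication_weight must be a positive integer")
  }
  code <- trimws(raw$diagnostic_code)
  bad_code <- !grepl("^[A-Z][0-9]{2}(\\.[A-Za-z0-9]{1,2})?$", code)
  if (any(bad_code)) {
    abort(paste0("invalid ICD-10 diagnostic_code in row(s): ",
                 paste(head(which(bad_code), 5), collapse = ", ")))
  }

  tibble(
    record_id = id, site = site, technique = tech,
    dose_per_fraction_cgy = dose, n_fractions = as.integer(frac),
    energy = tolower(trimws(raw$energy)), rx_isodose_line_pct = isodose,
    intent = intent, diagnostic_code = code, age_years = age,
    age_group = age_group, start_date = date,
    replication_weight = as.integer(wt)
  )
}

# SBRT / SRT / SRS are one stereotactic family in this model.
canonical_technique <- function(x) {
  x <- toupper(trimws(x))
  x[x %in% c("SBRT", "SRT", "SRS", "SBRT/SRT", "SBRT_SRT")] <- "SBRT_SRT"
  x[x %in% c("3D", "3DRT", "3DCRT")] <- "3D"
  x[!x %in% .techniques] <- NA_character_
  x
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort_csv()]: dates are written ISO-8601, doses as plain
#' decimals, missing optional values as empty strings, so that a read/write
#' round trip reproduces the cohort field for field.
#'
#' @param cohort A cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort[intersect(.cohort_cols, names(cohort))]
  out$start_date <- format(out$start_date, "%Y-%m-%d")
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Split a cohort into per-technique historical databases
#'
#' The detector is calibrated separately for each treatment technique (IMRT,
#' 3D conformal, and the pooled stereotactic SBRT/SRT family), so the site
#' cohort is partitioned on the `technique` column. Partitions are disjoint
#' and exhaustive and inherit all engineered columns.
#'
#' @param cohort A cohort tibble.
#' @return A named list of cohort tibbles, one per technique present.
#' @export
partition_by_technique <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  split(as_tibble(cohort), cohort$technique)
}

#' Summarise record counts and missingness of a cohort
#'
#' @param cohort A cohort tibble.
#' @return A one-row tibble with record counts (raw and replication-weighted)
#'   and per-field missingness for the imputable features.
#' @export
cohort_summary <- function(cohort) {
  tibble(
    site = cohort$site[1] %||% NA_character_,
    n_records = nrow(cohort),
    n_effective = sum(cohort$replication_weight),
    n_missing_intent = sum(is.na(cohort$intent)),
    n_missing_isodose = sum(is.na(cohort$rx_isodose_line_pct)),
    n_missing_age = sum(is.na(cohort$age_years) & is.na(cohort$age_group)),
    year_min = min(as.integer(format(cohort$start_date, "%Y"))),
    year_max = max(as.integer(format(cohort$start_date, "%Y")))
  )
}
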