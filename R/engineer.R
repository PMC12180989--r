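#' Feature-engineering configuration
#'
#' Bundles the tunable rules that turn a raw record export into a model-ready
#' historical database. Defaults follow standard clinical conventions:
#' pediatric means age under 18 years, site membership is decided by ICD-10
#' prefix (brain: C71, C79.3; thoracic: C34, C15, C22.8), QA/test rows are
#' recognised by marker tokens in the record id, diagnostic code or intent,
#' and rarely used reduced-field regimens can be upweighted so they are not
#' flagged excessively.
#'
#' @param site_icd_prefixes Named list mapping site to ICD-10 prefixes.
#' @param pediatric_age_cutoff Age in years; `age < cutoff` is pediatric,
#'   `age >= cutoff` adult (half-open interval, so exactly 18 is adult).
#' @param qa_markers Character tokens identifying QA/physics test rows.
#' @param rare_rx_upweight List of `list(dose, fractions, factor)` rules; a
#'   matching record's replication weight is multiplied by `factor`
#'   (integer `>= 1`). All distance statistics treat a record of weight `w`
#'   as `w` identical copies.
#' @param rx_exclusions List of `list(dose, fractions)` regimens to drop,
#'   standing in for physician-reviewed elimination of rare prescriptions.
#' @return An `engineering_config` list.
#' @export
engineering_config <- function(site_icd_prefixes = list(
                                 brain = c("C71", "C79.3"),
                                 thoracic = c("C34", "C15", "C22.8")
                               ),
                               pediatric_age_cutoff = 18,
                               qa_markers = c("QA", "TEST", "PHANTOM", "ZZ"),
                               rare_rx_upweight = list(),
                               rx_exclusions = list()) {
  stopifnot(pediatric_age_cutoff > 0)
  for (rule in rare_rx_upweight) {
    if (is.null(rule$factor) || rule$factor < 1 || rule$factor != round_half_up(rule$factor)) {
      abort("rare_rx_upweight factors must be integers >= 1")
    }
  }
  structure(
    list(
      site_icd_prefixes = site_icd_prefixes,
      pediatric_age_cutoff = pediatric_age_cutoff,
      qa_markers = toupper(qa_markers),
      rare_rx_upweight = rare_rx_upweight,
      rx_exclusions = rx_exclusions
    ),
    class = "engineering_config"
  )
}

#' Remove quality-assurance and physics-test records
#'
#' Treatment record systems accumulate QA/phantom/test rows that must never
#' enter the historical database. A record is dropped when any QA marker
#' token occurs (case-insensitively) in its record id, diagnostic code or
#' intent field. Order of the surviving rows is preserved.
#'
#' @param cohort A cohort tibble.
#' @param config An [engineering_config()].
#' @return The cohort without QA rows.
#' @export
remove_qa_records <- function(cohort, config = engineering_config()) {
  fields <- toupper(paste(cohort$record_id, cohort$diagnostic_code,
                          ifelse(is.na(cohort$intent), "", cohort$intent)))
  hit <- rep(FALSE, nrow(cohort))
  for (marker in config$qa_markers) hit <- hit | grepl(marker, fields, fixed = TRUE)
  cohort[!hit, , drop = FALSE]
}

#' Select site-specific records by ICD-10 prefix
#'
#' Diagnostic codes are the handle for extracting site-specific records from
#' a mixed export: a record survives when its ICD-10 code starts with one of
#' the prefixes registered for the site (e.g. C71/C79.3 for brain).
#'
#' @inheritParams remove_qa_records
#' @param site Site whose prefix list applies.
#' @return The site-restricted cohort.
#' @export
select_site_by_icd <- function(cohort, site, config = engineering_config()) {
  prefixes <- config$site_icd_prefixes[[site]]
  if (is.null(prefixes)) abort(paste0("no ICD prefixes configured for site '", site, "'"))
  keep <- rep(FALSE, nrow(cohort))
  for (p in prefixes) keep <- keep | startsWith(cohort$diagnostic_code, p)
  cohort[keep, , drop = FALSE]
}

#' Impute missing intent and Rx isodose line by the most-often rule
#'
#' Missing treatment intent and Rx isodose line values are replaced by the
#' most used value of that feature among records sharing the *exact same
#' prescription* (dose per fraction, number of fractions). Groups with no
#' observed value fall back to the technique-level mode, then the
#' cohort-level mode. Ties are broken by lexicographic (numeric ascending)
#' order of the candidate values, so imputation is deterministic and
#' idempotent.
#'
#' @param cohort A cohort tibble.
#' @return The cohort with no missing `intent` or `rx_isodose_line_pct`.
#' @export
impute_most_often <- function(cohort) {
  for (feature in c("intent", "rx_isodose_line_pct")) {
    x <- cohort[[feature]]
    if (all(is.na(x))) {
      abort(paste0("feature '", feature, "' is missing in the entire cohort"))
    }
    if (!anyNA(x)) next
    key <- paste(cohort$dose_per_fraction_cgy, cohort$n_fractions)
    fill <- stats_mode_by(x, key)
    fill[is.na(fill)] <- stats_mode_by(x, cohort$technique)[is.na(fill)]
    fill[is.na(fill)] <- stats_mode(x)
    x[is.na(x)] <- fill[is.na(x)]
    cohort[[feature]] <- x
  }
  cohort
}

# Modal non-missing value; ties broken by sort order of the values.
stats_mode <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(x[NA_integer_])
  tab <- table(x)
  v <- names(tab)[tab == max(tab)][1]   # table() names are sorted
  if (is.numeric(x)) as.numeric(v) else v
}

# Per-group mode, returned aligned with the input rows.
stats_mode_by <- function(x, key) {
  modes <- tapply(x, key, stats_mode)
  out <- modes[key]
  if (is.numeric(x)) as.numeric(out) else as.character(out)
}

#' Derive the categorical age group
#'
#' Patient age is collapsed to `pediatric`/`adult` to accentuate the
#' radiobiological difference between pediatric and adult treatments:
#' `pediatric` iff `age < cutoff` (default 18 years; exactly 18 is adult).
#'
#' @param age Non-negative age(s) in years.
#' @param config An [engineering_config()] carrying the cutoff.
#' @return Character vector of `"pediatric"`/`"adult"`.
#' @export
derive_age_group <- function(age, config = engineering_config()) {
  if (any(!is.na(age) & age < 0)) abort("age must be non-negative")
  ifelse(is.na(age), NA_character_,
         ifelse(age < config$pediatric_age_cutoff, "pediatric", "adult"))
}

#' Diagnostic-code frequency weights within each prescription
#'
#' Converts the categorical ICD-10 code into a numeric feature that
#' prioritises frequent prescription/diagnosis combinations: for each exact
#' prescription, the weight of a code is the number of records carrying that
#' code divided by the number of records carrying that prescription
#' (replication weights count as copies). Weights within a prescription
#' group sum to 1.
#'
#' @param cohort A cohort tibble.
#' @return A tibble with columns `dose_per_fraction_cgy`, `n_fractions`,
#'   `diagnostic_code`, `icd_weight`.
#' @seealso [apply_icd_weights()] to attach the weight as a record feature.
#' @export
icd_weights <- function(cohort) {
  cohort %>%
    group_by(.data$dose_per_fraction_cgy, .data$n_fractions) %>%
    mutate(.rx_total = sum(.data$replication_weight)) %>%
    group_by(.data$dose_per_fraction_cgy, .data$n_fractions,
             .data$diagnostic_code, .data$.rx_total) %>%
    summarise(icd_weight = sum(.data$replication_weight), .groups = "drop") %>%
    mutate(icd_weight = .data$icd_weight / .data$.rx_total) %>%
    select("dose_per_fraction_cgy", "n_fractions", "diagnostic_code", "icd_weight")
}

#' Attach diagnostic-code weights as a record feature
#'
#' Replaces each record's categorical diagnostic code by its frequency
#' weight for downstream distance computation. Codes never seen with a
#' prescription in the reference cohort get weight 0 (a maximally atypical
#' combination).
#'
#' @param records Records to featurise.
#' @param reference Cohort whose weight map applies; defaults to `records`
#'   itself (the usual case when engineering a historical database).
#' @return `records` with an `icd_weight` column.
#' @export
apply_icd_weights <- function(records, reference = records) {
  wmap <- icd_weights(reference)
  records$icd_weight <- NULL
  out <- left_join(records, wmap,
                   by = c("dose_per_fraction_cgy", "n_fractions", "diagnostic_code"))
  out$icd_weight[is.na(out$icd_weight)] <- 0
  out
}

#' Upweight rarely used reduced-field prescriptions
#'
#' Rarely used but legitimate regimens (e.g. reduced-field boosts) would be
#' flagged excessively by a frequency-driven detector; their representation
#' in the historical database is intentionally increased by multiplying the
#' replication weight of matching records by a configured factor.
#'
#' @inheritParams remove_qa_records
#' @return The cohort with adjusted `replication_weight`.
#' @export
upweight_rare_rx <- function(cohort, config = engineering_config()) {
  for (rule in config$rare_rx_upweight) {
    hit <- cohort$dose_per_fraction_cgy == rule$dose & cohort$n_fractions == rule$fractions
    cohort$replication_weight[hit] <- cohort$replication_weight[hit] * as.integer(rule$factor)
  }
  cohort
}

#' Run the full feature-engineering pipeline
#'
#' QA removal, ICD-based site selection, configured regimen exclusions, age
#' grouping, most-often imputation, diagnostic-code weighting and rare-Rx
#' upweighting, in that order. The result is a model-ready historical
#' database with no missing values. Prescription fields, technique and dates
#' are never altered.
#'
#' @inheritParams select_site_by_icd
#' @return The engineered cohort tibble (extra column `icd_weight`).
#' @export
engineer_cohort <- function(cohort, site = cohort$site[1],
                            config = engineering_config()) {
  out <- remove_qa_records(cohort, config)
  out <- select_site_by_icd(out, site, config)
  for (rule in config$rx_exclusions) {
    out <- out[!(out$dose_per_fraction_cgy == rule$dose &
                   out$n_fractions == rule$fractions), , drop = FALSE]
  }
  if (nrow(out) == 0) abort("no records survive engineering")
  derived <- derive_age_group(out$age_years, config)
  out$age_group <- ifelse(is.na(out$age_group), derived, out$age_group)
  if (anyNA(out$age_group)) abort("records without age_years or age_group")
  out <- impute_most_often(out)
  out <- apply_icd_weights(out)
  out <- upweight_rare_rx(out, config)
  out
}

#' Prepare query records against an engineered cohort
#'
#' New records to be screened are put on the same footing as the historical
#' database: age group derived, missing intent / isodose line imputed from
#' the cohort's most-often values, and the diagnostic code replaced by its
#' frequency weight *under the cohort's map* (unseen combinations get 0).
#'
#' @param records New records (same columns as a raw cohort).
#' @param cohort The engineered historical cohort they are screened against.
#' @param config An [engineering_config()].
#' @return `records` ready for [detect_anomalies()].
#' @export
prepare_queries <- function(records, cohort, config = engineering_config()) {
  derived <- derive_age_group(records$age_years, config)
  records$age_group <- ifelse(is.na(records$age_group), derived, records$age_group)
  for (feature in c("intent", "rx_isodose_line_pct")) {
    x <- records[[feature]]
    if (!anyNA(x)) next
    key <- paste(records$dose_per_fraction_cgy, records$n_fractions)
    ref_key <- paste(cohort$dose_per_fraction_cgy, cohort$n_fractions)
    modes <- tapply(cohort[[feature]], ref_key, stats_mode)
    fill <- modes[key]
    fill <- if (is.numeric(x)) as.numeric(fill) else as.character(fill)
    tech_modes <- tapply(cohort[[feature]], cohort$technique, stats_mode)
    tfill <- tech_modes[records$technique]
    tfill <- if (is.numeric(x)) as.numeric(tfill) else as.character(tfill)
    fill[is.na(fill)] <- tfill[is.na(fill)]
    fill[is.na(fill)] <- stats_mode(cohort[[feature]])
    x[is.na(x)] <- fill[is.na(x)]
    records[[feature]] <- x
  }
  apply_icd_weights(records, reference = cohort)
}
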