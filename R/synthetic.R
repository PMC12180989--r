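#' Specification of a synthetic historical cohort
#'
#' Describes a site-specific multi-decade treatment database so the whole
#' pipeline is testable without clinical exports: per-technique regimen
#' catalogs with era windows (regimens appear and retire), logistic
#' technique-adoption curves over calendar years (the historical shift from
#' 3D conformal toward IMRT and stereotactic treatments), era-windowed beam
#' energies, intent/diagnosis conditionals, isodose and age distributions,
#' and missingness rates for the two imputable features.
#'
#' @param site `"brain"` or `"thoracic"` (or any label).
#' @param size Total number of records `S`.
#' @param regimens Tibble `technique, dose, fractions, freq, from, to,
#'   palliative_frac`: catalog of prescriptions with within-technique base
#'   frequencies (renormalised among regimens active in a year) and the
#'   probability that the regimen is used with palliative intent.
#' @param adoption Named list of logistic share parameters
#'   `c(mid, rate, max)` for `IMRT` and `SBRT_SRT`; the 3D share is the
#'   remainder (floored at 3% and renormalised). A technique's share is
#'   forced to zero before its earliest regimen year.
#' @param energies Tibble `technique, energy, freq, from, to` (era-windowed,
#'   renormalised among active energies).
#' @param icd_codes Named list with `curative` and `palliative` code pools,
#'   each a tibble `code, freq`.
#' @param isodose Named list per technique: tibble `value, freq` of Rx
#'   isodose line percentages, optionally era-windowed with `from`/`to`
#'   columns (prescribing conventions change over time).
#' @param pediatric_prob Probability that a record is pediatric.
#' @param adult_age,pediatric_age `c(mean, sd)` and `c(min, max)` of the age
#'   distributions.
#' @param missingness `c(intent = , isodose = )` missing-at-random rates
#'   injected into the raw export.
#' @param years Calendar span of the database.
#' @param year_growth Relative sampling weight of the last year versus the
#'   first (clinical volume grows over time).
#' @param seed Default seed used by [generate_cohort()].
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(site, size, regimens, adoption, energies, icd_codes,
                        isodose, pediatric_prob = 0.05,
                        adult_age = c(63, 13), pediatric_age = c(1, 17),
                        missingness = c(intent = 0.05, isodose = 0.08),
                        years = 1995:2021, year_growth = 2, seed = 1) {
  stopifnot(size > 0, all(missingness >= 0), all(missingness < 1))
  regimens <- as_tibble(regimens)
  by_tech <- split(regimens$freq, regimens$technique)
  if (any(vapply(by_tech, sum, 0) <= 0)) abort("regimen frequencies must be positive per technique")
  structure(
    list(site = site, size = size, regimens = regimens, adoption = adoption,
         energies = as_tibble(energies), icd_codes = icd_codes,
         isodose = isodose, pediatric_prob = pediatric_prob,
         adult_age = adult_age, pediatric_age = pediatric_age,
         missingness = missingness, years = years,
         year_growth = year_growth, seed = seed),
    class = "cohort_spec"
  )
}

# Technique shares per calendar year: logistic adoption for IMRT and
# SBRT_SRT (zero before each technique's first regimen), remainder to 3D.
.technique_shares <- function(spec, year) {
  first_year <- tapply(spec$regimens$from, spec$regimens$technique, min)
  share <- function(tech) {
    p <- spec$adoption[[tech]]
    if (is.null(p)) return(0)
    s <- p[["max"]] / (1 + exp(-p[["rate"]] * (year - p[["mid"]])))
    ifelse(year < first_year[[tech]], 0, s)
  }
  s_imrt <- share("IMRT")
  s_sbrt <- share("SBRT_SRT")
  s_3d <- pmax(1 - s_imrt - s_sbrt, 0.03)
  total <- s_imrt + s_sbrt + s_3d
  cbind(IMRT = s_imrt / total, `3D` = s_3d / total, SBRT_SRT = s_sbrt / total)
}

.sample_catalog <- function(catalog, year, n, what) {
  active <- catalog[catalog$from <= year & catalog$to >= year, , drop = FALSE]
  if (nrow(active) == 0) {
    abort(paste0("no active ", what, " in year ", year,
                 " for a technique with nonzero share"))
  }
  active[sample.int(nrow(active), n, replace = TRUE, prob = active$freq), ,
         drop = FALSE]
}

#' Generate a synthetic historical cohort
#'
#' Draws `spec$size` records: a calendar year (volume growing mildly over
#' time), a technique from the adoption-curve shares of that year, a
#' prescription from the technique's catalog restricted to regimens active
#' in that era, then intent, diagnostic code, beam energy, isodose line and
#' age from the configured conditionals; finally missingness is injected
#' into intent and isodose line at the configured rates. Fully reproducible
#' from the seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (defaults to `spec$seed`).
#' @return A raw (unengineered) cohort tibble; pass to [engineer_cohort()].
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  n <- spec$size
  withr::with_seed(seed, {
    yr_weights <- seq(1, spec$year_growth, length.out = length(spec$years))
    year <- sample(spec$years, n, replace = TRUE, prob = yr_weights)

    technique <- character(n)
    for (y in unique(year)) {
      idx <- which(year == y)
      shares <- .technique_shares(spec, y)
      technique[idx] <- sample(colnames(shares), length(idx), replace = TRUE,
                               prob = shares[1, ])
    }

    dose <- numeric(n); frac <- integer(n); pall_frac <- numeric(n)
    energy <- character(n); isodose <- numeric(n)
    for (tech in unique(technique)) {
      cat_rx <- spec$regimens[spec$regimens$technique == tech, ]
      cat_en <- spec$energies[spec$energies$technique == tech, ]
      iso <- spec$isodose[[tech]]
      for (y in unique(year[technique == tech])) {
        idx <- which(technique == tech & year == y)
        rx <- .sample_catalog(cat_rx, y, length(idx), "regimens")
        dose[idx] <- rx$dose
        frac[idx] <- as.integer(rx$fractions)
        pall_frac[idx] <- rx$palliative_frac
        en <- .sample_catalog(cat_en, y, length(idx), "energies")
        energy[idx] <- en$energy
        if (!all(c("from", "to") %in% names(iso))) {
          iso$from <- min(spec$years)
          iso$to <- max(spec$years)
        }
        isodose[idx] <- .sample_catalog(iso, y, length(idx), "isodose values")$value
      }
    }

    intent <- ifelse(runif(n) < pall_frac, "palliative", "curative")
    code <- character(n)
    for (it in c("curative", "palliative")) {
      idx <- which(intent == it)
      pool <- spec$icd_codes[[it]]
      code[idx] <- pool$code[sample.int(nrow(pool), length(idx),
                                        replace = TRUE, prob = pool$freq)]
    }

    pedi <- runif(n) < spec$pediatric_prob
    age <- numeric(n)
    age[pedi] <- sample(seq(spec$pediatric_age[1], spec$pediatric_age[2]),
                        sum(pedi), replace = TRUE)
    age[!pedi] <- pmin(pmax(round(rnorm(sum(!pedi), spec$adult_age[1],
                                        spec$adult_age[2])), 18), 95)

    start_date <- as.Date(paste0(year, "-01-01")) +
      sample.int(365, n, replace = TRUE) - 1L

    intent[runif(n) < spec$missingness[["intent"]]] <- NA_character_
    isodose[runif(n) < spec$missingness[["isodose"]]] <- NA_real_

    tibble(
      record_id = sprintf("SYN%05d", seq_len(n)), site = spec$site,
      technique = technique, dose_per_fraction_cgy = dose,
      n_fractions = frac, energy = energy, rx_isodose_line_pct = isodose,
      intent = intent, diagnostic_code = code, age_years = age,
      age_group = NA_character_, start_date = start_date,
      replication_weight = 1L
    )
  })
}

.regimen <- function(technique, dose, fractions, freq, from = 1995, to = 2021,
                     palliative_frac = 0.05) {
  tibble(technique = technique, dose = dose, fractions = fractions,
         freq = freq, from = from, to = to, palliative_frac = palliative_frac)
}

#' Default brain and thoracic cohort specifications
#'
#' Presets emulating the study's two site databases (about 4100 brain and
#' 2000 thoracic records spanning 1995-2021), including the documented
#' thoracic regimen trends: the rising SBRT regimens 4 x 1200 cGy and
#' 5 x 1000 cGy and the rising IMRT regimen 30 x 200 cGy, and the retired
#' 3D regimens 20 x 180, 17 x 180 and 20 x 200 cGy; brain presets cover
#' radiosurgery/SRT, IMRT and 3D (including palliative whole-brain courses)
#' with ICD-10 pools C71.x / C79.31 for brain and C34.x / C15.x / C22.8 for
#' thoracic. Real per-regimen frequencies are not published; these defaults
#' are synthetic but clinically shaped.
#'
#' @return Named list of [cohort_spec()] objects (`brain`, `thoracic`).
#' @export
default_specs <- function() {
  brain_regimens <- bind_rows(
    .regimen("SBRT_SRT", 1800, 1, 0.30, from = 1998, palliative_frac = 0.05),
    .regimen("SBRT_SRT", 2000, 1, 0.15, from = 1998, palliative_frac = 0.05),
    .regimen("SBRT_SRT", 1500, 1, 0.15, from = 1998, palliative_frac = 0.95),
    .regimen("SBRT_SRT", 900, 3, 0.25, from = 2008, palliative_frac = 0.05),
    .regimen("SBRT_SRT", 600, 5, 0.15, from = 2010, palliative_frac = 0.95),
    .regimen("IMRT", 200, 30, 0.40, from = 2004, palliative_frac = 0.05),
    .regimen("IMRT", 180, 33, 0.25, from = 2004, palliative_frac = 0.05),
    .regimen("IMRT", 300, 10, 0.20, from = 2012, palliative_frac = 0.95),
    .regimen("IMRT", 250, 15, 0.15, from = 2008, palliative_frac = 0.95),
    .regimen("3D", 300, 10, 0.35, palliative_frac = 0.95),
    .regimen("3D", 400, 5, 0.15, palliative_frac = 0.95),
    .regimen("3D", 180, 20, 0.15, to = 2016, palliative_frac = 0.05),
    .regimen("3D", 180, 25, 0.10, to = 2014, palliative_frac = 0.05),
    .regimen("3D", 200, 30, 0.25, to = 2012, palliative_frac = 0.05)
  )
  brain_energies <- tibble(
    technique = c("IMRT", "IMRT", "IMRT", "3D", "3D", "3D",
                  "SBRT_SRT", "SBRT_SRT", "SBRT_SRT"),
    energy = c("6x", "10x", "6fff", "6x", "10x", "4e",
               "1.25", "6x", "6fff"),
    freq = c(0.85, 0.15, 0.3, 0.8, 0.15, 0.05, 0.8, 0.85, 0.4),
    from = c(1995, 1995, 2016, 1995, 1995, 1995, 1995, 2004, 2014),
    to = c(2021, 2021, 2021, 2021, 2021, 2021, 2003, 2021, 2021)
  )
  brain_icd <- list(
    curative = tibble(
      code = sprintf("C71.%d", c(9, 1, 3, 0, 2)),
      freq = c(0.55, 0.18, 0.12, 0.08, 0.07)
    ),
    palliative = tibble(
      code = c("C79.31", "C71.9"),
      freq = c(0.9, 0.1)
    )
  )
  thoracic_regimens <- bind_rows(
    .regimen("SBRT_SRT", 1200, 4, 0.35, from = 2009, palliative_frac = 0.05),
    .regimen("SBRT_SRT", 1000, 5, 0.30, from = 2011, palliative_frac = 0.05),
    .regimen("SBRT_SRT", 1800, 3, 0.20, from = 2013, palliative_frac = 0.05),
    .regimen("SBRT_SRT", 800, 5, 0.15, from = 2008, palliative_frac = 0.95),
    .regimen("IMRT", 200, 30, 0.35, from = 2012, palliative_frac = 0.05),
    .regimen("IMRT", 180, 33, 0.25, from = 2006, palliative_frac = 0.05),
    .regimen("IMRT", 180, 25, 0.15, from = 2006, palliative_frac = 0.05),
    .regimen("IMRT", 200, 23, 0.10, from = 2008, palliative_frac = 0.05),
    .regimen("IMRT", 300, 10, 0.15, from = 2010, palliative_frac = 0.95),
    .regimen("IMRT", 300, 20, 0.12, from = 2019, palliative_frac = 0.05),
    .regimen("3D", 180, 20, 0.20, to = 2015, palliative_frac = 0.05),
    .regimen("3D", 180, 17, 0.15, to = 2015, palliative_frac = 0.05),
    .regimen("3D", 200, 20, 0.20, to = 2016, palliative_frac = 0.05),
    .regimen("3D", 300, 10, 0.20, palliative_frac = 0.95),
    .regimen("3D", 400, 5, 0.10, palliative_frac = 0.95),
    .regimen("3D", 250, 15, 0.10, to = 2014, palliative_frac = 0.05),
    .regimen("3D", 800, 1, 0.05, from = 2000, palliative_frac = 0.98)
  )
  thoracic_energies <- tibble(
    technique = c("IMRT", "IMRT", "IMRT", "3D", "3D",
                  "SBRT_SRT", "SBRT_SRT", "SBRT_SRT"),
    energy = c("6x", "10x", "6fff", "6x", "10x", "6x", "10x", "6fff"),
    freq = c(0.85, 0.15, 0.35, 0.85, 0.15, 0.85, 0.15, 0.92),
    from = c(1995, 1995, 2016, 1995, 1995, 1995, 1995, 2013),
    to = c(2021, 2021, 2021, 2021, 2021, 2012, 2012, 2021)
  )
  thoracic_icd <- list(
    curative = tibble(
      code = c("C34.10", "C34.11", "C34.31", "C15.4", "C34.90", "C22.8"),
      freq = c(0.45, 0.18, 0.15, 0.10, 0.08, 0.04)
    ),
    palliative = tibble(
      code = c("C34.90", "C34.10", "C15.5"),
      freq = c(0.60, 0.25, 0.15)
    )
  )
  isodose_brain <- list(
    IMRT = tibble(value = c(100, 98), freq = c(0.92, 0.08)),
    `3D` = tibble(value = c(100, 98, 95), freq = c(0.8, 0.1, 0.1)),
    SBRT_SRT = tibble(value = c(80, 84, 86), freq = c(0.5, 0.3, 0.2))
  )
  isodose_thoracic <- list(
    IMRT = tibble(value = c(100, 98), freq = c(0.92, 0.08)),
    `3D` = tibble(value = c(100, 98, 95), freq = c(0.8, 0.1, 0.1)),
    SBRT_SRT = tibble(value = c(84, 86, 88), freq = c(0.4, 0.35, 0.25))
  )
  list(
    brain = cohort_spec(
      site = "brain", size = 4100, regimens = brain_regimens,
      adoption = list(IMRT = c(mid = 2007, rate = 0.5, max = 0.62),
                      SBRT_SRT = c(mid = 2008, rate = 0.5, max = 0.42)),
      energies = brain_energies, icd_codes = brain_icd,
      isodose = isodose_brain, pediatric_prob = 0.03, seed = 101
    ),
    thoracic = cohort_spec(
      site = "thoracic", size = 2000, regimens = thoracic_regimens,
      adoption = list(IMRT = c(mid = 2010, rate = 0.55, max = 0.6),
                      SBRT_SRT = c(mid = 2012, rate = 0.5, max = 0.38)),
      energies = thoracic_energies, icd_codes = thoracic_icd,
      isodose = isodose_thoracic, pediatric_prob = 0.02, seed = 102
    )
  )
}

#' Thoracic specification with an injected sharp secular shift
#'
#' A variant of the default thoracic cohort whose IMRT practice changes
#' decisively in the mid-2010s — the regime where incremental retraining
#' matters. Beam energy converts completely from flattened (6x/10x) to
#' flattening-filter-free (6fff) delivery in 2016, the conventional
#' 33 x 180 cGy and 23 x 200 cGy courses retire by 2016-2017, and a
#' hypofractionated 20 x 300 cGy course is introduced in 2018 alongside the
#' rising 30 x 200 cGy standard. Used by [incremental_comparison()]: a model
#' trained on the raw history treats retired practice as current, while
#' linear time scaling shifts the effective database to the modern era.
#'
#' @return A [cohort_spec()].
#' @export
drifted_thoracic_spec <- function() {
  spec <- default_specs()$thoracic
  reg <- spec$regimens
  reg$to[reg$technique == "IMRT" & reg$fractions == 33] <- 2017
  reg$to[reg$technique == "IMRT" & reg$fractions == 23] <- 2016
  reg$freq[reg$technique == "IMRT" & reg$fractions == 20 & reg$dose == 300] <- 0.25
  spec$regimens <- reg
  en <- spec$energies
  imrt_flat <- en$technique == "IMRT" & en$energy %in% c("6x", "10x")
  en$to[imrt_flat] <- 2015
  en$freq[en$technique == "IMRT" & en$energy == "6fff"] <- 0.9
  en$from[en$technique == "IMRT" & en$energy == "6fff"] <- 2016
  spec$energies <- en
  # prescribing convention shifts from the 100% to the 98% isodose line
  spec$isodose$IMRT <- tibble(
    value = c(100, 98, 98, 100),
    freq = c(0.95, 0.05, 0.9, 0.1),
    from = c(1995, 1995, 2016, 2016),
    to = c(2015, 2015, 2021, 2021)
  )
  spec
}
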