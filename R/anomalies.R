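#' Specification of the anomaly simulator
#'
#' Simulated anomalies mimic realistic prescribing errors using conditional
#' frequencies from the historical database: a perturbed value only counts
#' as anomalous when it rarely or never co-occurs with the rest of the
#' record (empirical frequency below `p_min`).
#'
#' The prescription-error catalog holds the perturbation rules with
#' sampling weights: `swap` (dose per fraction and fraction number
#' exchanged), `scale10` (dose multiplied or divided by 10 — a decimal-point
#' error), `digit` (single-digit substitution in the dose), and
#' `cross_technique` (the prescription replaced by a regimen drawn from a
#' different technique's empirical distribution).
#'
#' @param rx_error_catalog Named numeric vector of sampling weights over the
#'   four rules.
#' @param p_min Frequency floor in (0, 1): a value with conditional
#'   frequency below this counts as "rarely/never co-occurring"
#'   (default 0.02).
#' @param dose_window Sanity window in cGy for perturbed doses (digit rule).
#' @param max_retries Bounded number of redraws before the simulator errors.
#' @return An `anomaly_spec` list.
#' @export
anomaly_spec <- function(rx_error_catalog = c(swap = 1, scale10 = 1,
                                              digit = 1, cross_technique = 1),
                         p_min = 0.02,
                         dose_window = c(10, 5000),
                         max_retries = 100) {
  if (length(rx_error_catalog) == 0 || any(rx_error_catalog < 0) ||
      sum(rx_error_catalog) <= 0) {
    abort("rx_error_catalog must hold non-negative weights with positive sum")
  }
  if (p_min <= 0 || p_min >= 1) abort("p_min must lie in (0, 1)")
  structure(
    list(rx_error_catalog = rx_error_catalog, p_min = p_min,
         dose_window = dose_window, max_retries = max_retries),
    class = "anomaly_spec"
  )
}

# Weighted empirical frequency of an exact prescription in a cohort.
.rx_frequency <- function(dose, fractions, cohort) {
  w <- cohort$replication_weight
  sum(w[cohort$dose_per_fraction_cgy == dose & cohort$n_fractions == fractions]) / sum(w)
}

.apply_rx_rule <- function(rule, dose, fractions, cohort, site_cohort, spec) {
  switch(rule,
    swap = {
      new_frac <- max(1L, as.integer(round_half_up(dose)))
      list(dose = max(as.numeric(fractions), 1), fractions = new_frac)
    },
    scale10 = {
      fac <- sample(c(10, 0.1), 1)
      list(dose = dose * fac, fractions = fractions)
    },
    digit = {
      digits <- strsplit(format(dose, scientific = FALSE, trim = TRUE), "")[[1]]
      pos <- which(digits %in% as.character(0:9))
      i <- if (length(pos) == 1) pos else sample(pos, 1)
      old <- digits[i]
      digits[i] <- sample(setdiff(as.character(0:9), old), 1)
      cand <- as.numeric(paste(digits, collapse = ""))
      if (is.na(cand) || cand < spec$dose_window[1] || cand > spec$dose_window[2]) {
        return(NULL)
      }
      list(dose = cand, fractions = fractions)
    },
    cross_technique = {
      other <- site_cohort[site_cohort$technique != cohort$technique[1], , drop = FALSE]
      if (nrow(other) == 0) return(NULL)
      i <- sample.int(nrow(other), 1, prob = other$replication_weight)
      list(dose = other$dose_per_fraction_cgy[i], fractions = other$n_fractions[i])
    }
  )
}

#' Simulate one prescription (Rx) anomaly
#'
#' Draws a base record uniformly from the cohort, applies one rule from the
#' error catalog to its prescription, and accepts the result only when the
#' perturbed exact prescription has empirical frequency below `p_min` in
#' the cohort — guaranteeing an atypical dose/fractionation while all
#' clinical features stay those of a real record. Labeled `truth = 1`,
#' `type = 1`.
#'
#' @param cohort Engineered cohort for one technique (base records are drawn
#'   from here).
#' @param spec An [anomaly_spec()].
#' @param site_cohort Optional full site cohort (all techniques), needed by
#'   the `cross_technique` rule; defaults to `cohort`.
#' @return A one-row labeled record tibble.
#' @note Call inside [withr::with_seed()] (or see [make_anomaly_sets()]) for
#'   reproducibility.
#' @export
simulate_rx_anomaly <- function(cohort, spec = anomaly_spec(),
                                site_cohort = cohort) {
  if (nrow(cohort) == 0) abort("empty cohort")
  rules <- names(spec$rx_error_catalog)
  for (try in seq_len(spec$max_retries)) {
    base <- cohort[sample.int(nrow(cohort), 1, prob = cohort$replication_weight), ]
    rule <- sample(rules, 1, prob = spec$rx_error_catalog)
    pert <- .apply_rx_rule(rule, base$dose_per_fraction_cgy, base$n_fractions,
                           cohort, site_cohort, spec)
    if (is.null(pert) || pert$dose <= 0 || pert$fractions < 1) next
    if (.rx_frequency(pert$dose, pert$fractions, cohort) < spec$p_min) {
      out <- base
      out$dose_per_fraction_cgy <- pert$dose
      out$n_fractions <- as.integer(pert$fractions)
      if ("icd_weight" %in% names(out)) {
        out$icd_weight <- .lookup_icd_weight(out, cohort)
      }
      out$record_id <- paste0(base$record_id, "-rxa")
      out$replication_weight <- 1L
      out$truth <- 1L
      out$type <- 1L
      return(out)
    }
  }
  abort("could not produce a sub-p_min prescription within the retry budget")
}

# Values of one feature that rarely/never co-occur with an exact Rx.
.rare_feature_values <- function(feature, dose, fractions, cohort, p_min) {
  pool <- unique(cohort[[feature]])
  grp <- cohort[cohort$dose_per_fraction_cgy == dose & cohort$n_fractions == fractions, ]
  w <- grp$replication_weight
  total <- sum(w)
  freq <- vapply(pool, function(v) sum(w[grp[[feature]] == v]) / total, 0)
  pool[freq < p_min]
}

#' Simulate one feature anomaly
#'
#' Draws a base record, keeps its prescription exactly, and replaces the
#' value of one feature (energy, intent, Rx isodose line, age group or
#' diagnostic code, chosen uniformly among those with an eligible
#' replacement) by a value whose conditional frequency *given that exact
#' prescription* is below `p_min` — e.g. a pediatric age group on an
#' adult-only regimen, or a palliative intent on a curative-only one.
#' Labeled `truth = 1`, `type = 2`.
#'
#' @inheritParams simulate_rx_anomaly
#' @return A one-row labeled record tibble (prescription equal to the base
#'   record's).
#' @export
simulate_feature_anomaly <- function(cohort, spec = anomaly_spec(),
                                     site_cohort = cohort) {
  if (nrow(cohort) == 0) abort("empty cohort")
  features <- c("energy", "intent", "rx_isodose_line_pct", "age_group",
                "diagnostic_code")
  for (try in seq_len(spec$max_retries)) {
    base <- cohort[sample.int(nrow(cohort), 1, prob = cohort$replication_weight), ]
    candidates <- lapply(features, function(f) {
      vals <- .rare_feature_values(f, base$dose_per_fraction_cgy,
                                   base$n_fractions, site_cohort, spec$p_min)
      setdiff(vals, base[[f]])   # the record must actually change
    })
    ok <- which(lengths(candidates) > 0)
    if (length(ok) == 0) next
    fi <- if (length(ok) == 1) ok else sample(ok, 1)
    feature <- features[fi]
    vals <- candidates[[fi]]
    out <- base
    out[[feature]] <- if (length(vals) == 1) vals else sample(vals, 1)
    if (feature == "diagnostic_code" && "icd_weight" %in% names(out)) {
      out$icd_weight <- .lookup_icd_weight(out, cohort)
    }
    out$record_id <- paste0(base$record_id, "-fta")
    out$replication_weight <- 1L
    out$truth <- 1L
    out$type <- 2L
    return(out)
  }
  abort("no sub-p_min feature replacement found within the retry budget")
}

# Frequency weight of (exact Rx, code) in a cohort, computed directly.
.lookup_icd_weight <- function(record, cohort) {
  in_rx <- cohort$dose_per_fraction_cgy == record$dose_per_fraction_cgy &
    cohort$n_fractions == record$n_fractions
  total <- sum(cohort$replication_weight[in_rx])
  if (total == 0) return(0)
  sum(cohort$replication_weight[in_rx &
        cohort$diagnostic_code == record$diagnostic_code]) / total
}

#' Build a labeled anomaly set per technique
#'
#' Generates exactly `n_rx` prescription anomalies (type 1) and `n_feature`
#' feature anomalies (type 2) for each technique partition of the cohort,
#' reproducibly from the seed. The testing preset of the validation
#' protocol is 20 + 20 per technique; the training preset is configured in
#' [fit_rx_model()].
#'
#' @param cohort Engineered site cohort (all techniques).
#' @param n_rx,n_feature Anomalies of each type per technique.
#' @param spec An [anomaly_spec()].
#' @param seed Integer seed.
#' @return A labeled tibble with `truth` and `type` columns.
#' @export
make_anomaly_sets <- function(cohort, n_rx = 20, n_feature = 20,
                              spec = anomaly_spec(), seed = 1) {
  if (n_rx < 0 || n_feature < 0) abort("counts must be non-negative")
  parts <- partition_by_technique(cohort)
  withr::with_seed(seed, {
    out <- lapply(names(parts), function(tech) {
      .technique_anomalies(parts[[tech]], cohort, n_rx, n_feature, spec)
    })
    bind_rows(out)
  })
}

# Anomalies for one technique partition; base records are drawn from
# `base_cohort`, conditional frequencies checked against it, and the
# diagnostic-code weights refreshed against the partition in one batch.
# Runs under the caller's RNG state.
.technique_anomalies <- function(base_cohort, site_cohort, n_rx, n_feature,
                                 spec, weight_reference = base_cohort) {
  rx <- lapply(seq_len(n_rx), function(i) {
    a <- simulate_rx_anomaly(base_cohort, spec, site_cohort = site_cohort)
    a$record_id <- sprintf("%s-%03d", a$record_id, i)
    a
  })
  ft <- lapply(seq_len(n_feature), function(i) {
    a <- simulate_feature_anomaly(base_cohort, spec, site_cohort = site_cohort)
    a$record_id <- sprintf("%s-%03d", a$record_id, i)
    a
  })
  out <- bind_rows(c(rx, ft))
  if (nrow(out) == 0) return(out)
  labels <- out[c("record_id", "truth", "type")]
  refreshed <- apply_icd_weights(
    out[setdiff(names(out), c("icd_weight", "truth", "type"))],
    reference = weight_reference
  )
  refreshed$truth <- labels$truth
  refreshed$type <- labels$type
  refreshed
}
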