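# Fixture builders and independent brute-force oracles used across tests.

toy_records <- function(n, dose, frac, technique = "IMRT", energy = "6x",
                        iso = 100, intent = "curative", code = "C71.9",
                        age_group = "adult", site = "brain", year = 2015,
                        weight = 1L, id_prefix = "T") {
  tibble::tibble(
    record_id = sprintf("%s%04d", id_prefix, seq_len(n)),
    site = site, technique = technique,
    dose_per_fraction_cgy = dose, n_fractions = as.integer(frac),
    energy = energy, rx_isodose_line_pct = iso, intent = intent,
    diagnostic_code = code, age_years = 60,
    age_group = age_group,
    start_date = as.Date(sprintf("%d-06-15", year)),
    replication_weight = as.integer(weight)
  )
}

# Distinct ids across blocks, then diagnostic-code weights attached.
toy_cohort <- function(...) {
  blocks <- list(...)
  for (i in seq_along(blocks)) {
    blocks[[i]]$record_id <- paste0("B", i, "-", blocks[[i]]$record_id)
  }
  apply_icd_weights(dplyr::bind_rows(blocks))
}

# A random raw cohort for IO round-trip property tests.
random_raw_cohort <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      record_id = sprintf("R%04d", sample.int(9999, n)),
      site = "brain",
      technique = sample(c("IMRT", "3D", "SBRT_SRT"), n, replace = TRUE),
      dose_per_fraction_cgy = sample(c(180, 200, 250, 300, 1200), n, replace = TRUE),
      n_fractions = sample.int(35, n, replace = TRUE),
      energy = sample(c("6x", "10x", "6fff", "4e"), n, replace = TRUE),
      rx_isodose_line_pct = ifelse(runif(n) < 0.1, NA_real_,
                                   sample(c(80, 95, 98, 100), n, replace = TRUE)),
      intent = ifelse(runif(n) < 0.1, NA_character_,
                      sample(c("curative", "palliative"), n, replace = TRUE)),
      diagnostic_code = sample(c("C71.1", "C71.9", "C79.31"), n, replace = TRUE),
      age_years = sample(1:90, n, replace = TRUE),
      age_group = NA_character_,
      start_date = as.Date("1995-01-01") + sample.int(9000, n, replace = TRUE),
      replication_weight = sample.int(3, n, replace = TRUE)
    )
  })
}

# Independent per-feature Gower implementation (brute force).
brute_gower <- function(u, v, ranges, weights = NULL) {
  feats <- c("technique", "energy", "intent", "age_group",
             "rx_isodose_line_pct", "icd_weight")
  w <- rep(1, 6)
  names(w) <- feats
  if (!is.null(weights)) w[names(weights)] <- weights
  num <- 0
  for (f in feats) {
    if (f %in% c("rx_isodose_line_pct", "icd_weight")) {
      span <- ranges[[f]][2] - ranges[[f]][1]
      s <- if (span == 0) as.numeric(u[[f]] != v[[f]])
        else min(abs(u[[f]] - v[[f]]) / span, 1)
    } else {
      s <- as.numeric(u[[f]] != v[[f]])
    }
    num <- num + w[[f]] * s
  }
  num / sum(w)
}

brute_rx_dist <- function(p, q, ranges) {
  sc <- function(x, r) if (r[2] == r[1]) 0 else (x - r[1]) / (r[2] - r[1])
  sqrt((sc(p$dose_per_fraction_cgy, ranges$dose) -
          sc(q$dose_per_fraction_cgy, ranges$dose))^2 +
         (sc(p$n_fractions, ranges$fractions) -
            sc(q$n_fractions, ranges$fractions))^2)
}

# Expand replication weights into explicit duplicate rows.
expand_weights <- function(cohort) {
  out <- cohort[rep(seq_len(nrow(cohort)), cohort$replication_weight), ]
  out$replication_weight <- 1L
  out$record_id <- paste0(out$record_id, "#", seq_len(nrow(out)))
  out
}

# Brute-force R / F statistics on the expanded cohort: sort by prescription
# distance, take whole equal-distance groups, pro-rata share of the boundary
# group.
brute_knn_stat <- function(query, cohort, frac_k, what = c("r", "f"),
                           ranges = rx_ranges(cohort)) {
  what <- match.arg(what)
  ex <- expand_weights(cohort)
  d <- vapply(seq_len(nrow(ex)), function(i) brute_rx_dist(query, ex[i, ], ranges), 0)
  val <- if (what == "r") d else
    vapply(seq_len(nrow(ex)), function(i) brute_gower(query, ex[i, ], ranges), 0)
  k <- min(max(1, floor(frac_k * nrow(ex) + 0.5)), nrow(ex))
  groups <- split(seq_along(d), factor(d, levels = sort(unique(d))))
  total <- 0
  left <- k
  for (g in groups) {
    if (left <= 0) break
    take <- min(left, length(g))
    total <- total + take * mean(val[g])
    left <- left - take
  }
  total / k
}
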