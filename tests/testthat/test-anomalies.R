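eng_part <- function(site = "thoracic", seed = 41, technique = "IMRT") {
  coh <- engineer_cohort(generate_cohort(default_specs()[[site]], seed = seed))
  list(site = coh, part = partition_by_technique(coh)[[technique]])
}

test_that("simulated Rx anomalies are rare by construction and keep their features", {
  fx <- eng_part()
  spec <- anomaly_spec()
  withr::with_seed(1, {
    for (i in 1:40) {
      a <- simulate_rx_anomaly(fx$part, spec, site_cohort = fx$site)
      freq <- sum(fx$part$replication_weight[
        fx$part$dose_per_fraction_cgy == a$dose_per_fraction_cgy &
          fx$part$n_fractions == a$n_fractions]) / sum(fx$part$replication_weight)
      expect_lt(freq, spec$p_min)
      expect_equal(a$truth, 1L)
      expect_equal(a$type, 1L)
      expect_gt(a$dose_per_fraction_cgy, 0)
      expect_gte(a$n_fractions, 1)
      base_id <- sub("-rxa$", "", a$record_id)
      base <- fx$part[fx$part$record_id == base_id, ]
      expect_equal(a$energy, base$energy)       # features untouched
      expect_equal(a$intent, base$intent)
    }
  })
})

test_that("the swap rule exchanges dose and fraction number with integer clamping", {
  coh <- toy_cohort(toy_records(30, 200, 30))
  spec <- anomaly_spec(rx_error_catalog = c(swap = 1))
  a <- withr::with_seed(3, simulate_rx_anomaly(coh, spec))
  expect_equal(a$dose_per_fraction_cgy, 30)
  expect_equal(a$n_fractions, 200L)
})

test_that("rejection guarantees the simulated Rx differs from a two-regimen catalog", {
  coh <- toy_cohort(
    toy_records(20, 1200, 4, technique = "SBRT_SRT"),
    toy_records(20, 1000, 5, technique = "SBRT_SRT", id_prefix = "U")
  )
  withr::with_seed(5, {
    for (i in 1:20) {
      a <- simulate_rx_anomaly(coh, anomaly_spec())
      expect_false(a$dose_per_fraction_cgy == 1200 && a$n_fractions == 4)
      expect_false(a$dose_per_fraction_cgy == 1000 && a$n_fractions == 5)
    }
  })
})

test_that("feature anomalies keep the prescription and use sub-p_min values", {
  fx <- eng_part("brain", seed = 42)
  spec <- anomaly_spec()
  feats <- c("energy", "intent", "rx_isodose_line_pct", "age_group", "diagnostic_code")
  withr::with_seed(2, {
    for (i in 1:40) {
      a <- simulate_feature_anomaly(fx$part, spec, site_cohort = fx$site)
      base <- fx$part[fx$part$record_id == sub("-fta$", "", a$record_id), ]
      expect_equal(a$dose_per_fraction_cgy, base$dose_per_fraction_cgy)
      expect_equal(a$n_fractions, base$n_fractions)
      changed <- feats[vapply(feats, function(f) !identical(a[[f]], base[[f]]), TRUE)]
      expect_length(changed, 1)
      grp <- fx$site[fx$site$dose_per_fraction_cgy == a$dose_per_fraction_cgy &
                       fx$site$n_fractions == a$n_fractions, ]
      freq <- sum(grp$replication_weight[grp[[changed]] == a[[changed]]]) /
        sum(grp$replication_weight)
      expect_lt(freq, spec$p_min)
      expect_equal(a$type, 2L)
    }
  })
})

test_that("an intent that is 100 percent curative flips to palliative", {
  coh <- toy_cohort(
    toy_records(40, 200, 30, intent = "curative"),
    toy_records(5, 300, 10, intent = "palliative", id_prefix = "P")
  )
  spec <- anomaly_spec()
  withr::with_seed(4, {
    hits <- 0
    for (i in 1:30) {
      a <- simulate_feature_anomaly(coh, spec)
      if (a$intent != coh$intent[match(sub("-fta$", "", a$record_id), coh$record_id)]) {
        hits <- hits + 1
        expect_true(a$intent %in% c("curative", "palliative"))
      }
    }
    expect_gt(hits, 0)
  })
})

test_that("feature anomalies score above normal records on the F statistic", {
  # Separation depends on which feature is flipped: categorical flips (a
  # pediatric age group on an adult regimen) and isodose flips move F by a
  # full feature share, while a diagnostic-code flip only shifts the
  # code-weight coordinate and is mild — as the published per-record
  # examples themselves show (code-flip anomalies printed with F well below
  # threshold).
  fx <- eng_part("thoracic", seed = 43)
  part <- fx$part
  normal_f <- vapply(seq_len(nrow(part)), function(i) {
    f_statistic(part[i, ], part, mu = 0.02)
  }, 0)
  q90 <- stats::quantile(normal_f, 0.9)
  med <- stats::median(normal_f)
  anoms <- withr::with_seed(6, {
    dplyr::bind_rows(lapply(1:500, function(i) {
      simulate_feature_anomaly(part, anomaly_spec(), site_cohort = fx$site)
    }))
  })
  anom_f <- vapply(seq_len(nrow(anoms)), function(i) {
    f_statistic(anoms[i, ], part, mu = 0.02)
  }, 0)
  feats <- c("energy", "intent", "rx_isodose_line_pct", "age_group", "diagnostic_code")
  base <- part[match(sub("-fta-?[0-9]*$", "", anoms$record_id), part$record_id), ]
  flipped <- vapply(seq_len(nrow(anoms)), function(i) {
    feats[which(vapply(feats, function(f) !identical(anoms[[f]][i], base[[f]][i]), TRUE))[1]]
  }, "")
  strong <- flipped %in% c("energy", "intent", "age_group")
  expect_gte(mean(anom_f[strong] > q90), 0.95)
  expect_gte(mean(anom_f > med), 0.90)
  code <- flipped == "diagnostic_code"
  expect_gt(stats::median(anom_f[code]), med)
})

test_that("labeled anomaly sets have the configured composition and are reproducible", {
  coh <- engineer_cohort(generate_cohort(default_specs()$brain, seed = 44))
  set1 <- make_anomaly_sets(coh, n_rx = 4, n_feature = 4, seed = 12)
  expect_equal(nrow(set1), 3 * 8)          # per technique
  counts <- table(set1$technique, set1$type)
  expect_true(all(counts == 4))
  set2 <- make_anomaly_sets(coh, n_rx = 4, n_feature = 4, seed = 12)
  expect_identical(set1, set2)
  expect_equal(nrow(make_anomaly_sets(coh, 0, 0, seed = 1)), 0)
})
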