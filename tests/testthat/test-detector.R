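test_that("thresholds follow t_Rx = a*theta and t_F = b*tau, with the pairing switch", {
  thr <- compute_thresholds(a = 0.02, b = 1.12, tau = 0.13, theta = 0.45)
  expect_equal(thr$t_rx, 0.009)
  expect_equal(thr$t_f, 0.1456)
  sw <- compute_thresholds(a = 0.02, b = 1.12, tau = 0.13, theta = 0.45,
                           pairing = "footnote")
  expect_equal(sw$t_rx, 1.12 * 0.45)
  expect_equal(sw$t_f, 0.02 * 0.13)
  expect_equal(compute_thresholds(1, 1, 0.5, 0)$t_rx, 0)
  expect_error(compute_thresholds(-1, 1, 0.5, 0.5), "positive")
})

test_that("classification routes through the Rx check first, then the feature check", {
  # database: one frequent regimen with a stereotyped feature profile
  coh <- toy_cohort(
    toy_records(45, 1500, 1, technique = "SBRT_SRT", energy = "6x", iso = 84,
                intent = "palliative", code = "C79.31"),
    toy_records(30, 900, 3, technique = "SBRT_SRT", energy = "6x", iso = 84,
                intent = "curative", code = "C71.9", id_prefix = "W")
  )
  params <- model_params("brain", "SBRT_SRT", a = 0.02, b = 0.6,
                         nu = 0.05, mu = 0.05,
                         tau = mean_pairwise(coh)$tau,
                         theta = mean_pairwise(coh)$theta)

  # novel prescription: R exceeds t_Rx, F not evaluated, no database matches
  rx_anom <- toy_cohort(toy_records(1, 150, 1, technique = "SBRT_SRT",
                                    id_prefix = "QA1"))[1, ]
  res <- classify(rx_anom, coh, params)
  expect_equal(res$prediction, 1L)
  expect_gt(res$r, res$t_rx)
  expect_true(is.na(res$f))
  expect_equal(res$n_rx_matches_in_db, 0)

  # frequent prescription with atypical features: R = 0, F flags
  ft_anom <- toy_cohort(toy_records(1, 1500, 1, technique = "SBRT_SRT",
                                    energy = "10x", iso = 100, intent = "curative",
                                    age_group = "pediatric", code = "C71.1",
                                    id_prefix = "QA2"))[1, ]
  ft_anom$icd_weight <- 0
  res2 <- classify(ft_anom, coh, params)
  expect_equal(res2$prediction, 2L)
  expect_equal(res2$r, 0)
  expect_gt(res2$f, res2$t_f)
  expect_equal(res2$n_rx_matches_in_db, 45)

  # query identical to a frequent record is normal with R = F = 0
  norm <- coh[1, ]
  norm$record_id <- "QN"
  res3 <- classify(norm, coh, params)
  expect_equal(res3$prediction, 0L)
  expect_equal(res3$r, 0)
  expect_equal(res3$f, 0)

  expect_error(classify(rx_anom, coh,
                        model_params("brain", "IMRT", 1, 1, 0.1, 0.1, 0.2, 0.2)),
               "technique")

  # repeat calls agree bit for bit
  expect_identical(classify(ft_anom, coh, params), res2)
})

test_that("raising thresholds never converts a normal into an anomaly", {
  coh <- engineer_cohort(generate_cohort(default_specs()$brain, seed = 31))
  part <- partition_by_technique(coh)$IMRT
  mp <- mean_pairwise(part)
  q <- part[40, ]
  q$record_id <- "Q"
  preds <- sapply(c(0.05, 0.2, 0.8), function(mult) {
    p <- model_params("brain", "IMRT", a = mult, b = mult, nu = 0.01, mu = 0.01,
                      tau = mp$tau, theta = mp$theta)
    classify(q, part, p)$prediction
  })
  anomalous <- preds > 0
  expect_true(all(diff(anomalous) <= 0))   # monotone: loosening never re-flags
})

test_that("F1 score follows its closed form", {
  expect_equal(f1_score(20, 0, 0), 1)
  expect_equal(f1_score(36, 4, 4), 0.9)
  expect_equal(f1_score(0, 0, 20), 0)
  expect_error(f1_score(0, 0, 0), "undefined")
  expect_error(f1_score(-1, 0, 2), "non-negative")
})

test_that("holdout split removes n per technique, reproducibly and conservatively", {
  coh <- engineer_cohort(generate_cohort(default_specs()$brain, seed = 32))
  sp <- split_holdout(coh, n_per_technique = 20, seed = 5)
  expect_equal(nrow(sp$holdout), 60)
  expect_equal(as.vector(table(sp$holdout$technique)), c(20, 20, 20))
  expect_equal(nrow(sp$train) + nrow(sp$holdout), nrow(coh))
  expect_length(intersect(sp$train$record_id, sp$holdout$record_id), 0)
  sp2 <- split_holdout(coh, n_per_technique = 20, seed = 5)
  expect_identical(sp$holdout$record_id, sp2$holdout$record_id)
  expect_error(split_holdout(coh[1:30, ], n_per_technique = 20), "too small")
})

test_that("grid search returns the single grid point when there is no choice", {
  coh <- engineer_cohort(generate_cohort(default_specs()$thoracic, seed = 33))
  part <- partition_by_technique(coh)$IMRT
  anoms <- make_anomaly_sets(part, n_rx = 5, n_feature = 5, seed = 9)
  anoms <- anoms[anoms$technique == "IMRT", ]
  normals <- part[1:10, ]
  normals$truth <- 0L
  grid1 <- list(a = 0.05, b = 0.5, nu = 0.01, mu = 0.01)
  rep1 <- train_grid_search(part, anoms, normals, grid = grid1, runs = 1, seed = 1)
  expect_equal(rep1$best, list(a = 0.05, b = 0.5, nu = 0.01, mu = 0.01))
  p <- model_params("thoracic", "IMRT", 0.05, 0.5, 0.01, 0.01, rep1$tau, rep1$theta)
  preds <- vapply(seq_len(20), function(i) {
    rec <- dplyr::bind_rows(normals[, names(part)], anoms[, names(part)])[i, ]
    classify(rec, part, p)$prediction
  }, 0L)
  truth <- c(rep(0, 10), rep(1, 10))
  expect_equal(rep1$mean_f1,
               f1_score(sum(preds > 0 & truth == 1), sum(preds > 0 & truth == 0),
                        sum(preds == 0 & truth == 1)))
  expect_error(train_grid_search(part, anoms, normals,
                                 grid = list(a = numeric(0), b = 1, nu = 0.1, mu = 0.1)),
               "nonempty")
})

test_that("grid search equals the exhaustive-enumeration oracle", {
  spec <- default_specs()$thoracic
  spec$size <- 200
  coh <- engineer_cohort(generate_cohort(spec, seed = 34))
  part <- partition_by_technique(coh)$`3D`
  anoms <- make_anomaly_sets(part, n_rx = 8, n_feature = 8, seed = 11)
  normals <- part[seq(1, 30, by = 2), ]
  normals$truth <- 0L
  grid <- list(a = c(0.02, 0.2, 0.9), b = c(0.05, 0.4, 1.1),
               nu = c(0.01, 0.05), mu = c(0.01, 0.05))
  rep <- train_grid_search(part, anoms, normals, grid = grid, runs = 1, seed = 2)

  labeled <- dplyr::bind_rows(normals[, c(names(part), "truth")],
                              anoms[, c(names(part), "truth")])
  best <- NULL
  for (mu in grid$mu) for (nu in grid$nu) for (b in grid$b) for (a in grid$a) {
    p <- model_params("thoracic", "3D", a, b, nu, mu, rep$tau, rep$theta)
    preds <- vapply(seq_len(nrow(labeled)), function(i) {
      classify(labeled[i, ], part, p)$prediction
    }, 0L)
    f1 <- f1_score(sum(preds > 0 & labeled$truth == 1),
                   sum(preds > 0 & labeled$truth == 0),
                   sum(preds == 0 & labeled$truth == 1))
    if (is.null(best) || f1 > best$f1 + 1e-12) {
      best <- list(a = a, b = b, nu = nu, mu = mu, f1 = f1)
    }
  }
  expect_equal(rep$best, best[c("a", "b", "nu", "mu")])
  expect_equal(rep$mean_f1, best$f1)
})
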