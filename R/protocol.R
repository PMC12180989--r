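#' Fit the anomaly-detection model for one site
#'
#' Runs the full training protocol on an engineered site cohort:
#' `n_holdout` records per technique are removed to serve as unseen normal
#' test records; each technique partition of the remainder becomes that
#' technique's historical database; per technique, a labeled training set
#' (sampled in-database normal records plus freshly simulated anomalies per
#' run) drives the grid search that selects `(a, b, nu, mu)` by maximum
#' detection F1; thresholds are then `t_Rx = a*theta`, `t_F = b*tau` with
#' `tau`/`theta` the database's mean pairwise distances.
#'
#' @param cohort An engineered site cohort (see [engineer_cohort()]).
#' @param grid Calibration grid, see [default_grid()].
#' @param runs Grid-search runs with fresh anomaly draws (50 gives the
#'   conventional mean +/- SD training report; smaller values are faster).
#' @param seed Master seed for the split, normal sampling and per-run
#'   anomaly draws.
#' @param n_holdout Held-out normal test records per technique.
#' @param n_train_normals In-database normal records labeled for training,
#'   per technique.
#' @param n_train_rx,n_train_feature Simulated training anomalies of each
#'   type, per technique, per run (defaults give the 60 training anomalies
#'   of the standard protocol; 15 + 15 reproduces the lighter 30-anomaly
#'   variant).
#' @param spec An [anomaly_spec()].
#' @param gower_weights Optional named feature weights.
#' @return An `rx_model` object: `params` (one [model_params()] row per
#'   technique), `cohorts` (per-technique historical databases), `holdout`
#'   (unseen normals), `reports` (per-technique `rx_train_report`s).
#' @export
fit_rx_model <- function(cohort, grid = default_grid(), runs = 10, seed = 1,
                         n_holdout = 20, n_train_normals = 40,
                         n_train_rx = 30, n_train_feature = 30,
                         spec = anomaly_spec(), gower_weights = NULL) {
  site <- cohort$site[1]
  split <- split_holdout(cohort, n_holdout, seed = seed)
  parts <- partition_by_technique(split$train)

  params <- list()
  reports <- list()
  for (tech in names(parts)) {
    part <- parts[[tech]]
    normals <- withr::with_seed(seed + 1000 + match(tech, names(parts)), {
      part[sample.int(nrow(part), n_train_normals), ]
    })
    gen <- function(s) {
      withr::with_seed(s, {
        .technique_anomalies(part, split$train, n_train_rx, n_train_feature, spec)
      })
    }
    report <- train_grid_search(part, gen, normals, grid = grid, runs = runs,
                                seed = seed, gower_weights = gower_weights)
    params[[tech]] <- model_params(site, tech, report$best$a, report$best$b,
                                   report$best$nu, report$best$mu,
                                   report$tau, report$theta)
    reports[[tech]] <- report
  }
  structure(
    list(site = site, params = bind_rows(params), cohorts = parts,
         holdout = split$holdout, reports = reports, seed = seed,
         anomaly_spec = spec, gower_weights = gower_weights,
         config = engineering_config()),
    class = "rx_model"
  )
}

#' @export
print.rx_model <- function(x, ...) {
  cat("rxguard model for site '", x$site, "'\n", sep = "")
  print(as.data.frame(x$params), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Build the standard labeled test set for a fitted model
#'
#' Per technique: the model's held-out normal records (truth 0) plus
#' `n_rx` simulated prescription anomalies and `n_feature` simulated
#' feature anomalies (truth 1) drawn from the training databases — the
#' 20 + 20 + 20 testing protocol by default.
#'
#' @param model A fitted [fit_rx_model()] object.
#' @param n_rx,n_feature Simulated anomalies of each type per technique.
#' @param seed Integer seed.
#' @return A labeled tibble ready for [evaluate()].
#' @export
make_test_set <- function(model, n_rx = 20, n_feature = 20, seed = 1) {
  train <- bind_rows(model$cohorts)
  anoms <- withr::with_seed(seed, {
    bind_rows(lapply(names(model$cohorts), function(tech) {
      .technique_anomalies(model$cohorts[[tech]], train, n_rx, n_feature,
                           model$anomaly_spec)
    }))
  })
  normals <- bind_rows(lapply(names(model$cohorts), function(tech) {
    h <- model$holdout[model$holdout$technique == tech, ]
    h <- apply_icd_weights(h[setdiff(names(h), "icd_weight")],
                           reference = model$cohorts[[tech]])
    h$truth <- 0L
    h$type <- 0L
    h
  }))
  bind_rows(normals, anoms)
}

#' Run the full two-site validation study on synthetic cohorts
#'
#' Generates a cohort per site specification, engineers it, fits the model
#' (holdout split, per-technique grid search), builds the standard
#' 20 normals + 20 Rx anomalies + 20 feature anomalies test set per
#' technique, and evaluates. The pooled chi-squared agreement test is
#' computed over all test records of all sites, mirroring the published
#' two-row contingency construction.
#'
#' @param specs Named list of [cohort_spec()]s (default [default_specs()]).
#' @param seed Master seed; site cohorts, splits and draws derive from it.
#' @param grid,runs Passed to [fit_rx_model()].
#' @param ... Further arguments for [fit_rx_model()].
#' @return An `rx_validation_study` list: `models`, `evaluations`,
#'   `by_technique` tibble (site, technique, F1, confusion counts) and the
#'   pooled `chi_square`.
#' @export
run_validation_study <- function(specs = default_specs(), seed = 1,
                                 grid = default_grid(), runs = 10, ...) {
  models <- list()
  evals <- list()
  for (i in seq_along(specs)) {
    site <- names(specs)[i]
    cohort <- engineer_cohort(generate_cohort(specs[[i]], seed = seed + i))
    model <- fit_rx_model(cohort, grid = grid, runs = runs, seed = seed + i, ...)
    test <- make_test_set(model, seed = seed + 100 + i)
    models[[site]] <- model
    evals[[site]] <- evaluate(model, test)
  }
  by_tech <- bind_rows(lapply(names(evals), function(site) {
    out <- evals[[site]]$by_technique
    out$site <- site
    out[c("site", setdiff(names(out), "site"))]
  }))
  all_res <- bind_rows(lapply(evals, function(e) e$results))
  chi <- chi_square_validation(
    n_true_anomaly = sum(all_res$truth == 1),
    n_true_normal = sum(all_res$truth == 0),
    n_pred_anomaly = sum(all_res$prediction > 0),
    n_pred_normal = sum(all_res$prediction == 0)
  )
  structure(
    list(models = models, evaluations = evals, by_technique = by_tech,
         chi_square = chi, seed = seed),
    class = "rx_validation_study"
  )
}

#' @export
print.rx_validation_study <- function(x, ...) {
  cat("Two-site validation study (seed ", x$seed, ")\n", sep = "")
  print(as.data.frame(x$by_technique), row.names = FALSE, digits = 3)
  cat(sprintf("pooled chi-squared = %.3f (critical %.2f) -> %s\n",
              x$chi_square$statistic, x$chi_square$critical_value,
              x$chi_square$decision))
  invisible(x)
}

# Detection F1 of fixed params on a labeled set against a cohort.
.eval_f1 <- function(test, cohort, params, gower_weights = NULL) {
  preds <- vapply(seq_len(nrow(test)), function(i) {
    classify(test[i, ], cohort, params, gower_weights)$prediction
  }, 0L)
  f1_score(tp = sum(preds > 0 & test$truth == 1),
           fp = sum(preds > 0 & test$truth == 0),
           fn = sum(preds == 0 & test$truth == 1))
}

#' Compare linearly scaled against unscaled training under secular drift
#'
#' Proof-of-concept experiment for incremental learning: on a cohort with an
#' injected secular shift (see [drifted_thoracic_spec()]: complete beam-energy
#' conversion, regimens retiring and appearing mid-2010s), one technique's
#' model is calibrated twice — once on the raw historical database and once
#' after [linear_scale()] upweighting of recent records — and both are
#' evaluated on a recent-era test set: held-out normals from the last
#' `recent_years` years plus anomalies simulated from recent-era base
#' records, with rarity measured against recent practice (so that, e.g., a
#' retired beam energy on a modern regimen counts as anomalous). Repeated
#' over seeds, reporting both detection F1 values per seed.
#'
#' @param spec A [cohort_spec()] with secular drift.
#' @param technique Technique under study (default `"IMRT"`).
#' @param seeds Integer seeds, one experiment per seed.
#' @param recent_years Width of the recent era in years.
#' @param grid,runs Grid-search settings (a reduced grid keeps the repeated
#'   experiment fast).
#' @param n_holdout,n_train_normals,n_train_rx,n_train_feature,n_test_rx,n_test_feature
#'   Protocol sizes.
#' @param anomaly_spec An [anomaly_spec()].
#' @return A tibble `seed, f1_unscaled, f1_scaled`.
#' @export
incremental_comparison <- function(spec = drifted_thoracic_spec(),
                                   technique = "IMRT", seeds = 1:10,
                                   recent_years = 4,
                                   grid = default_grid(8), runs = 3,
                                   n_holdout = 20, n_train_normals = 40,
                                   n_train_rx = 30, n_train_feature = 30,
                                   n_test_rx = 20, n_test_feature = 20,
                                   anomaly_spec = rxguard::anomaly_spec()) {
  out <- lapply(seeds, function(s) {
    cohort <- engineer_cohort(generate_cohort(spec, seed = s))
    part <- partition_by_technique(cohort)[[technique]]
    year <- as.integer(format(part$start_date, "%Y"))
    recent_ids <- part$record_id[year > max(year) - recent_years]
    if (length(recent_ids) <= n_holdout) abort("recent era too small for the holdout")
    hold_ids <- withr::with_seed(s, sample(recent_ids, n_holdout))
    train_part <- part[!part$record_id %in% hold_ids, ]
    site_train <- cohort[!cohort$record_id %in% hold_ids, ]
    recent_train <- train_part[as.integer(format(train_part$start_date, "%Y")) >
                                 max(year) - recent_years, ]

    test_anoms <- withr::with_seed(s + 700, {
      .technique_anomalies(recent_train, site_train, n_test_rx, n_test_feature,
                           anomaly_spec, weight_reference = train_part)
    })
    holdout <- apply_icd_weights(
      part[part$record_id %in% hold_ids, setdiff(names(part), "icd_weight")],
      reference = train_part
    )
    holdout$truth <- 0L
    holdout$type <- 0L
    test <- bind_rows(holdout, test_anoms)

    # Both models calibrate against the records they are about to screen:
    # training normals come from the recent era (identically for both), while
    # anomaly base records are drawn weight-proportionally from each model's
    # effective database.
    normals <- withr::with_seed(s + 500, {
      recent_train[sample.int(nrow(recent_train), n_train_normals,
                              replace = nrow(recent_train) < n_train_normals), ]
    })
    fit_one <- function(db) {
      gen <- function(rs) withr::with_seed(rs, {
        .technique_anomalies(db, site_train, n_train_rx, n_train_feature,
                             anomaly_spec, weight_reference = db)
      })
      rep <- train_grid_search(db, gen, normals, grid = grid, runs = runs, seed = s)
      model_params(spec$site, technique, rep$best$a, rep$best$b,
                   rep$best$nu, rep$best$mu, rep$tau, rep$theta)
    }
    scaled_db <- linear_scale(train_part, bin_years = 2)
    p_raw <- fit_one(train_part)
    p_scaled <- fit_one(scaled_db)
    tibble(
      seed = s,
      f1_unscaled = .eval_f1(test, train_part, p_raw),
      f1_scaled = .eval_f1(
        apply_icd_weights(test[setdiff(names(test), "icd_weight")],
                          reference = scaled_db),
        scaled_db, p_scaled)
    )
  })
  bind_rows(out)
}
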