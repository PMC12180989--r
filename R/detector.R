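#' Flagging thresholds from the optimisation parameters
#'
#' The two flagging thresholds are proportional to the cohort's mean
#' pairwise distances: `t_Rx = a * theta` (prescription threshold) and
#' `t_F = b * tau` (feature threshold). The alternative pairing
#' (`a -> t_F`, `b -> t_Rx`) is available as `pairing = "footnote"`.
#'
#' @param a,b Positive optimisation parameters.
#' @param tau Mean pairwise feature (Gower) distance of the cohort.
#' @param theta Mean pairwise prescription distance of the cohort.
#' @param pairing `"rx_theta"` (default: `t_Rx = a*theta`, `t_F = b*tau`) or
#'   `"footnote"` (swapped).
#' @return A list with `t_rx` and `t_f`.
#' @export
compute_thresholds <- function(a, b, tau, theta,
                               pairing = c("rx_theta", "footnote")) {
  pairing <- arg_match(pairing)
  if (any(c(a, b) <= 0) || tau < 0 || theta < 0) {
    abort("a and b must be positive; tau and theta non-negative")
  }
  if (pairing == "rx_theta") list(t_rx = a * theta, t_f = b * tau)
  else list(t_rx = b * theta, t_f = a * tau)
}

#' Calibrated model parameters for one technique
#'
#' @param site,technique Labels of the historical database the parameters
#'   were calibrated on.
#' @param a,b Threshold multipliers.
#' @param nu,mu Neighbourhood fractions for the R and F statistics.
#' @param tau,theta Cached mean pairwise distances of that database.
#' @param pairing Threshold pairing passed to [compute_thresholds()].
#' @return A one-row `model_params` tibble including the derived thresholds
#'   `t_rx` and `t_f`.
#' @export
model_params <- function(site, technique, a, b, nu, mu, tau, theta,
                         pairing = "rx_theta") {
  thr <- compute_thresholds(a, b, tau, theta, pairing)
  out <- tibble(site = site, technique = technique, a = a, b = b,
                nu = nu, mu = mu, tau = tau, theta = theta,
                t_rx = thr$t_rx, t_f = thr$t_f)
  class(out) <- c("model_params", class(out))
  out
}

#' Classify one record against a historical database
#'
#' Computes the R statistic first: if `R > t_Rx` the record is flagged as a
#' *prescription anomaly* (prediction 1) and F is not evaluated. Otherwise F
#' is computed: `F > t_F` flags a *feature anomaly* (prediction 2), else the
#' record is normal (prediction 0). Flags use strict inequality; equality
#' with a threshold is not flagged. The result also reports how many
#' effective historical records share the exact prescription, which is the
#' explanation reviewers see.
#'
#' @param new A single prepared record (one-row tibble, see
#'   [prepare_queries()]).
#' @param cohort The engineered historical cohort for the record's
#'   technique.
#' @param params A [model_params()] row for the same technique.
#' @param gower_weights Optional named feature weights.
#' @return A one-row tibble: `record_id`, `technique`, `r`, `t_rx`, `f`
#'   (`NA` when not evaluated), `t_f`, `prediction` (0/1/2),
#'   `n_rx_matches_in_db`.
#' @export
classify <- function(new, cohort, params, gower_weights = NULL) {
  if (nrow(cohort) == 0) abort("empty cohort")
  if (!identical(new$technique, params$technique)) {
    abort(paste0("record technique '", new$technique,
                 "' does not match params technique '", params$technique, "'"))
  }
  ranges <- rx_ranges(cohort)
  prof <- .query_profile(new, cohort, ranges, gower_weights)
  s_eff <- sum(cohort$replication_weight)
  r <- .knn_mean(prof$cum_rx, prof$cw, prof$gd, .neighbour_count(params$nu, s_eff))
  match_n <- sum(cohort$replication_weight[
    cohort$dose_per_fraction_cgy == new$dose_per_fraction_cgy &
      cohort$n_fractions == new$n_fractions])
  if (r > params$t_rx) {
    f <- NA_real_
    pred <- 1L
  } else {
    f <- .knn_mean(prof$cum_gw, prof$cw, prof$g_gw_mean, .neighbour_count(params$mu, s_eff))
    pred <- if (f > params$t_f) 2L else 0L
  }
  tibble(record_id = new$record_id, technique = new$technique,
         r = r, t_rx = params$t_rx, f = f, t_f = params$t_f,
         prediction = pred, n_rx_matches_in_db = match_n)
}

#' Screen a table of new records with a fitted model
#'
#' Vectorised [classify()]: each record is routed to its technique's
#' historical database and calibrated parameters.
#'
#' @param new_data Prepared records (tibble). Records are prepared against
#'   each technique cohort with [prepare_queries()] unless they already
#'   carry an `icd_weight` column.
#' @param model A fitted [fit_rx_model()] object.
#' @return A tibble of per-record detection results in input order.
#' @export
detect_anomalies <- function(new_data, model) {
  out <- vector("list", nrow(new_data))
  for (i in seq_len(nrow(new_data))) {
    rec <- new_data[i, ]
    tech <- rec$technique
    cohort <- model$cohorts[[tech]]
    if (is.null(cohort)) abort(paste0("model has no technique '", tech, "'"))
    if (!"icd_weight" %in% names(rec) || is.na(rec$icd_weight)) {
      rec <- prepare_queries(rec[setdiff(names(rec), "icd_weight")], cohort, model$config)
    }
    out[[i]] <- classify(rec, cohort, model$params[model$params$technique == tech, ],
                         model$gower_weights)
  }
  bind_rows(out)
}

#' Detection-level F1 score
#'
#' Harmonic mean of precision and recall with *anomaly of either type* as
#' the positive class: `2 tp / (2 tp + fp + fn)`. Whether the anomaly
#' subtype was identified correctly does not enter this score (subtype
#' agreement is reported separately by [confusion()]).
#'
#' @param tp,fp,fn Non-negative counts (not all zero).
#' @return Numeric in \[0, 1\].
#' @export
f1_score <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) abort("counts must be non-negative")
  if (tp + fp + fn == 0) abort("F1 undefined when tp = fp = fn = 0")
  2 * tp / (2 * tp + fp + fn)
}

#' Hold out normal test records per technique
#'
#' Removes `n_per_technique` records (default 20) from each technique
#' partition, uniformly at random without replacement, to serve as unseen
#' normal records during testing; the remainder is the training cohort.
#'
#' @param cohort An engineered cohort tibble.
#' @param n_per_technique Records to hold out per technique.
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return A list with `train` and `holdout` tibbles; their union is the
#'   input cohort and they are disjoint.
#' @export
split_holdout <- function(cohort, n_per_technique = 20, seed = 1) {
  parts <- partition_by_technique(cohort)
  small <- names(parts)[vapply(parts, nrow, 0L) <= n_per_technique]
  if (length(small) > 0) {
    abort(paste0("technique partition(s) too small to hold out ",
                 n_per_technique, " records: ", paste(small, collapse = ", ")))
  }
  withr::with_seed(seed, {
    hold_ids <- unlist(lapply(parts, function(p) {
      sample(p$record_id, n_per_technique)
    }), use.names = FALSE)
  })
  list(
    train = cohort[!cohort$record_id %in% hold_ids, , drop = FALSE],
    holdout = cohort[cohort$record_id %in% hold_ids, , drop = FALSE]
  )
}

#' Default calibration grid
#'
#' Threshold multipliers `a`, `b` on a 12-point log-spaced grid over
#' \[0.01, 1.2\]; neighbourhood fractions `nu`, `mu` over
#' \{0.005, 0.01, 0.02, 0.03, 0.05\}.
#'
#' @param n_ab Number of log-spaced `a`/`b` points.
#' @return A list with components `a`, `b`, `nu`, `mu`.
#' @export
default_grid <- function(n_ab = 12) {
  ab <- exp(seq(log(0.01), log(1.2), length.out = n_ab))
  list(a = ab, b = ab, nu = c(0.005, 0.01, 0.02, 0.03, 0.05),
       mu = c(0.005, 0.01, 0.02, 0.03, 0.05))
}

# F1 over the whole (a, b) grid for fixed per-record R and F vectors, via
# complement-indicator cross products: a record is predicted anomalous iff
# R > a*theta or F > b*tau.
.grid_f1_ab <- function(r, f, truth, a_vals, b_vals, tau, theta) {
  not_r <- outer(r, a_vals * theta, "<=") * 1   # n x n_a
  not_f <- outer(f, b_vals * tau, "<=") * 1     # n x n_b
  pos <- truth == 1
  miss <- crossprod(not_r[pos, , drop = FALSE], not_f[pos, , drop = FALSE])
  fp <- sum(!pos) - crossprod(not_r[!pos, , drop = FALSE], not_f[!pos, , drop = FALSE])
  tp <- sum(pos) - miss
  2 * tp / (2 * tp + fp + miss)                 # n_a x n_b matrix
}

#' Grid-search calibration maximising detection F1
#'
#' Evaluates every grid point `(a, b, nu, mu)` on a labeled set of simulated
#' anomalies and normal records and keeps the F1 maximiser. The search is
#' repeated over `runs` runs with a fresh seeded anomaly draw each run (when
#' `anomalies` is a generator function); the returned parameters are the
#' per-run maximisers' consensus (modal grid point, ties resolved by the
#' highest mean F1 across runs, then by grid order) and the report carries
#' the mean and standard deviation of the per-run best F1.
#'
#' @param cohort The engineered historical cohort for one technique.
#' @param anomalies Labeled anomalous records (tibble with a `truth` column
#'   equal to 1), or a `function(seed)` returning such a tibble for per-run
#'   draws.
#' @param normals Labeled normal records (`truth` 0).
#' @param grid A [default_grid()]-shaped list.
#' @param runs Number of repeated runs (the reported mean/SD are over
#'   exactly this many).
#' @param seed Master seed; run `i` uses `seed + i - 1`.
#' @param gower_weights Optional named feature weights.
#' @return An `rx_train_report` list: `best` (a, b, nu, mu), `mean_f1`,
#'   `sd_f1`, `runs`, `per_run` tibble, `grid_mean` tibble of mean F1 per
#'   grid point, and the cached `tau`/`theta`.
#' @export
train_grid_search <- function(cohort, anomalies, normals, grid = default_grid(),
                              runs = 1, seed = 1, gower_weights = NULL) {
  if (length(grid$a) == 0 || length(grid$b) == 0 ||
      length(grid$nu) == 0 || length(grid$mu) == 0) {
    abort("calibration grid must be nonempty in every dimension")
  }
  ranges <- rx_ranges(cohort)
  s_eff <- sum(cohort$replication_weight)
  mp <- mean_pairwise(cohort, gower_weights)
  numu <- expand.grid(nu = grid$nu, mu = grid$mu, KEEP.OUT.ATTRS = FALSE)
  n_ab <- length(grid$a) * length(grid$b)
  n_points <- n_ab * nrow(numu)

  static_anoms <- if (!is.function(anomalies)) {
    if (nrow(anomalies) == 0) abort("labeled anomaly set is empty")
    anomalies
  }
  if (nrow(normals) == 0) abort("labeled normal set is empty")

  profile_rf <- function(records) {
    profs <- lapply(seq_len(nrow(records)), function(i) {
      .query_profile(records[i, ], cohort, ranges, gower_weights)
    })
    rf <- lapply(seq_len(nrow(numu)), function(g) {
      k_r <- .neighbour_count(numu$nu[g], s_eff)
      k_f <- .neighbour_count(numu$mu[g], s_eff)
      list(
        r = vapply(profs, function(p) .knn_mean(p$cum_rx, p$cw, p$gd, k_r), 0),
        f = vapply(profs, function(p) .knn_mean(p$cum_gw, p$cw, p$g_gw_mean, k_f), 0)
      )
    })
    rf
  }
  rf_norm <- profile_rf(normals)

  f1_sum <- numeric(n_points)
  per_run <- vector("list", runs)
  for (run in seq_len(runs)) {
    run_seed <- seed + run - 1
    anoms <- if (is.function(anomalies)) anomalies(run_seed) else static_anoms
    rf_anom <- profile_rf(anoms)
    truth <- c(rep(0L, nrow(normals)), rep(1L, nrow(anoms)))
    f1_run <- numeric(n_points)
    for (g in seq_len(nrow(numu))) {
      r <- c(rf_norm[[g]]$r, rf_anom[[g]]$r)
      f <- c(rf_norm[[g]]$f, rf_anom[[g]]$f)
      f1_mat <- .grid_f1_ab(r, f, truth, grid$a, grid$b, mp$tau, mp$theta)
      f1_run[(g - 1) * n_ab + seq_len(n_ab)] <- as.numeric(f1_mat)
    }
    f1_sum <- f1_sum + f1_run
    best_idx <- which.max(f1_run)
    per_run[[run]] <- tibble(run = run, seed = run_seed, point = best_idx,
                             f1 = f1_run[best_idx])
  }
  per_run <- bind_rows(per_run)

  point_params <- function(idx) {
    g <- (idx - 1) %/% n_ab + 1
    ab <- (idx - 1) %% n_ab
    list(a = grid$a[ab %% length(grid$a) + 1],
         b = grid$b[ab %/% length(grid$a) + 1],
         nu = numu$nu[g], mu = numu$mu[g])
  }
  counts <- table(per_run$point)
  modal <- as.integer(names(counts)[counts == max(counts)])
  best_point <- modal[order(-f1_sum[modal], modal)][1]
  best <- point_params(best_point)

  pp <- lapply(per_run$point, point_params)
  per_run$a <- vapply(pp, `[[`, 0, "a")
  per_run$b <- vapply(pp, `[[`, 0, "b")
  per_run$nu <- vapply(pp, `[[`, 0, "nu")
  per_run$mu <- vapply(pp, `[[`, 0, "mu")

  structure(
    list(
      best = best,
      mean_f1 = mean(per_run$f1),
      sd_f1 = if (runs > 1) sd(per_run$f1) else 0,
      runs = runs,
      seed = seed,
      per_run = per_run[c("run", "seed", "a", "b", "nu", "mu", "f1")],
      mean_f1_by_point = f1_sum / runs,
      tau = mp$tau, theta = mp$theta,
      grid = grid
    ),
    class = "rx_train_report"
  )
}

#' @export
print.rx_train_report <- function(x, ...) {
  cat("Grid-search calibration (", x$runs, " run(s))\n", sep = "")
  cat(sprintf("  best: a = %.4g, b = %.4g, nu = %.3g, mu = %.3g\n",
              x$best$a, x$best$b, x$best$nu, x$best$mu))
  cat(sprintf("  training F1 = %.3f +/- %.3f; tau = %.3f, theta = %.3f\n",
              x$mean_f1, x$sd_f1, x$tau, x$theta))
  invisible(x)
}
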