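#' Detection confusion counts and subtype breakdown
#'
#' Detection-level counts treat an anomaly of either type as the positive
#' class (a type-1 truth caught as a type-2 flag is still a true positive);
#' subtype agreement is reported separately as a 3x3 matrix of truth type
#' versus predicted type.
#'
#' @param results A detection-result tibble from [detect_anomalies()].
#' @param truths A tibble with `record_id`, `truth` (0/1) and optionally
#'   `type` (0/1/2), aligned by `record_id`.
#' @return A list: `tp`, `fp`, `fn`, `tn`, and `subtype` (3x3 table).
#' @export
confusion <- function(results, truths) {
  m <- match(results$record_id, truths$record_id)
  if (anyNA(m)) abort("results contain record_ids absent from truths")
  truth <- truths$truth[m]
  truth_type <- if ("type" %in% names(truths)) truths$type[m] else truth
  pred_pos <- results$prediction > 0
  lev <- 0:2
  list(
    tp = sum(pred_pos & truth == 1),
    fp = sum(pred_pos & truth == 0),
    fn = sum(!pred_pos & truth == 1),
    tn = sum(!pred_pos & truth == 0),
    subtype = table(truth = factor(truth_type, levels = lev),
                    prediction = factor(results$prediction, levels = lev))
  )
}

#' Chi-squared agreement test of model output versus ground truth
#'
#' Builds the 2x2 contingency table with ground truth and model prediction
#' as its two rows and (anomaly, normal) as its columns, and computes the
#' Pearson chi-squared statistic without continuity correction from the
#' closed form `sum((O - E)^2 / E)` with expected counts from the margins.
#' The null hypothesis — the model's predictions are not significantly
#' different from the ground truth — is *retained* iff the statistic is
#' strictly below the df = 1 critical value at `alpha`.
#'
#' @param n_true_anomaly,n_true_normal Ground-truth row counts.
#' @param n_pred_anomaly,n_pred_normal Model-prediction row counts; row
#'   totals must match the ground-truth row.
#' @param alpha Significance level (default 0.05).
#' @return A list: `statistic`, `df` (1), `critical_value`, `p_value`,
#'   `decision` (`"retain null"` / `"reject null"`) and the observed
#'   `table`.
#' @export
chi_square_validation <- function(n_true_anomaly, n_true_normal,
                                  n_pred_anomaly, n_pred_normal,
                                  alpha = 0.05) {
  obs <- matrix(c(n_true_anomaly, n_true_normal, n_pred_anomaly, n_pred_normal),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("ground_truth", "model_prediction"),
                                c("anomaly", "normal")))
  if (any(obs < 0)) abort("counts must be non-negative")
  if (sum(obs[1, ]) != sum(obs[2, ])) {
    abort("ground-truth and model-prediction rows must total the same number of records")
  }
  if (any(rowSums(obs) == 0) || any(colSums(obs) == 0)) {
    abort("contingency table has a zero margin")
  }
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  statistic <- sum((obs - expected)^2 / expected)
  critical <- qchisq(1 - alpha, df = 1)
  list(
    statistic = statistic, df = 1,
    critical_value = critical,
    p_value = pchisq(statistic, df = 1, lower.tail = FALSE),
    decision = if (statistic < critical) "retain null" else "reject null",
    table = obs
  )
}

#' Evaluate a fitted model on a labeled test set
#'
#' Screens every test record, then aggregates per technique (detection F1
#' and confusion counts) and over the whole set (pooled confusion, pooled
#' F1, and the chi-squared agreement test of predicted versus true
#' anomaly/normal totals).
#'
#' @param model A fitted [fit_rx_model()] object.
#' @param test_set Labeled records: cohort columns plus `truth` (0/1) and
#'   optionally `type`.
#' @return An `rx_evaluation` list: `results` (per-record detections joined
#'   with truth), `by_technique` tibble, `pooled` confusion list,
#'   `f1`, and `chi_square`.
#' @export
evaluate <- function(model, test_set) {
  missing_tech <- setdiff(unique(test_set$technique), names(model$cohorts))
  if (length(missing_tech) > 0) {
    abort(paste0("test set contains technique(s) absent from the model: ",
                 paste(missing_tech, collapse = ", ")))
  }
  res <- detect_anomalies(test_set, model)
  truths <- test_set[c("record_id", "technique")]
  truths$truth <- test_set$truth
  truths$type <- if ("type" %in% names(test_set)) test_set$type else test_set$truth
  by_tech <- lapply(split(seq_len(nrow(res)), res$technique), function(idx) {
    cm <- confusion(res[idx, ], truths[idx, ])
    tibble(technique = res$technique[idx[1]], n = length(idx),
           tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
           f1 = f1_score(cm$tp, cm$fp, cm$fn))
  })
  pooled <- confusion(res, truths)
  chi <- chi_square_validation(
    n_true_anomaly = sum(truths$truth == 1),
    n_true_normal = sum(truths$truth == 0),
    n_pred_anomaly = sum(res$prediction > 0),
    n_pred_normal = sum(res$prediction == 0)
  )
  results <- res
  results$truth <- truths$truth[match(res$record_id, truths$record_id)]
  results$type <- truths$type[match(res$record_id, truths$record_id)]
  structure(
    list(results = results, by_technique = bind_rows(by_tech),
         pooled = pooled, f1 = f1_score(pooled$tp, pooled$fp, pooled$fn),
         chi_square = chi),
    class = "rx_evaluation"
  )
}

#' @export
print.rx_evaluation <- function(x, ...) {
  cat("Detection evaluation on", nrow(x$results), "records\n")
  print(as.data.frame(x$by_technique), row.names = FALSE)
  cat(sprintf("pooled F1 = %.3f; chi-squared = %.3f (critical %.2f) -> %s\n",
              x$f1, x$chi_square$statistic, x$chi_square$critical_value,
              x$chi_square$decision))
  invisible(x)
}

#' Export a review sheet for peer-review chart rounds
#'
#' Writes one row per screened record with its prescription, clinical
#' features, the R and F statistics against their thresholds, the flag
#' type, and how many historical records share the exact prescription — the
#' explanation a reviewing physician sees. `F` prints as `"--"` on
#' prescription-anomaly rows, where it is not evaluated.
#'
#' @param results Detection results from [detect_anomalies()].
#' @param records The screened records (for the feature columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_review_sheet <- function(results, records, path) {
  m <- match(results$record_id, records$record_id)
  sheet <- tibble(
    record_id = results$record_id,
    n_fractions = records$n_fractions[m],
    dose_per_fraction_cgy = records$dose_per_fraction_cgy[m],
    technique = results$technique,
    energy = records$energy[m],
    rx_isodose_line_pct = records$rx_isodose_line_pct[m],
    intent = records$intent[m],
    diagnostic_code = records$diagnostic_code[m],
    age_group = records$age_group[m],
    prediction = results$prediction,
    type = ifelse(results$prediction > 0, results$prediction, 0L),
    r = results$r,
    t_rx = results$t_rx,
    f = ifelse(is.na(results$f), "--", format(results$f, trim = TRUE)),
    t_f = results$t_f,
    n_records_in_db = results$n_rx_matches_in_db
  )
  readr::write_csv(sheet, path, na = "", progress = FALSE)
  invisible(path)
}

#' McNemar test on paired model/truth outcomes (extension)
#'
#' The primary validation compares ground truth and model prediction as two
#' independent rows of one contingency table ([chi_square_validation()]).
#' Because the 360 outcomes are actually paired per record, a McNemar test
#' on the discordant pairs is also offered, clearly labeled as an
#' extension, not part of the published construction.
#'
#' @param results Detection results joined with truth (as in
#'   `evaluate()$results`).
#' @return A list: `statistic`, `df`, `p_value`, and the paired 2x2 table.
#' @export
mcnemar_validation <- function(results) {
  tab <- table(truth = results$truth > 0, predicted = results$prediction > 0)
  b <- tab["TRUE", "FALSE"]
  c_ <- tab["FALSE", "TRUE"]
  statistic <- if (b + c_ == 0) 0 else (b - c_)^2 / (b + c_)
  list(statistic = statistic, df = 1,
       p_value = pchisq(statistic, 1, lower.tail = FALSE), table = tab)
}
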