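#' Tidy a fitted model into its per-technique parameter table
#'
#' @param x An `rx_model`.
#' @param ... Unused.
#' @return A tibble with one row per technique: `a`, `b`, `nu`, `mu`,
#'   `tau`, `theta`, `t_rx`, `t_f`, plus the training mean/SD F1.
#' @export
tidy.rx_model <- function(x, ...) {
  params <- as_tibble(x$params)
  params$train_f1_mean <- vapply(x$reports[params$technique], function(r) r$mean_f1, 0)
  params$train_f1_sd <- vapply(x$reports[params$technique], function(r) r$sd_f1, 0)
  params
}

#' @rdname tidy.rx_model
#' @export
glance.rx_model <- function(x, ...) {
  tibble(
    site = x$site,
    n_techniques = nrow(x$params),
    n_records = sum(vapply(x$cohorts, nrow, 0L)),
    n_holdout = nrow(x$holdout),
    train_f1_mean = mean(vapply(x$reports, function(r) r$mean_f1, 0))
  )
}

#' Tidy a grid-search report into its per-run results
#'
#' @param x An `rx_train_report`.
#' @param ... Unused.
#' @return The per-run tibble (`run`, `seed`, `a`, `b`, `nu`, `mu`, `f1`).
#' @export
tidy.rx_train_report <- function(x, ...) x$per_run

#' @rdname tidy.rx_train_report
#' @export
glance.rx_train_report <- function(x, ...) {
  tibble(a = x$best$a, b = x$best$b, nu = x$best$nu, mu = x$best$mu,
         mean_f1 = x$mean_f1, sd_f1 = x$sd_f1, runs = x$runs,
         tau = x$tau, theta = x$theta)
}

#' Tidy an evaluation into per-technique detection performance
#'
#' @param x An `rx_evaluation`.
#' @param ... Unused.
#' @return The per-technique tibble of confusion counts and F1.
#' @export
tidy.rx_evaluation <- function(x, ...) x$by_technique

#' @rdname tidy.rx_evaluation
#' @export
glance.rx_evaluation <- function(x, ...) {
  tibble(
    n = nrow(x$results), f1 = x$f1,
    tp = x$pooled$tp, fp = x$pooled$fp, fn = x$pooled$fn, tn = x$pooled$tn,
    chi_square = x$chi_square$statistic,
    chi_critical = x$chi_square$critical_value,
    decision = x$chi_square$decision
  )
}

#' Plot detection results in the (R, F) plane
#'
#' Each screened record is placed at its prescription distance R (x axis)
#' and feature distance F (y axis; prescription anomalies, where F is not
#' evaluated, are drawn at F = 0 with an open shape), with the calibrated
#' thresholds as dashed lines, faceted by technique.
#'
#' @param object An `rx_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rx_evaluation <- function(object, ...) {
  df <- object$results
  df$f_plot <- ifelse(is.na(df$f), 0, df$f)
  df$evaluated_f <- !is.na(df$f)
  df$outcome <- dplyr::case_when(
    df$prediction > 0 & df$truth == 1 ~ "true positive",
    df$prediction > 0 & df$truth == 0 ~ "false positive",
    df$prediction == 0 & df$truth == 1 ~ "false negative",
    TRUE ~ "true negative"
  )
  thresholds <- distinct(df, .data$technique, .data$t_rx, .data$t_f)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$f_plot)) +
    ggplot2::geom_vline(data = thresholds, ggplot2::aes(xintercept = .data$t_rx),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(data = thresholds, ggplot2::aes(yintercept = .data$t_f),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outcome,
                                     shape = .data$evaluated_f), alpha = 0.8) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                labels = c(`TRUE` = "yes", `FALSE` = "no (Rx anomaly)"),
                                name = "F evaluated") +
    ggplot2::facet_wrap(~technique, scales = "free_x") +
    ggplot2::labs(x = "prescription distance R", y = "feature distance F",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot secular technique and regimen usage trends
#'
#' @param trends Output of [usage_trends()].
#' @param panel `"technique"` for technique adoption, `"regimen"` for
#'   per-regimen counts.
#' @param top_regimens How many most-used regimens to show in the regimen
#'   panel.
#' @return A ggplot object.
#' @export
plot_usage_trends <- function(trends, panel = c("technique", "regimen"),
                              top_regimens = 6) {
  panel <- arg_match(panel)
  if (panel == "technique") {
    return(
      ggplot2::ggplot(trends$technique,
                      ggplot2::aes(.data$year, .data$n, colour = .data$technique)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "year", y = "records / year", colour = "technique") +
        ggplot2::theme_minimal()
    )
  }
  reg <- trends$regimen %>%
    mutate(regimen = paste0(.data$n_fractions, " x ",
                            .data$dose_per_fraction_cgy, " cGy"))
  keep <- reg %>%
    group_by(.data$regimen) %>%
    summarise(total = sum(.data$n), .groups = "drop") %>%
    arrange(dplyr::desc(.data$total)) %>%
    head(top_regimens) %>%
    pull("regimen")
  ggplot2::ggplot(filter(reg, .data$regimen %in% keep),
                  ggplot2::aes(.data$year, .data$n, colour = .data$regimen)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "year", y = "records / year", colour = "regimen") +
    ggplot2::theme_minimal()
}
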