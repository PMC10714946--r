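#' Plot a simulated concentration profile
#'
#' @param object A `concentration_profile`.
#' @param log_y Plot concentration on a log scale.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.concentration_profile <- function(object, log_y = FALSE, ...) {
  p <- ggplot(object, aes(x = .data$time_h, y = .data$conc_ng_per_ml)) +
    geom_line(colour = "#2166ac") +
    labs(
      x = "Time (h)", y = "Plasma concentration (ng/mL)",
      title = "Simulated tirzepatide plasma profile"
    ) +
    theme_minimal()
  if (log_y) p <- p + scale_y_log10()
  p
}

#' Predicted-vs-observed qualification plot
#'
#' Scatter of predicted against observed PK parameters on log-log axes with
#' the identity and two-fold acceptance lines.
#'
#' @param object A `validation_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.validation_report <- function(object, ...) {
  df <- object$per_study |> filter(!is.na(.data$fold_error))
  ggplot(df, aes(x = .data$observed, y = .data$predicted,
                 colour = .data$parameter)) +
    geom_abline(slope = 1, intercept = 0, linetype = 1) +
    geom_abline(slope = 1, intercept = log10(2), linetype = 2) +
    geom_abline(slope = 1, intercept = -log10(2), linetype = 2) +
    geom_point(size = 2) +
    scale_x_log10() +
    scale_y_log10() +
    labs(
      x = "Observed", y = "Predicted",
      title = "Model qualification: predicted vs observed PK parameters",
      subtitle = "dashed lines: two-fold acceptance window"
    ) +
    theme_minimal()
}

#' Dose-band exposure plot
#'
#' Population mean AUC_0-168h and Cmax per candidate dose against the adult
#' reference bands.
#'
#' @param object A `dose_recommendation`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dose_recommendation <- function(object, ...) {
  df <- object$per_dose |>
    tidyr::pivot_longer(
      c("mean_auc_0_168", "mean_cmax"),
      names_to = "metric", values_to = "value"
    ) |>
    mutate(metric = dplyr::recode(.data$metric,
      mean_auc_0_168 = "AUC[0-168h] (ng*h/mL)",
      mean_cmax = "Cmax (ng/mL)"
    ))
  band <- tibble(
    metric = c("AUC[0-168h] (ng*h/mL)", "Cmax (ng/mL)"),
    lo = c(object$ref$auc_0_168[[1]], object$ref$cmax[[1]]),
    hi = c(object$ref$auc_0_168[[2]], object$ref$cmax[[2]])
  )
  ggplot(df, aes(x = factor(.data$dose_mg), y = .data$value)) +
    geom_rect(
      data = band,
      aes(ymin = .data$lo, ymax = .data$hi),
      xmin = -Inf, xmax = Inf,
      inherit.aes = FALSE, alpha = 0.15, fill = "#4daf4a"
    ) +
    geom_col(aes(fill = .data$qualifies), width = 0.6) +
    facet_wrap(~ .data$metric, scales = "free_y") +
    scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b")) +
    labs(
      x = "Dose (mg)", y = NULL, fill = "Within adult range",
      title = "Population mean exposure vs adult reference range"
    ) +
    theme_minimal()
}
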