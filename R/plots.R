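#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Monte-Carlo convergence study
#'
#' Log-log plot of the corrected repeat-to-repeat uncertainty of the CI
#' width against the number of realisations, with the theoretical
#' `N^(-1/2)` Monte-Carlo convergence as a reference line.
#'
#' @param object a [convergence_study()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot convergence_table
#' @export
autoplot.convergence_table <- function(object, ...) {
  ref <- object$sd_width_corrected[object$n == max(object$n)] *
    sqrt(max(object$n) / object$n)
  df <- dplyr::mutate(object, ref = ref)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ref), linetype = "dotted",
                       colour = "blue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$sd_width_corrected)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "number of MC realisations",
                  y = "corrected sd of 95% CI width",
                  title = "MC convergence of the CI-width estimator") +
    ggplot2::theme_minimal()
}

#' Plot an information-criterion weight set
#'
#' @param object an [ic_weights()] result.
#' @param ... unused.
#' @return a ggplot bar chart of the normalized weights.
#' @method autoplot weight_set
#' @export
autoplot.weight_set <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      model = factor(.data$model, levels = .data$model))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = paste0(attr(object, "criterion"), " weight")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Excess risk versus dose for every fitted model
#'
#' Per-model dose-response curves at the reference ages with Monte-Carlo
#' CI ribbons, faceted by model, coloured by sex. EAR-family risks are
#' shown per 1e4 person-years.
#'
#' @param study a [run_study()] result.
#' @param family `"ERR"` or `"EAR"`.
#' @param mode `"variable"` or `"constant"` baseline.
#' @return a ggplot.
#' @export
plot_dose_response <- function(study, family = "ERR", mode = "variable") {
  stopifnot(inherits(study, "risk_study"))
  df <- study$curves
  df <- df[df$family == family & df$mode == mode &
             df$attained_age == study$config$reference_age, ]
  if (nrow(df) == 0) stop("no curves for this family/mode", call. = FALSE)
  scale <- if (family == "EAR") 1e4 else 1
  df <- dplyr::mutate(df, dplyr::across(c("estimate", "lo", "hi"), ~ .x * scale))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data$estimate,
                                   colour = .data$sex, fill = .data$sex)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "weighted colon dose (Gy)",
                  y = if (family == "EAR") "EAR per 10⁴ PYR" else "ERR") +
    ggplot2::theme_minimal()
}

#' Excess risk versus attained age for every fitted model
#'
#' @inheritParams plot_dose_response
#' @return a ggplot of the attained-age curves at the reference dose.
#' @export
plot_age_response <- function(study, family = "ERR", mode = "variable") {
  stopifnot(inherits(study, "risk_study"))
  df <- study$curves
  df <- df[df$family == family & df$mode == mode &
             df$dose == study$config$reference_dose, ]
  if (nrow(df) == 0) stop("no curves for this family/mode", call. = FALSE)
  scale <- if (family == "EAR") 1e4 else 1
  df <- dplyr::mutate(df, dplyr::across(c("estimate", "lo", "hi"), ~ .x * scale))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$attained_age, y = .data$estimate,
                                   colour = .data$sex, fill = .data$sex)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "attained age (years)",
                  y = if (family == "EAR") "EAR per 10⁴ PYR" else "ERR") +
    ggplot2::theme_minimal()
}
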