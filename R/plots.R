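#' Plot a ROC curve
#'
#' @param object A `roc_result` from [roc_auc()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a Kaplan–Meier curve
#'
#' @param object A `km_curve` from [km_estimate()].
#' @param ... Ignored.
#' @return A ggplot (step function of survival probability over time).
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(time = 0, survival = 1),
    tibble(time = object$time, survival = object$survival)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Kaplan–Meier curves for expression-positive vs negative patients
#'
#' Convenience plot mirroring a per-miRNA survival stratification: patients
#' are dichotomized at RPM >= 1 for one miRNA and each stratum's
#' product-limit curve is drawn.
#'
#' @param m An rpm-unit [mir_expr()].
#' @param surv Tibble with `sample_id`, `time`, `event`.
#' @param mirna_id miRNA to stratify on.
#' @param min_rpm Positivity threshold (default 1 RPM).
#' @return A ggplot.
#' @export
plot_km_strata <- function(m, surv, mirna_id, min_rpm = 1) {
  d <- dichotomize(m, mirna_id, min_rpm = min_rpm)
  joined <- dplyr::inner_join(d, surv, by = "sample_id")
  curves <- joined |>
    dplyr::group_by(.data$stratum) |>
    dplyr::group_modify(~{
      km <- km_estimate(.x$time, .x$event)
      dplyr::bind_rows(tibble(time = 0, survival = 1),
                       tibble(time = km$time, survival = km$survival))
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$survival,
                                       colour = .data$stratum)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Overall survival", colour = mirna_id) +
    ggplot2::theme_minimal()
}
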