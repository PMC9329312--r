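# ggplot2 autoplot methods for the result types.

#' Plot a VIMP screening table
#'
#' Horizontal bar chart of the top predictors by permutation importance,
#' mirroring the usual presentation of kinome screening results.
#'
#' @param object A `vimp_table` from [screen_ae()].
#' @param k Number of predictors shown (default the table's `top_k`).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.vimp_table <- function(object, k = NULL, ...) {
  top <- top_predictors(object, k)
  ggplot2::ggplot(top,
                  ggplot2::aes(x = .data$vimp,
                               y = stats::reorder(.data$predictor,
                                                  .data$vimp))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "permutation variable importance", y = NULL,
                  title = unique(top$ae_term)) +
    ggplot2::theme_minimal()
}

#' Plot median-split stratified survival curves
#'
#' Mean ensemble survival per inhibition stratum with its 95% pointwise
#' band; diverging curves indicate exposure-dependent onset of the event.
#'
#' @param object A `stratified_curves` table from [stratify_survival()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.stratified_curves <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = .data$mean_survival,
                               colour = .data$stratum,
                               fill = .data$stratum)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "days since treatment start",
                  y = "event-free probability",
                  title = attr(object, "kinase"),
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation C-index distribution
#'
#' @param object A `cv_result` from [bootstrap_cv()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$iterations, ggplot2::aes(x = .data$c_index)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = object$mean, linetype = 2) +
    ggplot2::labs(x = "held-out C-index", y = "iterations",
                  title = sprintf("%s: mean C = %.3f (90%% interval %.3f-%.3f)",
                                  object$ae_term, object$mean, object$lower,
                                  object$upper)) +
    ggplot2::theme_minimal()
}

#' Plot an external validation report
#'
#' Predicted AE probability against observed incidence with the frequent-AE
#' threshold marked on both axes.
#'
#' @param object An `external_validation` from [external_validate()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.external_validation <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 3) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 3) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "observed incidence", y = "predicted probability") +
    ggplot2::theme_minimal()
}
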