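#' Plot actual versus forecast discharges over the test period
#'
#' Overlays each model's rolling one-step-ahead forecasts on the realised
#' daily discharge counts.
#'
#' @param object A `ward_eval` from [rolling_evaluate()].
#' @param models Optional subset of model names to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ward_eval
#' @export
autoplot.ward_eval <- function(object, models = NULL, ...) {
  runs <- object$runs
  if (!is.null(models)) runs <- runs[runs$model %in% models, , drop = FALSE]
  actual <- runs |> dplyr::distinct(.data$date, .data$actual)
  ggplot2::ggplot(runs, ggplot2::aes(x = .data$date)) +
    ggplot2::geom_line(data = actual, ggplot2::aes(y = .data$actual),
                       colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$forecast, colour = .data$model)) +
    ggplot2::facet_wrap(~model) +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = NULL, y = "Discharges per day",
                  title = "Actual (grey) vs forecast discharges")
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot

#' Plot per-weekday forecast MAE by model
#'
#' @param eval A `ward_eval` from [rolling_evaluate()].
#' @return A ggplot object.
#' @export
plot_weekday_mae <- function(eval) {
  wm <- eval$weekday_mae |>
    dplyr::mutate(weekday = factor(.data$weekday, levels = DOW_LABELS))
  ggplot2::ggplot(wm, ggplot2::aes(x = .data$weekday, y = .data$mae,
                                   group = .data$model,
                                   colour = .data$model)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "MAE (discharges/day)",
                  title = "Forecast error by day of week")
}

#' Plot the top random-forest feature importances
#'
#' @param eval A `ward_eval` (with `rf` among its models) or a
#'   [feature_importance()] tibble.
#' @param top Number of features to show.
#' @return A ggplot object.
#' @export
plot_importance <- function(eval, top = 15L) {
  imp <- if (inherits(eval, "ward_eval")) eval$importance else eval
  if (is.null(imp))
    abort("No importance ranking available; run the `rf` model first.",
          class = "wardflow_validation_error")
  imp <- head(imp, top)
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$importance,
                                    y = stats::reorder(.data$column,
                                                       .data$importance),
                                    fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Permutation importance", y = NULL, fill = "Group",
                  title = "Top predictors of next-day discharges")
}
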