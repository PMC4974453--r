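#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an evaluation into one row per model
#'
#' @param x A `ward_eval` from [rolling_evaluate()].
#' @param ... Unused.
#' @return The per-model metrics tibble (MFE, MAE, RMSE, sMAPE and MAE
#'   improvement over the baseline).
#' @method tidy ward_eval
#' @export
tidy.ward_eval <- function(x, ...) {
  x$metrics
}

#' One-row summary of an evaluation
#'
#' @param x A `ward_eval` from [rolling_evaluate()].
#' @param ... Unused.
#' @return A one-row tibble: number of test days and models, the best model
#'   by MAE and its MAE/sMAPE.
#' @method glance ward_eval
#' @export
glance.ward_eval <- function(x, ...) {
  best <- x$metrics |> dplyr::arrange(.data$mae) |> dplyr::slice(1)
  tibble::tibble(
    n_test_days = length(unique(x$runs$date)),
    n_models = length(unique(x$runs$model)),
    best_model = best$model,
    best_mae = best$mae,
    best_smape = best$smape
  )
}

#' Tidy a fitted random-forest forecaster into its importance ranking
#'
#' @param x A `ward_rf` from [rf_forecast()].
#' @param ... Unused.
#' @return The [feature_importance()] tibble.
#' @method tidy ward_rf
#' @export
tidy.ward_rf <- function(x, ...) feature_importance(x)
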