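check_metric_input <- function(y, f) {
  if (length(y) == 0L || length(f) == 0L)
    abort("Metric inputs must be nonempty.", class = "wardflow_validation_error")
  if (length(y) != length(f))
    abort("`y` and `f` must have the same length.",
          class = "wardflow_validation_error")
  invisible(TRUE)
}

#' Forecast error metrics
#'
#' The four standard point-forecast error metrics for actuals `y` and
#' forecasts `f`:
#' * `mfe(y, f) = mean(y - f)` -- mean forecast error, a bias measure; 0 for
#'   an ideal model, positive when the model tends to under-forecast,
#'   negative when it over-forecasts;
#' * `mae(y, f) = mean(|y - f|)` -- mean absolute error;
#' * `rmse(y, f) = sqrt(mean((y - f)^2))` -- root mean square error, giving
#'   large errors more influence;
#' * `smape(y, f) = mean(200 * |y - f| / (y + f))` -- symmetric mean
#'   absolute percentage error, in percent. It is scale-free and defined
#'   when the true value is zero; for nonnegative series it lies in
#'   `[0, 200]`, attaining 200 when exactly one of the pair is zero. Pairs
#'   with `y + f = 0` (both zero -- forecast and actual agree) contribute 0.
#'
#' @param y Numeric vector of actual values.
#' @param f Numeric vector of forecasts, same length.
#' @return A single number; `smape` is in percent.
#' @export
#' @examples
#' mfe(c(10), c(5))    # 5
#' smape(c(10), c(5))  # 200 * 5 / 15 = 66.67
#' smape(c(0), c(3))   # 200
mfe <- function(y, f) {
  check_metric_input(y, f)
  mean(y - f)
}

#' @rdname mfe
#' @export
mae <- function(y, f) {
  check_metric_input(y, f)
  mean(abs(y - f))
}

#' @rdname mfe
#' @export
rmse <- function(y, f) {
  check_metric_input(y, f)
  sqrt(mean((y - f)^2))
}

#' @rdname mfe
#' @export
smape <- function(y, f) {
  check_metric_input(y, f)
  denom <- y + f
  term <- ifelse(denom == 0, 0, 200 * abs(y - f) / denom)
  mean(term)
}

#' Percentage MAE improvement over a reference forecaster
#'
#' `100 * (reference_mae - model_mae) / reference_mae`: the relative
#' reduction in mean absolute error a model achieves over a named reference
#' (conventionally the strongest naive baseline).
#'
#' @param reference_mae MAE of the reference model (> 0).
#' @param model_mae MAE of the model being compared.
#' @return Improvement in percent (negative when the model is worse).
#' @export
#' @examples
#' improvement_over(3.44, 2.66)  # 22.7
improvement_over <- function(reference_mae, model_mae) {
  if (!is.finite(reference_mae) || reference_mae <= 0)
    abort("`reference_mae` must be > 0.", class = "wardflow_validation_error")
  100 * (reference_mae - model_mae) / reference_mae
}
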