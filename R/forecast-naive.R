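# Shared: pull the discharge history strictly before target_date, as a
# contiguous daily vector, and check sufficiency.
history_before <- function(daily, target_date, min_days) {
  target_date <- as.Date(target_date)
  h <- daily[daily$date < target_date, , drop = FALSE]
  if (nrow(h) < min_days)
    abort(sprintf("Need at least %d days of history before %s.",
                  min_days, format(target_date)),
          class = "wardflow_validation_error")
  if (tail(h$date, 1) != target_date - 1L)
    abort("History must run through the day before the target date.",
          class = "wardflow_validation_error")
  h
}

#' Naive baselines for next-day discharges
#'
#' Three forecasting rules mirroring how a floor manager might eyeball past
#' discharges: `naive_last_weekday()` repeats the discharge count observed on
#' the same weekday one week earlier; `naive_mean_week()` averages the
#' trailing 7 days; `naive_mean_3weeks()` averages the trailing 21 days
#' (smoothing over weekly and some monthly variation).
#'
#' @param daily A `ward_daily` tibble from [derive_daily_series()], covering
#'   at least the 7 (resp. 21) days before `target_date`.
#' @param target_date The day being forecast; only data strictly before it is
#'   used.
#' @return A single numeric forecast.
#' @export
#' @examples
#' d <- tibble::tibble(date = as.Date("2020-01-01") + 0:20,
#'                     discharges = rep(c(8, 9, 7, 8, 10, 6, 8), 3))
#' naive_mean_week(d, as.Date("2020-01-22"))
naive_last_weekday <- function(daily, target_date) {
  h <- history_before(daily, target_date, 7L)
  as.numeric(h$discharges[h$date == as.Date(target_date) - 7L])
}

#' @rdname naive_last_weekday
#' @export
naive_mean_week <- function(daily, target_date) {
  h <- history_before(daily, target_date, 7L)
  mean(tail(h$discharges, 7L))
}

#' @rdname naive_last_weekday
#' @export
naive_mean_3weeks <- function(daily, target_date) {
  h <- history_before(daily, target_date, 21L)
  mean(tail(h$discharges, 21L))
}
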