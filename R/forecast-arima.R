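# AICc-based automatic order selection over a small (p, d, q) grid, the
# likelihood fit itself delegated to stats::arima. Failed or non-converged
# candidates are skipped.
select_arima_order <- function(y, xreg = NULL, max_p = 3L, max_q = 3L,
                               d_opts = 0:1) {
  best <- NULL
  best_aicc <- Inf
  n <- length(y)
  for (d in d_opts) {
    for (p in 0:max_p) {
      for (q in 0:max_q) {
        fit <- tryCatch(
          suppressWarnings(arima(y, order = c(p, d, q), xreg = xreg,
                                 method = "CSS-ML")),
          error = function(e) NULL
        )
        if (is.null(fit)) next
        npar <- length(fit$coef) + 1  # + innovation variance
        aicc <- AIC(fit) + 2 * npar * (npar + 1) / max(n - npar - 1, 1)
        if (is.finite(aicc) && aicc < best_aicc) {
          best_aicc <- aicc
          best <- c(p, d, q)
        }
      }
    }
  }
  best %||% c(0L, 0L, 0L)
}

fit_and_predict_arima <- function(y, xreg = NULL, newxreg = NULL, order) {
  fit <- tryCatch(
    suppressWarnings(arima(y, order = order, xreg = xreg, method = "CSS-ML")),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NA_real_)
  pr <- tryCatch(as.numeric(predict(fit, n.ahead = 1, newxreg = newxreg)$pred),
                 error = function(e) NA_real_)
  pr
}

# Day-of-week indicator contrasts (Tue..Sun, Monday as reference) for ARMAX.
dow_contrasts <- function(dates) {
  dow <- iso_dow(dates)
  m <- vapply(2:7, function(d) as.numeric(dow == d), numeric(length(dates)))
  m <- matrix(m, nrow = length(dates), ncol = 6)
  colnames(m) <- paste0("dow_", DOW_LABELS[2:7])
  m
}

#' One-step-ahead ARIMA / ARMAX forecasts on a rolling window
#'
#' Adapters around [stats::arima()] implementing the rolling next-day
#' protocol: the model is fit on the trailing `window` days of discharges
#' (default 90, i.e. roughly the past 3 months) and the one-step-ahead mean
#' forecast is returned. Orders are selected automatically by an AICc scan
#' over a small grid unless supplied. `armax_forecast()` additionally
#' conditions on known exogenous regressors for the target day: six
#' day-of-week indicator contrasts (Monday reference) and the previous-day
#' ward occupancy.
#'
#' If the fit fails or yields a non-finite forecast (e.g. on a degenerate
#' constant window), the forecast falls back to [naive_mean_week()] with a
#' warning.
#'
#' @param daily A `ward_daily` tibble from [derive_daily_series()].
#' @param target_date The day being forecast; only data strictly before it is
#'   used.
#' @param window Trailing window length in days (>= 30).
#' @param order Optional `c(p, d, q)`; selected by AICc scan when `NULL`.
#' @return A single numeric forecast.
#' @export
arima_forecast <- function(daily, target_date, window = 90L, order = NULL) {
  if (window < 30L)
    abort("`window` must be at least 30 days.", class = "wardflow_config_error")
  h <- history_before(daily, target_date, window)
  y <- as.numeric(tail(h$discharges, window))
  if (is.null(order)) order <- select_arima_order(y)
  out <- fit_and_predict_arima(y, order = order)
  if (!is.finite(out)) {
    warn(sprintf("ARIMA forecast for %s non-finite; falling back to naive_mean_week.",
                 format(as.Date(target_date))))
    out <- naive_mean_week(daily, target_date)
  }
  out
}

# Exogenous design for ARMAX: day-of-week contrasts + previous-day
# occupancy. For day t in the window the occupancy regressor is o_{t-1}; for
# the target day it is the last observed occupancy -- all known at the
# cutoff. Constant columns (e.g. occupancy that never varies in the window,
# or a weekday absent from a short window) are dropped to keep the design
# full-rank.
armax_design <- function(daily, target_date, window) {
  target_date <- as.Date(target_date)
  h <- tail(history_before(daily, target_date, window), window)
  y <- as.numeric(h$discharges)
  occ_lag <- dplyr::lag(daily$occupancy)[match(h$date, daily$date)]
  keep_row <- !is.na(occ_lag)
  y <- y[keep_row]; h <- h[keep_row, , drop = FALSE]
  occ_lag <- occ_lag[keep_row]
  xreg <- cbind(dow_contrasts(h$date), occ_lag_1 = occ_lag)
  newxreg <- cbind(dow_contrasts(target_date),
                   occ_lag_1 = tail(daily$occupancy[daily$date < target_date], 1))
  keep_col <- apply(xreg, 2, function(v) var(v) > 0)
  list(y = y,
       xreg = xreg[, keep_col, drop = FALSE],
       newxreg = newxreg[, keep_col, drop = FALSE])
}

#' @rdname arima_forecast
#' @export
armax_forecast <- function(daily, target_date, window = 90L, order = NULL) {
  if (window < 30L)
    abort("`window` must be at least 30 days.", class = "wardflow_config_error")
  target_date <- as.Date(target_date)
  des <- armax_design(daily, target_date, window)
  if (is.null(order)) order <- select_arima_order(des$y, xreg = des$xreg)
  out <- fit_and_predict_arima(des$y, xreg = des$xreg, newxreg = des$newxreg,
                               order = order)
  if (!is.finite(out)) {
    warn(sprintf("ARMAX forecast for %s non-finite; falling back to naive_mean_week.",
                 format(target_date)))
    out <- naive_mean_week(daily, target_date)
  }
  out
}
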