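#' Registry of available forecasters
#'
#' @return Character vector of model names understood by
#'   [rolling_evaluate()]: the three naive baselines (`naive_lw` = last
#'   weekday, `naive_mw` = mean of last week, `naive_m3w` = mean of last 3
#'   weeks), the pattern-matching `knn`, the `arima`/`armax` adapters and
#'   the feature-based `rf`/`svr` learners.
#' @export
ward_model_registry <- function() {
  c("naive_lw", "naive_mw", "naive_m3w", "knn", "arima", "armax", "rf", "svr")
}

resolve_models <- function(models) {
  registry <- ward_model_registry()
  if (identical(models, "all")) return(registry)
  unknown <- setdiff(models, registry)
  if (length(unknown) > 0L)
    abort(paste0("Unknown model(s): ", paste(unknown, collapse = ", "),
                 ". Registry: ", paste(registry, collapse = ", ")),
          class = "wardflow_config_error")
  models
}

#' Rolling one-step-ahead evaluation over a time-separated test block
#'
#' The core evaluation harness: for every day after `split_date`, each
#' requested model produces a next-day forecast using only information
#' available at the end of the previous day, and the forecasts are scored
#' against the realised discharge counts. Training and testing are separated
#' by time, mirroring deployment.
#'
#' Protocols per model:
#' * naive baselines -- recomputed from the trailing history each day;
#' * `knn` -- pattern length and neighbour count tuned once on the training
#'   block via [tune_knn()] (unless a [knn_config()] is supplied), then
#'   applied with an expanding history;
#' * `arima` / `armax` -- refit daily on the trailing `arima_window` days;
#'   orders reselected by AICc scan every `reselect_every` test days;
#' * `rf` / `svr` -- fit once on the training block of the feature matrix
#'   (no daily refit) with their tuning protocols ([rf_forecast()],
#'   [svr_forecast()]).
#'
#' @param daily A `ward_daily` tibble covering training and test periods.
#' @param features A `ward_features` tibble from [build_feature_matrix()]
#'   (required when `rf` or `svr` is requested).
#' @param models Character vector of registry names, or `"all"`.
#' @param split_date Last training day; all later days in `daily` are test
#'   days.
#' @param knn Optional [knn_config()]; tuned on the training block when
#'   `NULL`.
#' @param knn_p_grid,knn_k_grid Grids for [tune_knn()].
#' @param arima_window Trailing window for the ARIMA/ARMAX refits.
#' @param reselect_every Reselect ARIMA/ARMAX orders every this many test
#'   days.
#' @param seed Seed recorded for the random-forest fit.
#' @param baseline Model name used as the reference for MAE improvement.
#' @param rf_args,svr_args Named lists of extra arguments for
#'   [rf_forecast()] and [svr_forecast()] (e.g. `num_trees`, `C_grid`).
#' @return An object of class `ward_eval`: list with `runs` (long tibble:
#'   `date`, `model`, `actual`, `forecast`), `metrics` (per-model MFE, MAE,
#'   RMSE, sMAPE and MAE improvement over the baseline), `weekday_mae`,
#'   `importance` (RF permutation ranking, when `rf` is run), and `state`
#'   (tuned configurations and fitted models, kept for auditing).
#' @seealso [ward_metrics()], [audit_information_cutoff()]
#' @export
rolling_evaluate <- function(daily, features = NULL, models = "all",
                             split_date, knn = NULL,
                             knn_p_grid = c(2L, 3L, 5L, 7L, 10L, 14L),
                             knn_k_grid = c(5L, 10L, 25L, 50L, 100L),
                             arima_window = 90L, reselect_every = 28L,
                             seed = 1L, baseline = "naive_m3w",
                             rf_args = list(), svr_args = list()) {
  models <- resolve_models(models)
  split_date <- as.Date(split_date)
  if (split_date < min(daily$date) || split_date >= max(daily$date))
    abort("`split_date` must fall inside the data range, before its last day.",
          class = "wardflow_config_error")
  test_dates <- daily$date[daily$date > split_date]
  actual <- daily$discharges[match(test_dates, daily$date)]
  state <- list(seed = seed, split_date = split_date, models = models)

  forecasts <- list()

  roll <- function(fun) vapply(test_dates, fun, numeric(1))
  if ("naive_lw" %in% models)
    forecasts$naive_lw <- roll(function(d) naive_last_weekday(daily, d))
  if ("naive_mw" %in% models)
    forecasts$naive_mw <- roll(function(d) naive_mean_week(daily, d))
  if ("naive_m3w" %in% models)
    forecasts$naive_m3w <- roll(function(d) naive_mean_3weeks(daily, d))

  if ("knn" %in% models) {
    if (is.null(knn)) {
      train_y <- daily$discharges[daily$date <= split_date]
      knn <- tune_knn(train_y, p_grid = knn_p_grid, k_grid = knn_k_grid)
    }
    state$knn <- knn
    forecasts$knn <- roll(function(d)
      knn_forecast(daily, knn, d, train_end = split_date))
  }

  roll_arima <- function(fun_select, fun_forecast) {
    order <- NULL
    orders <- vector("list", length(test_dates))
    out <- numeric(length(test_dates))
    for (i in seq_along(test_dates)) {
      if ((i - 1L) %% reselect_every == 0L) order <- fun_select(test_dates[i])
      orders[[i]] <- order
      out[i] <- fun_forecast(test_dates[i], order)
    }
    list(forecast = out,
         orders = tibble::tibble(date = test_dates,
                                 order = vapply(orders, paste, character(1),
                                                collapse = ",")))
  }
  if ("arima" %in% models) {
    res <- roll_arima(
      function(d) {
        y <- tail(history_before(daily, d, arima_window)$discharges, arima_window)
        select_arima_order(as.numeric(y))
      },
      function(d, ord) arima_forecast(daily, d, window = arima_window, order = ord)
    )
    forecasts$arima <- res$forecast
    state$arima_orders <- res$orders
  }
  if ("armax" %in% models) {
    res <- roll_arima(
      function(d) {
        des <- armax_design(daily, d, arima_window)
        select_arima_order(des$y, xreg = des$xreg)
      },
      function(d, ord) armax_forecast(daily, d, window = arima_window, order = ord)
    )
    forecasts$armax <- res$forecast
    state$armax_orders <- res$orders
  }

  if (any(c("rf", "svr") %in% models)) {
    if (is.null(features))
      abort("`features` is required for the rf/svr models.",
            class = "wardflow_config_error")
    train_fm <- features[features$date <= split_date & !is.na(features$target), ]
    test_fm <- features[features$date %in% test_dates, ]
    if (!setequal(test_fm$date, test_dates))
      abort("`features` must contain a row for every test day.",
            class = "wardflow_config_error")
    test_fm <- test_fm[order(test_fm$date), ]
    if ("rf" %in% models) {
      fit <- do.call(rf_forecast,
                     c(list(train_fm, test_fm, seed = seed), rf_args))
      forecasts$rf <- fit$predictions$forecast[match(test_dates,
                                                     fit$predictions$date)]
      state$rf <- fit
    }
    if ("svr" %in% models) {
      fit <- do.call(svr_forecast, c(list(train_fm, test_fm), svr_args))
      forecasts$svr <- fit$predictions$forecast[match(test_dates,
                                                      fit$predictions$date)]
      state$svr <- fit
    }
  }

  runs <- purrr::imap(forecasts, function(f, nm)
    tibble::tibble(date = test_dates, model = nm, actual = actual,
                   forecast = as.numeric(f))) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$date, .data$model)

  out <- structure(
    list(runs = runs,
         metrics = ward_metrics(runs, baseline = baseline),
         weekday_mae = weekday_mae(runs),
         importance = if (!is.null(state$rf)) feature_importance(state$rf),
         state = state),
    class = "ward_eval"
  )
  out
}

#' Score a long table of forecast runs
#'
#' Computes MFE, MAE, RMSE and sMAPE per model from a long `runs` table
#' (`date`, `model`, `actual`, `forecast`), plus each model's percentage MAE
#' improvement over the named baseline (`NA` for the baseline itself, and
#' omitted entirely when the baseline was not run).
#'
#' @param runs Long tibble of forecasts as produced by [rolling_evaluate()].
#' @param baseline Reference model name for [improvement_over()].
#' @return A tibble with one row per model.
#' @export
ward_metrics <- function(runs, baseline = "naive_m3w") {
  m <- runs |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      n = dplyr::n(),
      mfe = mfe(.data$actual, .data$forecast),
      mae = mae(.data$actual, .data$forecast),
      rmse = rmse(.data$actual, .data$forecast),
      smape = smape(.data$actual, .data$forecast),
      .groups = "drop"
    )
  if (baseline %in% m$model) {
    ref <- m$mae[m$model == baseline]
    m$mae_improvement <- ifelse(m$model == baseline, NA_real_,
                                improvement_over(ref, m$mae))
  }
  ordering <- match(m$model, ward_model_registry())
  m[order(ordering), , drop = FALSE]
}

#' Per-weekday MAE breakdown
#'
#' @param runs Long tibble of forecasts (`date`, `model`, `actual`,
#'   `forecast`).
#' @return A tibble `model`, `dow` (Mon=1..Sun=7), `weekday`, `mae`.
#' @export
weekday_mae <- function(runs) {
  runs |>
    dplyr::mutate(dow = iso_dow(.data$date),
                  weekday = DOW_LABELS[.data$dow]) |>
    dplyr::group_by(.data$model, .data$dow, .data$weekday) |>
    dplyr::summarise(mae = mae(.data$actual, .data$forecast),
                     .groups = "drop") |>
    dplyr::arrange(.data$model, .data$dow)
}

#' @export
print.ward_eval <- function(x, ...) {
  cat("<ward_eval> ", length(unique(x$runs$model)), " model(s), ",
      length(unique(x$runs$date)), " test day(s)\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' Audit the information cutoff of an evaluation
#'
#' Verifies that no forecaster used information from its own forecast day or
#' later: for each audited test day `d`, the raw inputs are truncated at the
#' end of day `d - 1` (future visits dropped, in-ward patients' exits
#' censored -- exactly what would have been known that evening) and every
#' model's day-`d` forecast is recomputed from the truncated data using the
#' tuned state of the original run. A leak-free pipeline reproduces every
#' forecast exactly.
#'
#' @param eval A `ward_eval` from [rolling_evaluate()].
#' @param visits The `ward_visits` records behind the evaluation.
#' @param daily The `ward_daily` series used in the evaluation.
#' @param dates Test days to audit; defaults to `n_days` sampled with
#'   `seed`.
#' @param n_days Number of test days to sample when `dates` is `NULL`.
#' @param seed Sampling seed.
#' @param tol Numeric tolerance on forecast equality.
#' @return A tibble `date`, `model`, `original`, `recomputed`, `ok`
#'   (invisible attribute aside); errors if any forecast changes.
#' @export
audit_information_cutoff <- function(eval, visits, daily, dates = NULL,
                                     n_days = 5L, seed = 1L, tol = 1e-8) {
  stopifnot(inherits(eval, "ward_eval"))
  all_dates <- sort(unique(eval$runs$date))
  if (is.null(dates)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(seed)
    dates <- sort(sample(all_dates, min(n_days, length(all_dates))))
  }
  state <- eval$state
  models <- state$models

  one_day <- function(d) {
    cutoff <- d - 1L
    daily_t <- daily[daily$date <= cutoff, , drop = FALSE]
    visits_t <- visits[visits$entry_date <= cutoff, , drop = FALSE]
    open <- visits_t$exit_date > cutoff
    visits_t$exit_date[open] <- cutoff + 10000L  # exit not yet known
    visits_t$ward_exit[open] <- as.POSIXct(visits_t$exit_date[open], tz = "UTC")

    fc <- list()
    if ("naive_lw" %in% models) fc$naive_lw <- naive_last_weekday(daily_t, d)
    if ("naive_mw" %in% models) fc$naive_mw <- naive_mean_week(daily_t, d)
    if ("naive_m3w" %in% models) fc$naive_m3w <- naive_mean_3weeks(daily_t, d)
    if ("knn" %in% models)
      fc$knn <- knn_forecast(daily_t, state$knn, d,
                             train_end = state$split_date)
    ord_of <- function(tb) as.integer(strsplit(tb$order[tb$date == d], ",")[[1]])
    if ("arima" %in% models)
      fc$arima <- arima_forecast(daily_t, d, order = ord_of(state$arima_orders))
    if ("armax" %in% models)
      fc$armax <- armax_forecast(daily_t, d, order = ord_of(state$armax_orders))
    if (any(c("rf", "svr") %in% models)) {
      row <- build_feature_matrix(visits_t, daily = daily_t, dates = d)
      if ("rf" %in% models) {
        x <- as.matrix(row[predictor_columns(row)])[, state$rf$kept, drop = FALSE]
        fc$rf <- as.numeric(predict(state$rf$model, data = x,
                                    num.threads = 1L)$predictions)
      }
      if ("svr" %in% models) {
        x <- as.matrix(row[predictor_columns(row)])[, state$svr$kept, drop = FALSE]
        xs <- scale(x, center = state$svr$center, scale = state$svr$scale)
        fc$svr <- svm_predict_safe(state$svr$model, xs, state$svr$train_mean)
      }
    }
    tibble::tibble(date = d, model = names(fc),
                   recomputed = as.numeric(unlist(fc)))
  }

  audit <- purrr::map(dates, one_day) |> purrr::list_rbind() |>
    dplyr::inner_join(eval$runs |> dplyr::select("date", "model",
                                                 original = "forecast"),
                      by = c("date", "model")) |>
    dplyr::mutate(ok = abs(.data$recomputed - .data$original) <= tol)
  if (!all(audit$ok)) {
    bad <- audit[!audit$ok, , drop = FALSE]
    abort(paste0("Information-cutoff violation for: ",
                 paste(sprintf("%s@%s", bad$model, bad$date), collapse = ", ")),
          class = "wardflow_leakage_error")
  }
  audit
}
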