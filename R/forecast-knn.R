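#' Configuration for the pattern-matching kNN forecaster
#'
#' @param p Pattern length in days: the query is the vector of the last `p`
#'   discharge counts.
#' @param k Number of nearest historical windows to match.
#' @param loss How the matched next-day values are combined:
#'   `"robust_median"` (their median -- the minimiser of absolute-error loss,
#'   robust to the outlier-heavy variation typical of discharge counts) or
#'   `"weighted_quadratic"` (a weighted mean -- the minimiser of weighted
#'   squared-error loss).
#' @param weights For `"weighted_quadratic"` only: `k` nonnegative weights
#'   summing to 1, applied to the matched values in order of increasing
#'   distance. Defaults to uniform, in which case the combination is the
#'   plain mean.
#' @return An object of class `knn_config`.
#' @export
knn_config <- function(p, k, loss = c("robust_median", "weighted_quadratic"),
                       weights = NULL) {
  loss <- match.arg(loss)
  p <- as.integer(p); k <- as.integer(k)
  if (p < 1L || k < 1L)
    abort("`p` and `k` must be positive integers.",
          class = "wardflow_config_error")
  if (!is.null(weights)) {
    if (length(weights) != k || any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
      abort("`weights` must be k nonnegative reals summing to 1.",
            class = "wardflow_config_error")
  }
  structure(list(p = p, k = k, loss = loss, weights = weights),
            class = "knn_config")
}

#' Pattern-matching k-nearest-neighbour forecast of next-day discharges
#'
#' Treats the last `p` days of discharges as a query pattern, finds the `k`
#' historical windows of length `p` closest to it in Euclidean distance, and
#' forecasts the next day as a robust summary of the `k` matched next-day
#' values: their median under `"robust_median"`, or a weighted mean under
#' `"weighted_quadratic"`. Distance ties are broken in favour of the
#' earlier-starting window, so the forecast is deterministic.
#'
#' Candidate windows are drawn from the training data: every window of
#' length `p` whose next-day value also lies inside the training range. By
#' default the whole supplied history is training; in a time-separated
#' evaluation, `train_end` pins the training range to the pre-split block so
#' matches never come from the test period even as the query pattern rolls
#' forward through it.
#'
#' @param history Either a `ward_daily` tibble (combined with `target_date`)
#'   or a plain numeric vector of past discharges ending the day before the
#'   day being forecast.
#' @param config A [knn_config()].
#' @param target_date Required when `history` is a tibble; only data strictly
#'   before it is used.
#' @param train_end Optional end of the training range: a `Date` when
#'   `history` is a tibble, or the number of leading observations when it is
#'   a vector. `NULL` (default) treats all history as training.
#' @return A single numeric forecast, always within the range of the
#'   training next-day values.
#' @export
#' @examples
#' knn_forecast(c(5, 3, 8, 5, 3, 8, 5, 3), knn_config(p = 2, k = 2))  # 8
knn_forecast <- function(history, config, target_date = NULL,
                         train_end = NULL) {
  stopifnot(inherits(config, "knn_config"))
  y <- as_history_vector(history, target_date, min_days = config$p + config$k)
  p <- config$p; k <- config$k
  n <- length(y)
  n_train <- n
  if (!is.null(train_end)) {
    n_train <- if (is.numeric(train_end)) {
      as.integer(train_end)
    } else {
      if (is.numeric(history))
        abort("A `Date` `train_end` needs a daily-series `history`.",
              class = "wardflow_validation_error")
      sum(history$date <= as.Date(train_end) & history$date < as.Date(target_date))
    }
    if (n_train < p + k || n_train > n)
      abort("`train_end` must leave at least p + k observations within the history.",
            class = "wardflow_validation_error")
  }
  n_cand <- n_train - p
  if (n_cand < k)
    abort(sprintf("Only %d candidate windows for k = %d.", n_cand, k),
          class = "wardflow_validation_error")
  query <- y[(n - p + 1L):n]
  # Candidate windows start at i = 1..n_train-p; window y[i..i+p-1], next
  # value y[i+p] -- window and successor both inside the training range.
  win <- stats::embed(y[seq_len(n_train)], p + 1L)  # rows: [y_{i+p}, ..., y_i]
  nxt <- win[seq_len(n_cand), 1L]
  wins <- win[seq_len(n_cand), (p + 1L):2L, drop = FALSE]  # oldest..newest
  d2 <- colSums((t(wins) - query)^2)
  ord <- order(d2, seq_len(n_cand))         # ties: earlier window wins
  matched <- nxt[ord[seq_len(k)]]
  if (config$loss == "robust_median") {
    median(matched)
  } else {
    w <- config$weights %||% rep(1 / k, k)
    sum(w * matched)
  }
}

as_history_vector <- function(history, target_date, min_days) {
  if (is.numeric(history)) {
    y <- as.numeric(history)
  } else {
    if (is.null(target_date))
      abort("`target_date` is required when `history` is a daily series.",
            class = "wardflow_validation_error")
    y <- as.numeric(history_before(history, target_date, min_days)$discharges)
  }
  if (length(y) < min_days)
    abort(sprintf("Need at least %d days of history.", min_days),
          class = "wardflow_validation_error")
  y
}

#' Tune the kNN pattern forecaster by validation-tail RMSE
#'
#' Scans a grid of pattern lengths `p` and neighbour counts `k`, scoring each
#' pair by the RMSE of rolling one-step-ahead forecasts over the last 20% of
#' the training series (each forecast uses only data before its own day).
#' Ties are broken toward smaller `p`, then smaller `k`, so tuning is
#' deterministic.
#'
#' @param train A `ward_daily` tibble or numeric discharge vector.
#' @param p_grid,k_grid Integer grids to scan.
#' @param loss Passed to [knn_config()].
#' @param validation_frac Fraction of the series tail held out for scoring.
#' @return The winning [knn_config()], with the full score table in attribute
#'   `"scores"`.
#' @export
tune_knn <- function(train, p_grid = c(2L, 3L, 5L, 7L, 10L, 14L),
                     k_grid = c(5L, 10L, 25L, 50L, 100L),
                     loss = "robust_median", validation_frac = 0.2) {
  y <- if (is.numeric(train)) as.numeric(train) else as.numeric(train$discharges)
  n <- length(y)
  n_val <- max(1L, floor(n * validation_frac))
  val_idx <- (n - n_val + 1L):n
  max_p <- max(p_grid); max_k <- max(k_grid)
  if (min(val_idx) - 1L < max_p + max_k)
    abort("Training series too short for the largest (p, k) on the grid.",
          class = "wardflow_validation_error")

  scores <- tidyr::expand_grid(p = as.integer(p_grid), k = as.integer(k_grid))
  rmse_pk <- function(p, k) {
    cfg <- knn_config(p, k, loss)
    err <- vapply(val_idx, function(t) {
      f <- knn_forecast(y[seq_len(t - 1L)], cfg)
      y[t] - f
    }, numeric(1))
    sqrt(mean(err^2))
  }
  scores$rmse <- purrr::map2_dbl(scores$p, scores$k, rmse_pk)
  best <- scores |> dplyr::arrange(.data$rmse, .data$p, .data$k) |> dplyr::slice(1)
  out <- knn_config(best$p, best$k, loss)
  attr(out, "scores") <- scores
  out
}
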