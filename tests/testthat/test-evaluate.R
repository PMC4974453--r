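# One small evaluation shared across tests in this file.
eval_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- sim_fixture(n_days = 280, seed = 19)
      fm <- build_feature_matrix(fx$visits, daily = fx$daily)
      split <- fx$daily$date[220]
      ev <- suppressMessages(suppressWarnings(
        rolling_evaluate(fx$daily, features = fm, models = "all",
                         split_date = split,
                         knn_p_grid = c(2L, 7L), knn_k_grid = c(5L, 10L),
                         rf_args = list(num_trees = 300L))))
      cache <<- list(fx = fx, fm = fm, split = split, ev = ev)
    }
    cache
  }
})

test_that("an injected perfect model scores zero on all metrics", {
  set.seed(4)
  y <- rpois(60, 8)
  runs <- dplyr::bind_rows(
    tibble::tibble(date = as.Date("2020-01-01") + 1:60, model = "oracle",
                   actual = y, forecast = as.numeric(y)),
    tibble::tibble(date = as.Date("2020-01-01") + 1:60, model = "naive_m3w",
                   actual = y, forecast = y + 2)
  )
  m <- ward_metrics(runs, baseline = "naive_m3w")
  oracle <- m[m$model == "oracle", ]
  expect_equal(oracle$mfe, 0)
  expect_equal(oracle$mae, 0)
  expect_equal(oracle$rmse, 0)
  expect_equal(oracle$smape, 0)
  expect_equal(oracle$mae_improvement, 100)
  expect_true(is.na(m$mae_improvement[m$model == "naive_m3w"]))
})

test_that("every requested model is scored on every post-split day", {
  e <- eval_fixture()
  n_test <- sum(e$fx$daily$date > e$split)
  expect_equal(sort(unique(e$ev$runs$model)), sort(ward_model_registry()))
  counts <- table(e$ev$runs$model)
  expect_true(all(counts == n_test))
  expect_true(all(e$ev$runs$date > e$split))
  expect_equal(nrow(e$ev$metrics), 8L)
})

test_that("actuals in the runs table match the daily series", {
  e <- eval_fixture()
  d <- e$fx$daily
  ref <- d$discharges[match(e$ev$runs$date, d$date)]
  expect_equal(e$ev$runs$actual, ref)
})

test_that("weekday MAE uses Mon=1..Sun=7 and aggregates correctly", {
  e <- eval_fixture()
  wm <- e$ev$weekday_mae
  expect_true(all(wm$dow %in% 1:7))
  expect_equal(wm$weekday[wm$dow == 1][1], "Mon")
  one <- e$ev$runs[e$ev$runs$model == "knn", ]
  mon <- one[wardflow:::iso_dow(one$date) == 1, ]
  expect_equal(wm$mae[wm$model == "knn" & wm$dow == 1],
               mae(mon$actual, mon$forecast))
})

test_that("tidy/glance/autoplot surface the evaluation", {
  e <- eval_fixture()
  expect_identical(tidy(e$ev), e$ev$metrics)
  g <- glance(e$ev)
  expect_equal(g$n_models, 8L)
  expect_equal(g$best_mae, min(e$ev$metrics$mae))
  expect_s3_class(autoplot(e$ev), "ggplot")
  expect_s3_class(plot_weekday_mae(e$ev), "ggplot")
  expect_s3_class(plot_importance(e$ev), "ggplot")
})

test_that("the importance ranking is attached when rf runs", {
  e <- eval_fixture()
  expect_equal(nrow(e$ev$importance), 108L)
})

test_that("identical inputs and seeds reproduce the metrics exactly", {
  fx <- sim_fixture(n_days = 120, seed = 77)
  run_once <- function() {
    suppressMessages(rolling_evaluate(
      fx$daily, models = c("naive_mw", "naive_m3w", "knn"),
      split_date = fx$daily$date[90],
      knn_p_grid = c(2L, 3L), knn_k_grid = c(5L, 10L)))
  }
  expect_identical(run_once()$metrics, run_once()$metrics)
})

test_that("unknown model names list the registry", {
  fx <- sim_fixture(n_days = 60, seed = 1)
  expect_error(
    rolling_evaluate(fx$daily, models = "gradient_boost",
                     split_date = fx$daily$date[40]),
    regexp = "naive_lw", class = "wardflow_config_error")
})

test_that("a split outside the data range is refused", {
  fx <- sim_fixture(n_days = 60, seed = 1)
  expect_error(rolling_evaluate(fx$daily, models = "naive_mw",
                                split_date = max(fx$daily$date)),
               class = "wardflow_config_error")
})

test_that("the cutoff audit reproduces forecasts from truncated inputs", {
  e <- eval_fixture()
  audit <- audit_information_cutoff(e$ev, e$fx$visits, e$fx$daily,
                                    n_days = 3L, seed = 2)
  expect_true(all(audit$ok))
  expect_equal(sort(unique(audit$model)), sort(ward_model_registry()))
})
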