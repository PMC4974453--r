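# One moderate simulated feature matrix shared across the ML tests.
ml_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- sim_fixture(n_days = 320, seed = 33)
      fm <- build_feature_matrix(fx$visits, daily = fx$daily)
      cache <<- list(fx = fx, fm = fm,
                     train = fm[fm$date <= fx$daily$date[250], ],
                     test = fm[fm$date > fx$daily$date[250], ])
    }
    cache
  }
})

test_that("a perfectly predictable target is learned almost exactly", {
  m <- ml_fixture()
  train <- m$train; test <- m$test
  train$target <- train$dis_lag_7
  test$target <- test$dis_lag_7
  fit <- suppressMessages(rf_forecast(train, test, seed = 1))
  expect_lt(mae(test$target, fit$predictions$forecast), 0.5)
})

test_that("averaging many trees does not hurt accuracy vs a single tree", {
  m <- ml_fixture()
  rmse_by <- function(n_trees, seed) {
    fit <- suppressMessages(
      rf_forecast(m$train, m$test, num_trees = n_trees, mtry = 36, seed = seed))
    rmse(m$test$target, fit$predictions$forecast)
  }
  many <- mean(vapply(1:3, function(s) rmse_by(500L, s), numeric(1)))
  one <- mean(vapply(1:3, function(s) rmse_by(1L, s), numeric(1)))
  expect_lte(many, one)
})

test_that("the rf fit is reproducible under a fixed seed", {
  m <- ml_fixture()
  f1 <- suppressMessages(rf_forecast(m$train, m$test, seed = 9, mtry = 36))
  f2 <- suppressMessages(rf_forecast(m$train, m$test, seed = 9, mtry = 36))
  expect_identical(f1$predictions, f2$predictions)
  expect_identical(f1$mtry, f2$mtry)
})

test_that("an epsilon tube wider than the target range yields a flat forecast", {
  m <- ml_fixture()
  rng <- diff(range(m$train$target))
  fit <- suppressMessages(
    svr_forecast(m$train, m$test, C_grid = 1, epsilon_grid = rng + 10,
                 gamma_grid = 1 / 216))
  expect_lt(sd(fit$predictions$forecast), 1e-6)
})

test_that("svr tuning picks the grid minimiser and predictions are finite", {
  m <- ml_fixture()
  fit <- suppressMessages(
    svr_forecast(m$train, m$test, C_grid = c(1, 10), epsilon_grid = c(0.5, 1)))
  expect_true(all(is.finite(fit$predictions$forecast)))
  best_rmse <- fit$grid$rmse[fit$grid$C == fit$C &
                               fit$grid$epsilon == fit$epsilon &
                               fit$grid$gamma == fit$gamma]
  expect_equal(best_rmse, min(fit$grid$rmse))
})

test_that("training rows must precede test rows", {
  m <- ml_fixture()
  expect_error(rf_forecast(m$test, m$train), class = "wardflow_validation_error")
})

test_that("importance ranking covers all 108 predictors with group labels", {
  m <- ml_fixture()
  fit <- suppressMessages(rf_forecast(m$train, m$test, seed = 2, mtry = 36))
  imp <- feature_importance(fit)
  expect_equal(nrow(imp), 108L)
  expect_setequal(unique(imp$group), c("ward", "patient"))
  expect_equal(imp$rank, seq_len(108L))
  expect_true(all(diff(imp$importance) <= 1e-12))
  expect_identical(tidy(fit), imp)
})

test_that("a day-of-week-driven target puts day of week first", {
  m <- ml_fixture()
  set.seed(21)
  effect <- c(6, 7, 8, 9, 14, 3, 2)
  train <- m$train; test <- m$test
  train$target <- effect[train$dow] + rnorm(nrow(train), sd = 0.3)
  test$target <- effect[test$dow] + rnorm(nrow(test), sd = 0.3)
  fit <- suppressMessages(rf_forecast(train, test, seed = 3))
  imp <- feature_importance(fit)
  expect_equal(imp$column[1], "dow")
})

test_that("a pure-noise target produces no importance beyond the permutation null", {
  m <- ml_fixture()
  train <- m$train; test <- m$test
  set.seed(99)
  train$target <- rnorm(nrow(train))
  test$target <- rnorm(nrow(test))
  observed <- suppressMessages(
    feature_importance(rf_forecast(train, test, seed = 4, mtry = 36,
                                   num_trees = 300)))
  null_max <- vapply(1:12, function(s) {
    tr <- train
    tr$target <- sample(tr$target)
    imp <- suppressMessages(
      feature_importance(rf_forecast(tr, test, seed = s, mtry = 36,
                                     num_trees = 300)))
    max(imp$importance)
  }, numeric(1))
  expect_lte(max(observed$importance), quantile(null_max, 0.99) * 1.5)
})
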