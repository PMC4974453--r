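# Split a feature matrix into predictor matrix + target, dropping
# zero-variance predictor columns (by training-set variance).
prepare_xy <- function(features, keep = NULL) {
  x <- as.matrix(features[predictor_columns(features)])
  if (is.null(keep)) {
    v <- apply(x, 2, var)
    keep <- colnames(x)[is.finite(v) & v > 0]
    dropped <- setdiff(colnames(x), keep)
    if (length(dropped) > 0L)
      inform(paste0("Dropping zero-variance predictor(s): ",
                    paste(dropped, collapse = ", ")))
  }
  list(x = x[, keep, drop = FALSE], y = features$target, keep = keep)
}

#' Random-forest forecaster over the feature matrix
#'
#' Fits a random-forest regression of next-day discharges on the 108
#' predictors, once on the training block (no daily refit), and predicts
#' every test row. The number of variables tried at each split (`mtry`) is
#' chosen by scanning a small set of candidates and keeping the one with the
#' lowest out-of-bag error; the scan and the final fit use the recorded
#' `seed`, so results are reproducible. Zero-variance predictors (as judged
#' on the training block) are dropped with a message.
#'
#' @param train,test `ward_features` tibbles; all training dates must
#'   strictly precede all test dates.
#' @param num_trees Number of trees in the final fit.
#' @param mtry Variables per split; scanned over `mtry_grid` by out-of-bag
#'   error when `NULL`.
#' @param mtry_grid Candidate `mtry` values (defaults to roughly sqrt(P),
#'   P/3 and P/2 for P predictors).
#' @param min_node_size Minimum terminal node size.
#' @param seed Integer seed recorded in the result.
#' @return An object of class `ward_rf`: list with the fitted `ranger`
#'   model, `predictions` (tibble `date`, `forecast`), the chosen `mtry`,
#'   `kept`/`dropped` predictor names and the `seed`.
#' @export
rf_forecast <- function(train, test, num_trees = 500L, mtry = NULL,
                        mtry_grid = NULL, min_node_size = 5L, seed = 1L) {
  check_time_split(train, test)
  tr <- prepare_xy(train)
  te_x <- as.matrix(test[predictor_columns(test)])[, tr$keep, drop = FALSE]
  p <- ncol(tr$x)
  if (is.null(mtry)) {
    mtry_grid <- mtry_grid %||%
      sort(unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3), floor(p / 2)))))
    oob <- vapply(mtry_grid, function(m) {
      ranger::ranger(x = tr$x, y = tr$y, num.trees = 300L, mtry = m,
                     min.node.size = min_node_size, seed = seed,
                     num.threads = 1L)$prediction.error
    }, numeric(1))
    mtry <- mtry_grid[which.min(oob)]
  }
  model <- ranger::ranger(x = tr$x, y = tr$y, num.trees = num_trees,
                          mtry = mtry, min.node.size = min_node_size,
                          importance = "permutation", seed = seed,
                          num.threads = 1L)
  preds <- predict(model, data = te_x, num.threads = 1L)$predictions
  structure(
    list(model = model,
         predictions = tibble::tibble(date = test$date,
                                      forecast = as.numeric(preds)),
         mtry = mtry, kept = tr$keep,
         dropped = setdiff(predictor_columns(train), tr$keep),
         seed = seed),
    class = "ward_rf"
  )
}

#' Permutation feature importance of a fitted random forest
#'
#' Ranks every predictor column by the permutation importance recorded
#' during the [rf_forecast()] fit, in descending order, labelled with its
#' ward/patient column group. Predictors dropped before fitting (zero
#' variance) appear with importance 0, so the ranking always covers the full
#' predictor set.
#'
#' @param fit A `ward_rf` object.
#' @param vocab Vocabulary used to label column groups.
#' @return A tibble with columns `rank`, `column`, `group`, `importance`.
#' @export
feature_importance <- function(fit, vocab = ward_vocab()) {
  if (!inherits(fit, "ward_rf") || is.null(fit$model))
    abort("`fit` must be a fitted ward_rf object.",
          class = "wardflow_validation_error")
  imp <- fit$model$variable.importance
  if (is.null(imp))
    abort("Model was fitted without permutation importance.",
          class = "wardflow_validation_error")
  all_imp <- c(imp, setNames(rep(0, length(fit$dropped)), fit$dropped))
  man <- feature_manifest(vocab)
  tibble::tibble(column = names(all_imp), importance = as.numeric(all_imp)) |>
    dplyr::left_join(man[c("column", "group")], by = "column") |>
    dplyr::arrange(dplyr::desc(.data$importance)) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("rank", "column", "group", "importance")
}

#' Support-vector-regression forecaster over the feature matrix
#'
#' Fits an epsilon-insensitive support-vector regression with an RBF kernel
#' on the training block and predicts every test row. Predictors are
#' standardised using training-set means and standard deviations only. The
#' penalty `C`, tube width `epsilon` and kernel bandwidth `gamma` are chosen
#' by grid search minimising one-step RMSE on the last 20% of training rows
#' (fitting on the earlier 80%); the winning triple is then refit on the full
#' training block. Ties are broken deterministically toward smaller `C`,
#' then smaller `epsilon`, then smaller `gamma`.
#'
#' @param train,test `ward_features` tibbles; training dates must strictly
#'   precede test dates.
#' @param C_grid,epsilon_grid Grids for the penalty and tube parameters.
#' @param gamma_grid Bandwidth grid; defaults to `1/(2P)` for `P`
#'   standardised predictors, plus one decade either side.
#' @param validation_frac Fraction of training rows held out for the grid
#'   search.
#' @return An object of class `ward_svr`: list with the fitted `e1071::svm`
#'   model, `predictions` (tibble `date`, `forecast`), the chosen
#'   `C`/`epsilon`/`gamma`, scaling statistics and kept/dropped predictors.
#' @export
svr_forecast <- function(train, test,
                         C_grid = c(0.1, 1, 10, 100),
                         epsilon_grid = c(0.1, 0.5, 1, 2),
                         gamma_grid = NULL, validation_frac = 0.2) {
  check_time_split(train, test)
  tr <- prepare_xy(train)
  te_x <- as.matrix(test[predictor_columns(test)])[, tr$keep, drop = FALSE]
  ctr <- colMeans(tr$x)
  scl <- apply(tr$x, 2, sd)
  scl[scl == 0] <- 1
  xs <- scale(tr$x, center = ctr, scale = scl)
  te_xs <- scale(te_x, center = ctr, scale = scl)
  p <- ncol(xs)
  gamma_grid <- gamma_grid %||% (1 / (2 * p) * c(0.1, 1, 10))

  n <- nrow(xs)
  n_val <- max(1L, floor(n * validation_frac))
  fit_idx <- seq_len(n - n_val)
  val_idx <- (n - n_val + 1L):n

  grid <- tidyr::expand_grid(C = C_grid, epsilon = epsilon_grid,
                             gamma = gamma_grid)
  grid$rmse <- purrr::pmap_dbl(grid, function(C, epsilon, gamma) {
    m <- e1071::svm(x = xs[fit_idx, , drop = FALSE], y = tr$y[fit_idx],
                    type = "eps-regression", kernel = "radial",
                    cost = C, epsilon = epsilon, gamma = gamma,
                    scale = FALSE, fitted = FALSE)
    f <- svm_predict_safe(m, xs[val_idx, , drop = FALSE], tr$y[fit_idx])
    sqrt(mean((tr$y[val_idx] - f)^2))
  })
  best <- grid |>
    dplyr::arrange(.data$rmse, .data$C, .data$epsilon, .data$gamma) |>
    dplyr::slice(1)
  model <- e1071::svm(x = xs, y = tr$y, type = "eps-regression",
                      kernel = "radial", cost = best$C,
                      epsilon = best$epsilon, gamma = best$gamma,
                      scale = FALSE, fitted = FALSE)
  preds <- svm_predict_safe(model, te_xs, tr$y)
  structure(
    list(model = model,
         predictions = tibble::tibble(date = test$date, forecast = preds),
         C = best$C, epsilon = best$epsilon, gamma = best$gamma,
         center = ctr, scale = scl, kept = tr$keep, train_mean = mean(tr$y),
         dropped = setdiff(predictor_columns(train), tr$keep),
         grid = grid),
    class = "ward_svr"
  )
}

# With an epsilon tube wider than the whole response range every residual is
# loss-free, libsvm keeps no support vectors, and its predict() refuses to
# run; the implied fit is any constant inside the tube -- use the training
# mean.
svm_predict_safe <- function(model, x, y_train) {
  if (model$tot.nSV == 0L) return(rep(mean(y_train), nrow(x)))
  as.numeric(predict(model, x))
}

check_time_split <- function(train, test) {
  if (nrow(train) == 0L || nrow(test) == 0L)
    abort("`train` and `test` must both be nonempty.",
          class = "wardflow_validation_error")
  if (max(train$date) >= min(test$date))
    abort("All training rows must strictly precede all test rows.",
          class = "wardflow_validation_error")
  invisible(TRUE)
}
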