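test_that("trend of a constant sequence is the constant", {
  expect_equal(trend_feature(rep(6, 6)), 6.0, tolerance = 1e-6)
})

test_that("trend extrapolates an exactly linear sequence", {
  expect_lt(abs(trend_feature(c(2, 4, 6, 8, 10, 12)) - 14), 0.5)
})

test_that("trend of a noisy constant stays near the constant", {
  set.seed(31)
  c0 <- 8
  y <- c0 + rnorm(50, sd = 1)
  expect_lt(abs(trend_feature(y) - c0), 3 * 1 / sqrt(50) * 3)
})

test_that("trend falls back to the mean below five observations", {
  expect_equal(trend_feature(c(3, 5, 7)), 5)
  expect_error(trend_feature(numeric(0)), class = "wardflow_validation_error")
})

test_that("patient-level counts: empty ward gives 87 zeros and LOS 0", {
  counts <- patient_level_counts(make_visits(character(0), character(0)),
                                 as.Date("2020-01-01"))
  expect_length(counts, 88L)
  expect_true(all(counts == 0))
})

test_that("patient-level counts concentrate on the observed categories", {
  d0 <- as.Date("2020-01-01")
  roster <- make_visits(rep(d0, 3), rep(d0 + 5, 3), referral = "REF_01")
  counts <- patient_level_counts(roster, d0 + 1)
  expect_equal(unname(counts["n_REF_01"]), 3)
  expect_equal(sum(counts[paste0("n_", ward_vocab()$referral)]), 3)
  expect_equal(unname(counts["mean_elapsed_los"]), 2)  # entered yesterday
})

test_that("out-of-vocabulary roster values are an error", {
  d0 <- as.Date("2020-01-01")
  roster <- make_visits(d0, d0 + 3)
  roster$referral <- "REF_99"
  expect_error(patient_level_counts(roster, d0 + 1), regexp = "REF_99",
               class = "wardflow_validation_error")
})

test_that("partition identities: each attribute's counts sum to the roster size", {
  fx <- sim_fixture(n_days = 160, seed = 14)
  vocab <- ward_vocab()
  set.seed(2)
  for (d in sample(fx$daily$date[30:160], 25)) {
    d <- as.Date(d, origin = "1970-01-01")
    roster <- ward_roster(fx$visits, d)
    counts <- patient_level_counts(roster, d)
    for (att in c("referral", "patient_class", "age_band", "admission_type",
                  "wards_visited")) {
      expect_equal(sum(counts[paste0("n_", vocab[[att]])]), nrow(roster))
    }
  }
})

test_that("feature matrix has 20 ward-level and 88 patient-level predictors", {
  fx <- sim_fixture(n_days = 100, seed = 4)
  fm <- build_feature_matrix(fx$visits, daily = fx$daily)
  man <- attr(fm, "manifest")
  preds <- setdiff(names(fm), c("date", "target"))
  expect_length(preds, 108L)
  expect_equal(sum(man$group == "ward"), 20L)
  expect_equal(sum(man$group == "patient"), 88L)
  expect_identical(preds, man$column)
  expect_equal(nrow(fm), 100L - 21L)
  expect_true(all(fm$dow %in% 1:7) && all(fm$month %in% 1:12))
})

test_that("lag columns equal direct series lookups", {
  fx <- sim_fixture(n_days = 150, seed = 16)
  fm <- build_feature_matrix(fx$visits, daily = fx$daily)
  set.seed(3)
  for (j in sample(nrow(fm), 50)) {
    d <- fm$date[j]
    i <- which(fx$daily$date == d)
    expect_equal(fm$dis_lag_14[j], fx$daily$discharges[i - 14])
    expect_equal(fm$dis_lag_21[j], fx$daily$discharges[i - 21])
    expect_equal(fm$dis_lag_1[j], fx$daily$discharges[i - 1])
    expect_equal(fm$adm_lag_7[j], fx$daily$admissions[i - 7])
    expect_equal(fm$occ_lag_1[j], fx$daily$occupancy[i - 1])
    expect_equal(fm$target[j], fx$daily$discharges[i])
  }
})

test_that("roster partitions in the matrix sum to previous-day occupancy", {
  fx <- sim_fixture(n_days = 120, seed = 18)
  fm <- build_feature_matrix(fx$visits, daily = fx$daily)
  vocab <- ward_vocab()
  ref_sum <- rowSums(fm[paste0("n_", vocab$referral)])
  cls_sum <- rowSums(fm[paste0("n_", vocab$patient_class)])
  age_sum <- rowSums(fm[paste0("n_", vocab$age_band)])
  expect_equal(ref_sum, fm$occ_lag_1, ignore_attr = TRUE)
  expect_equal(cls_sum, fm$occ_lag_1, ignore_attr = TRUE)
  expect_equal(age_sum, fm$occ_lag_1, ignore_attr = TRUE)
})

test_that("an all-zero discharge series zeroes lags and trend", {
  d0 <- as.Date("2021-01-01")
  # one long-stayer so the series is well-defined but nobody leaves in range
  v <- make_visits(d0, d0 + 400)
  daily <- derive_daily_series(v, c(d0, d0 + 59))
  fm <- build_feature_matrix(v, daily = daily)
  dis_cols <- c(sprintf("dis_lag_%d", 1:7), "dis_lag_14", "dis_lag_21", "trend")
  expect_true(all(as.matrix(fm[dis_cols]) == 0))
})

test_that("a too-short series is refused", {
  fx <- sim_fixture(n_days = 30, seed = 2)
  short <- fx$daily[1:20, ]
  expect_error(build_feature_matrix(fx$visits, daily = short),
               class = "wardflow_validation_error")
})

test_that("features are unchanged when future data is truncated away", {
  fx <- sim_fixture(n_days = 90, seed = 23)
  fm <- build_feature_matrix(fx$visits, daily = fx$daily)
  for (j in c(10L, 40L, 68L)) {
    d <- fm$date[j]
    cutoff <- d - 1L
    daily_t <- fx$daily[fx$daily$date <= cutoff, ]
    visits_t <- fx$visits[fx$visits$entry_date <= cutoff, ]
    open <- visits_t$exit_date > cutoff
    visits_t$exit_date[open] <- cutoff + 10000L
    row_t <- build_feature_matrix(visits_t, daily = daily_t, dates = d)
    preds <- setdiff(names(fm), c("date", "target"))
    expect_equal(as.numeric(row_t[1, preds]), as.numeric(fm[j, preds]))
  }
})

test_that("the manifest can be written as YAML", {
  fx <- sim_fixture(n_days = 60, seed = 2)
  fm <- build_feature_matrix(fx$visits, daily = fx$daily)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_feature_manifest(fm, path)
  man <- yaml::read_yaml(path)
  expect_length(man, 108L)
  expect_equal(man[[1]]$column, "dow")
})
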