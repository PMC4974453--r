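base_date <- as.Date("2020-03-01")

raw_fixture <- function() {
  list(
    patients = tibble::tibble(
      patient_id = c("P1", "P2", "P3"),
      age = c(70, 45, 82),
      gender = c("F", "M", "F")),
    ward_stay = tibble::tibble(
      admission_id = c("A1", "A2", "A3"),
      ward = "HW5",
      entry_time = as.POSIXct(base_date, tz = "UTC") + c(9, 10, 11) * 3600,
      exit_time = as.POSIXct(base_date + c(2, 3, 1), tz = "UTC") + 14 * 3600,
      bed_id = "BED_01"),
    admissions = tibble::tibble(
      patient_id = c("P1", "P2", "P3"),
      admission_id = c("A1", "A2", "A3"),
      admit_time = as.POSIXct(base_date, tz = "UTC") + c(9, 10, 11) * 3600,
      discharge_time = as.POSIXct(base_date + c(2, 3, 1), tz = "UTC") + 14 * 3600,
      patient_class = c("PC_01", "PC_02", "PC_01"),
      admission_type = c("AT_01", "AT_01", "AT_02"),
      referral = c("REF_01", "REF_05", "REF_01"))
  )
}

test_that("a well-formed three-visit fixture yields three visit records", {
  visits <- read_ward_tables(raw_fixture())
  expect_equal(nrow(visits), 3L)
  expect_setequal(visits$admission_id, c("A1", "A2", "A3"))
  expect_equal(visits$n_prior_wards, rep(0L, 3))
})

test_that("a ward exit before entry is an error naming the admission", {
  raw <- raw_fixture()
  raw$ward_stay$exit_time[2] <- raw$ward_stay$entry_time[2] - 3600
  expect_error(read_ward_tables(raw), regexp = "A2",
               class = "wardflow_validation_error")
})

test_that("missing schema columns raise a schema error", {
  raw <- raw_fixture()
  raw$admissions$referral <- NULL
  expect_error(read_ward_tables(raw), regexp = "referral",
               class = "wardflow_schema_error")
})

test_that("missing categoricals map to UNKNOWN; out-of-vocabulary rows are rejected", {
  raw <- raw_fixture()
  raw$admissions$referral[1] <- NA
  raw$admissions$patient_class[2] <- "NOT_A_CLASS"
  expect_warning(visits <- read_ward_tables(raw), regexp = "rejected")
  expect_equal(nrow(visits), 2L)
  expect_equal(visits$referral[visits$admission_id == "A1"], "UNKNOWN")
  rejects <- attr(visits, "rejects")
  expect_equal(rejects$admission_id, "A2")
})

test_that("simulated tables round-trip through CSV with zero rejects", {
  cfg <- sim_config(n_days = 120, seed = 3)
  tabs <- simulate_ward(cfg)
  dir <- withr::local_tempdir()
  write_ward_tables(tabs, dir)
  expect_no_warning(visits_csv <- read_ward_tables(dir))
  visits_mem <- read_ward_tables(tabs)
  expect_equal(nrow(visits_csv), nrow(tabs$admissions))
  expect_equal(visits_csv$ward_entry, visits_mem$ward_entry)
  expect_equal(visits_csv$referral, visits_mem$referral)
  expect_equal(visits_csv$n_prior_wards, visits_mem$n_prior_wards)
})

test_that("single-visit bookkeeping: enter day 1, exit day 3", {
  v <- make_visits(base_date, base_date + 2)
  daily <- derive_daily_series(v, c(base_date, base_date + 2))
  expect_equal(daily$discharges, c(0L, 0L, 1L))
  expect_equal(daily$admissions, c(1L, 0L, 0L))
  expect_equal(daily$occupancy, c(1L, 1L, 0L))
})

test_that("no visits give an all-zero series over the requested range", {
  daily <- derive_daily_series(make_visits(character(0), character(0)),
                               c(base_date, base_date + 9))
  expect_equal(nrow(daily), 10L)
  expect_true(all(daily$discharges == 0 & daily$admissions == 0 &
                    daily$occupancy == 0))
})

test_that("occupancy equals a brute-force membership count every day", {
  fx <- sim_fixture(n_days = 150, seed = 8)
  brute <- vapply(fx$daily$date, function(d)
    sum(fx$visits$entry_date <= d & fx$visits$exit_date > d), integer(1))
  expect_equal(fx$daily$occupancy, brute)
})

test_that("conservation o_t = o_{t-1} + a_t - y_t holds exactly", {
  fx <- sim_fixture(n_days = 300, seed = 12)
  d <- fx$daily
  expect_equal(diff(d$occupancy), (d$admissions - d$discharges)[-1])
})

test_that("total discharges equal visits exiting inside the range", {
  fx <- sim_fixture(n_days = 200, seed = 21)
  rng <- range(fx$daily$date)
  expect_equal(sum(fx$daily$discharges),
               sum(fx$visits$exit_date >= rng[1] & fx$visits$exit_date <= rng[2]))
})

test_that("roster matches occupancy and the half-open exit convention", {
  fx <- sim_fixture(n_days = 120, seed = 5)
  expect_equal(nrow(ward_roster(fx$visits, min(fx$visits$entry_date) - 1)), 0L)
  set.seed(1)
  for (d in sample(fx$daily$date, 30)) {
    d <- as.Date(d, origin = "1970-01-01")
    expect_equal(nrow(ward_roster(fx$visits, d)),
                 fx$daily$occupancy[fx$daily$date == d])
  }
  # a patient exiting at 09:00 on day D is not in the end-of-day-D roster
  v <- make_visits(base_date, base_date + 2, exit_hour = 9L)
  expect_equal(nrow(ward_roster(v, base_date + 2)), 0L)
  expect_equal(nrow(ward_roster(v, base_date + 1)), 1L)
})
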