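#' Read and validate the raw three-table ward schema
#'
#' Joins the `patients`, `ward_stay` and `admissions` tables into one visit
#' record per stay on the study ward, validates it, and derives the
#' categorical attributes the feature builder needs (age band, number of
#' wards visited). Accepts either a directory containing `patients.csv`,
#' `ward_stay.csv`, `admissions.csv` (as written by [write_ward_tables()]) or
#' an in-memory `ward_tables` object.
#'
#' Validation rules:
#' * a ward exit earlier than the ward entry is a hard error naming the
#'   offending admission IDs;
#' * missing categorical values are mapped to an explicit `"UNKNOWN"` level
#'   (never dropped -- patient-level predictors are counts over the ward
#'   roster and must not silently shrink);
#' * non-missing categorical values outside the declared vocabulary cause the
#'   row to be rejected; rejected rows are reported via a warning and kept in
#'   the `"rejects"` attribute of the result.
#'
#' @param x Directory path or `ward_tables` list.
#' @param ward Ward name selecting the study ward's stays.
#' @param vocab Declared vocabulary, see [ward_vocab()].
#' @return A tibble of visits (class `ward_visits`) with columns
#'   `patient_id`, `admission_id`, `age`, `gender`, `ward_entry`, `ward_exit`
#'   (POSIXct), `entry_date`, `exit_date` (Date), `patient_class`,
#'   `admission_type`, `referral`, `n_prior_wards`, `age_band`,
#'   `wards_visited`. Attribute `"rejects"` holds the per-row rejection
#'   report (possibly empty).
#' @export
#' @examples
#' tabs <- simulate_ward(sim_config(n_days = 40, seed = 7))
#' visits <- read_ward_tables(tabs)
#' nrow(visits)
read_ward_tables <- function(x, ward = "HW5", vocab = ward_vocab()) {
  if (is.character(x) && length(x) == 1L) {
    paths <- file.path(x, c("patients.csv", "ward_stay.csv", "admissions.csv"))
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0L)
      abort(paste0("Missing input file(s): ", paste(missing, collapse = ", ")),
            class = "wardflow_schema_error")
    tables <- list(
      patients = readr::read_csv(paths[1], show_col_types = FALSE),
      ward_stay = readr::read_csv(paths[2], show_col_types = FALSE),
      admissions = readr::read_csv(paths[3], show_col_types = FALSE)
    )
  } else if (inherits(x, "ward_tables") || (is.list(x) &&
             all(c("patients", "ward_stay", "admissions") %in% names(x)))) {
    tables <- x
    ward <- attr(x, "ward") %||% ward
  } else {
    abort("`x` must be a directory path or a ward_tables list.",
          class = "wardflow_schema_error")
  }

  required <- list(
    patients = c("patient_id", "age", "gender"),
    ward_stay = c("admission_id", "ward", "entry_time", "exit_time"),
    admissions = c("patient_id", "admission_id", "admit_time",
                   "discharge_time", "patient_class", "admission_type",
                   "referral")
  )
  for (nm in names(required)) {
    miss <- setdiff(required[[nm]], names(tables[[nm]]))
    if (length(miss) > 0L)
      abort(sprintf("Table `%s` is missing column(s): %s",
                    nm, paste(miss, collapse = ", ")),
            class = "wardflow_schema_error")
  }

  stays <- tables$ward_stay
  index_stays <- dplyr::filter(stays, .data$ward == !!ward)
  if (nrow(index_stays) == 0L)
    abort(sprintf("No ward_stay rows for ward '%s'.", ward),
          class = "wardflow_schema_error")

  # Wards visited during the admission, the study ward included.
  n_wards <- stays |>
    dplyr::group_by(.data$admission_id) |>
    dplyr::summarise(n_wards_total = dplyr::n_distinct(.data$ward),
                     n_stays_total = dplyr::n(), .groups = "drop")

  visits <- index_stays |>
    dplyr::select("admission_id", ward_entry = "entry_time",
                  ward_exit = "exit_time") |>
    dplyr::inner_join(tables$admissions, by = "admission_id") |>
    dplyr::left_join(tables$patients, by = "patient_id") |>
    dplyr::left_join(n_wards, by = "admission_id")

  bad <- visits$ward_exit < visits$ward_entry
  if (any(bad))
    abort(paste0("ward_exit earlier than ward_entry for admission(s): ",
                 paste(visits$admission_id[bad], collapse = ", ")),
          class = "wardflow_validation_error")

  # Missing categoricals become an explicit level; out-of-vocabulary values
  # reject the row with a report.
  cat_cols <- c("gender", "patient_class", "admission_type", "referral")
  for (cc in cat_cols) {
    visits[[cc]] <- ifelse(is.na(visits[[cc]]), "UNKNOWN",
                           as.character(visits[[cc]]))
  }
  ok_level <- function(value, levels) value == "UNKNOWN" | value %in% levels
  reject_reason <- rep(NA_character_, nrow(visits))
  for (cc in cat_cols) {
    out <- !ok_level(visits[[cc]], vocab[[cc]])
    reject_reason[out & is.na(reject_reason)] <-
      sprintf("%s value outside vocabulary", cc)
  }
  rejects <- visits[!is.na(reject_reason), , drop = FALSE]
  if (nrow(rejects) > 0L) {
    rejects$reason <- reject_reason[!is.na(reject_reason)]
    warn(sprintf("%d visit row(s) rejected (out-of-vocabulary values); see attr(, 'rejects').",
                 nrow(rejects)))
  }
  visits <- visits[is.na(reject_reason), , drop = FALSE]

  visits <- visits |>
    dplyr::mutate(
      entry_date = as.Date(.data$ward_entry, tz = "UTC"),
      exit_date = as.Date(.data$ward_exit, tz = "UTC"),
      n_prior_wards = pmax(dplyr::coalesce(.data$n_stays_total, 1L) - 1L, 0L),
      age = dplyr::coalesce(.data$age, NA_real_),
      age_band = ifelse(is.na(.data$age), "UNKNOWN",
                        age_to_band(.data$age, vocab)),
      wards_visited = wards_to_band(.data$n_prior_wards + 1L, vocab)
    ) |>
    dplyr::select("patient_id", "admission_id", "age", "gender", "ward_entry",
                  "ward_exit", "entry_date", "exit_date", "patient_class",
                  "admission_type", "referral", "n_prior_wards", "age_band",
                  "wards_visited") |>
    dplyr::arrange(.data$ward_entry, .data$admission_id)

  structure(visits, class = c("ward_visits", class(tibble::as_tibble(visits))),
            rejects = tibble::as_tibble(rejects), vocab = vocab)
}

#' Derive daily discharge, admission and occupancy series
#'
#' Collapses visit records to one row per calendar day: `discharges` counts
#' visits whose ward exit falls on that date, `admissions` counts ward
#' entries, and `occupancy` is the end-of-day census under the half-open stay
#' convention `[entry_date, exit_date)` -- a patient discharged at any time
#' on day D is not part of day D's census, so a turned-over bed is never
#' counted twice. Days without events carry zeros. The conservation identity
#' `o_t = o_{t-1} + a_t - y_t` holds exactly on every derived series.
#'
#' @param visits A `ward_visits` tibble (or any tibble with `entry_date` and
#'   `exit_date` columns).
#' @param date_range Optional length-2 `Date` vector; defaults to the full
#'   span of the visits. Visits outside the range still contribute to
#'   occupancy inside it.
#' @return A tibble (class `ward_daily`) with columns `date`, `discharges`,
#'   `admissions`, `occupancy`.
#' @export
#' @examples
#' v <- tibble::tibble(entry_date = as.Date("2020-01-01"),
#'                     exit_date = as.Date("2020-01-03"))
#' derive_daily_series(v, as.Date(c("2020-01-01", "2020-01-03")))
derive_daily_series <- function(visits, date_range = NULL) {
  if (is.null(date_range)) {
    if (nrow(visits) == 0L)
      abort("Empty visits need an explicit `date_range`.",
            class = "wardflow_validation_error")
    date_range <- c(min(visits$entry_date), max(visits$exit_date))
  }
  date_range <- as.Date(date_range)
  if (length(date_range) != 2L || date_range[2] < date_range[1])
    abort("`date_range` must be two ordered dates.",
          class = "wardflow_validation_error")
  dates <- seq(date_range[1], date_range[2], by = "day")
  n <- length(dates)
  idx <- function(d) as.integer(d - date_range[1]) + 1L

  a <- tabulate(idx(visits$entry_date)[visits$entry_date >= date_range[1] &
                                         visits$entry_date <= date_range[2]], n)
  y <- tabulate(idx(visits$exit_date)[visits$exit_date >= date_range[1] &
                                        visits$exit_date <= date_range[2]], n)
  # End-of-day census: entered on or before t, exit strictly after t.
  # Events before the range start contribute a constant baseline; events
  # after the range end never count.
  cum_by_day <- function(d) {
    i <- idx(d)
    sum(i <= 0L) + cumsum(tabulate(i[i >= 1L & i <= n], n))
  }
  o <- cum_by_day(visits$entry_date) - cum_by_day(visits$exit_date)

  structure(
    tibble::tibble(date = dates, discharges = as.integer(y),
                   admissions = as.integer(a), occupancy = as.integer(o)),
    class = c("ward_daily", class(tibble::tibble()))
  )
}

#' Patients in the ward at the end of a given day
#'
#' Returns the visit records of patients present at the end-of-day census of
#' `date`, using the same half-open membership rule as occupancy in
#' [derive_daily_series()]: `entry_date <= date < exit_date`. Consequently
#' `nrow(ward_roster(visits, d))` equals the derived occupancy on `d`.
#'
#' @param visits A `ward_visits` tibble.
#' @param date A single `Date`.
#' @return The subset of `visits` in ward at end of `date`.
#' @export
ward_roster <- function(visits, date) {
  date <- as.Date(date)
  stopifnot(length(date) == 1L)
  visits[visits$entry_date <= date & visits$exit_date > date, , drop = FALSE]
}
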