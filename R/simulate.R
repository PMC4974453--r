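#' Configuration for the ward patient-flow simulator
#'
#' Builds a validated configuration object for [simulate_ward()]. The defaults
#' describe an open recovery ward of the kind studied in the Australian
#' patient-flow literature: roughly 8.6 admissions per day over five calendar
#' years, a geometric length-of-stay law with median 3 days and mean about
#' 4.3 days, a pronounced weekly discharge rhythm (Friday peak, weekend
#' trough), a mild annual sinusoid in admissions, and no long-term trend.
#'
#' Admissions are a nonhomogeneous Poisson process: the daily rate is
#' `base_admission_rate` times a weekday multiplier times
#' `1 + monthly_amplitude * sin(2 * pi * yday / 365.25)`. Discharge is not an
#' i.i.d. length-of-stay draw: each in-ward patient faces a daily discharge
#' hazard `los_base_hazard` times the weekday multiplier of the candidate
#' discharge day, starting the day after ward entry. This couples realised
#' length of stay to discharge weekday, which is what produces the weekend
#' effect in the simulated series. Both multiplier vectors are rescaled to
#' mean 1 so the base rate and base hazard keep their marginal meaning.
#'
#' @param n_days Number of simulated calendar days (default 1826, i.e. five
#'   years including one leap year).
#' @param start_date First simulated day (`Date` or string).
#' @param base_admission_rate Mean admissions per day before modulation.
#' @param dow_admission_multipliers Seven nonnegative reals, Monday..Sunday,
#'   modulating the admission rate by weekday.
#' @param dow_discharge_hazard_multipliers Seven nonnegative reals,
#'   Monday..Sunday, modulating the daily discharge hazard by weekday. Setting
#'   a day to 0 makes discharge on that weekday impossible.
#' @param monthly_amplitude Amplitude in `[0, 1)` of the annual sinusoidal
#'   modulation of admissions.
#' @param los_base_hazard Baseline daily discharge probability; `1/h` is the
#'   mean of the implied geometric length-of-stay law before weekday
#'   modulation. The default `1/4.26` yields realised median 3 and mean close
#'   to 4.26 days under the default weekday profile.
#' @param category_probs Named list of probability vectors over the
#'   [ward_vocab()] levels: `admission_type` (5), `referral` (49),
#'   `patient_class` (21), `gender` (2), `age_band` (8), `wards_visited` (4).
#'   Each must sum to 1. Defaults are mildly skewed draws fixed once.
#' @param prob_repeat_patient Probability a visit belongs to a previously seen
#'   patient rather than a new one (gives visits > unique patients).
#' @param seed Integer RNG seed; fixed default `20100101` so that
#'   `simulate_ward(sim_config())` is fully reproducible.
#' @return An object of class `ward_sim_config` (a named list).
#' @seealso [simulate_ward()]
#' @export
#' @examples
#' cfg <- sim_config(n_days = 100)
#' cfg$base_admission_rate
sim_config <- function(n_days = 1826L,
                       start_date = as.Date("2010-01-01"),
                       base_admission_rate = 8.6,
                       dow_admission_multipliers =
                         c(1.15, 1.10, 1.05, 1.05, 1.10, 0.80, 0.75),
                       dow_discharge_hazard_multipliers =
                         c(1.05, 1.00, 1.00, 1.10, 1.70, 0.40, 0.30),
                       monthly_amplitude = 0.15,
                       los_base_hazard = 1 / 4.26,
                       category_probs = default_category_probs(),
                       prob_repeat_patient = 0.126,
                       seed = 20100101L) {
  cfg <- list(
    n_days = as.integer(n_days),
    start_date = as.Date(start_date),
    base_admission_rate = base_admission_rate,
    dow_admission_multipliers = as.numeric(dow_admission_multipliers),
    dow_discharge_hazard_multipliers =
      as.numeric(dow_discharge_hazard_multipliers),
    monthly_amplitude = monthly_amplitude,
    los_base_hazard = los_base_hazard,
    category_probs = category_probs,
    prob_repeat_patient = prob_repeat_patient,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "ward_sim_config")
}

#' @rdname sim_config
#' @export
default_sim_config <- function() sim_config()

# Fixed, mildly skewed probability vectors over the synthetic vocabularies.
# Age-band weights put most mass above 45 (cohort mean age in the mid 60s);
# gender matches a 55/45 female/male split; most admissions touch one ward.
default_category_probs <- function() {
  vocab <- ward_vocab()
  skewed <- function(n) {
    w <- 0.85^(seq_len(n) - 1)
    w / sum(w)
  }
  list(
    admission_type = skewed(5),
    referral       = skewed(49),
    patient_class  = skewed(21),
    gender         = c(0.552, 0.448),
    age_band       = c(0.03, 0.05, 0.08, 0.16, 0.22, 0.24, 0.16, 0.06),
    wards_visited  = c(0.55, 0.30, 0.10, 0.05)
  )
}

validate_sim_config <- function(cfg) {
  if (!is.finite(cfg$n_days) || cfg$n_days < 1L)
    abort("`n_days` must be a positive integer.", class = "wardflow_config_error")
  if (!is.finite(cfg$base_admission_rate) || cfg$base_admission_rate <= 0)
    abort("`base_admission_rate` must be > 0.", class = "wardflow_config_error")
  for (nm in c("dow_admission_multipliers", "dow_discharge_hazard_multipliers")) {
    m <- cfg[[nm]]
    if (length(m) != 7L || any(!is.finite(m)) || any(m < 0))
      abort(sprintf("`%s` must be 7 nonnegative reals (Mon..Sun).", nm),
            class = "wardflow_config_error")
  }
  if (cfg$monthly_amplitude < 0 || cfg$monthly_amplitude >= 1)
    abort("`monthly_amplitude` must lie in [0, 1).", class = "wardflow_config_error")
  if (cfg$los_base_hazard <= 0 || cfg$los_base_hazard > 1)
    abort("`los_base_hazard` must lie in (0, 1].", class = "wardflow_config_error")
  vocab <- ward_vocab()
  expected_len <- lengths(vocab)
  for (nm in names(expected_len)) {
    p <- cfg$category_probs[[nm]]
    if (is.null(p) || length(p) != expected_len[[nm]])
      abort(sprintf("`category_probs$%s` must have length %d.", nm, expected_len[[nm]]),
            class = "wardflow_config_error")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      abort(sprintf("`category_probs$%s` must be a probability vector summing to 1.", nm),
            class = "wardflow_config_error")
  }
  invisible(cfg)
}

#' Simulate raw three-table ward patient-flow data
#'
#' Generates the three administrative tables a hospital database would hold
#' for a single ward -- `patients` (ID, age, gender), `ward_stay`
#' (admission ID, ward, entry/exit timestamps, bed) and `admissions`
#' (patient ID, admission ID, admit/discharge timestamps, patient class,
#' admission type, referral source) -- from a [sim_config()]. Output is
#' bit-identical for identical `(seed, config)`.
#'
#' Patients who visit other wards before the study ward get one `ward_stay`
#' row per prior ward, so the "number of wards visited" attribute is
#' derivable from the raw schema, as it would be in a real extract.
#' Timestamps have hour resolution; downstream analysis uses calendar dates
#' only.
#'
#' @param config A `ward_sim_config` from [sim_config()].
#' @param ward Name of the study ward in the `ward_stay` table.
#' @return An object of class `ward_tables`: a list of tibbles `patients`,
#'   `ward_stay`, `admissions`, with the config stored as attribute
#'   `"config"`.
#' @export
#' @examples
#' tabs <- simulate_ward(sim_config(n_days = 60, seed = 1))
#' names(tabs)
#' nrow(tabs$admissions)
simulate_ward <- function(config = sim_config(), ward = "HW5") {
  stopifnot(inherits(config, "ward_sim_config"))
  validate_sim_config(config)
  vocab <- ward_vocab(length(config$category_probs$admission_type))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  dates <- config$start_date + seq_len(config$n_days) - 1L
  dow <- iso_dow(dates)
  adm_mult <- config$dow_admission_multipliers /
    mean(config$dow_admission_multipliers)
  dis_mult <- config$dow_discharge_hazard_multipliers /
    mean(config$dow_discharge_hazard_multipliers)
  yday <- as.POSIXlt(dates)$yday
  season <- 1 + config$monthly_amplitude * sin(2 * pi * yday / 365.25)
  lambda <- config$base_admission_rate * adm_mult[dow] * season

  n_adm_day <- rpois(config$n_days, lambda)
  n_visits <- sum(n_adm_day)
  entry_date <- rep(dates, n_adm_day)

  # Daily discharge hazard: starting the day after entry, each day the
  # patient leaves with probability hazard * weekday multiplier. Capped at
  # 400 candidate days to bound the loop when weekend hazards are 0.
  los <- integer(n_visits)
  alive <- seq_len(n_visits)
  j <- 0L
  while (length(alive) > 0L && j < 400L) {
    j <- j + 1L
    d_j <- iso_dow(entry_date[alive] + j)
    p_j <- pmin(1, config$los_base_hazard * dis_mult[d_j])
    gone <- runif(length(alive)) < p_j
    los[alive[gone]] <- j
    alive <- alive[!gone]
  }
  los[alive] <- 400L  # pathological configs only; keeps exits finite
  exit_date <- entry_date + los

  # Patient identities with some repeat visitors.
  patient_of <- integer(n_visits)
  n_pat <- 0L
  repeat_draw <- runif(n_visits)
  for (i in seq_len(n_visits)) {
    if (n_pat > 0L && repeat_draw[i] < config$prob_repeat_patient) {
      patient_of[i] <- sample.int(n_pat, 1L)
    } else {
      n_pat <- n_pat + 1L
      patient_of[i] <- n_pat
    }
  }

  draw_cat <- function(levels, probs, n) {
    levels[sample.int(length(levels), n, replace = TRUE, prob = probs)]
  }
  cp <- config$category_probs
  admission_type <- draw_cat(vocab$admission_type, cp$admission_type, n_visits)
  referral <- draw_cat(vocab$referral, cp$referral, n_visits)
  patient_class <- draw_cat(vocab$patient_class, cp$patient_class, n_visits)
  wards_band <- sample.int(4L, n_visits, replace = TRUE, prob = cp$wards_visited)
  n_prior <- wards_band - 1L

  # Per-patient demographics (constant across repeat visits).
  pat_gender <- draw_cat(vocab$gender, cp$gender, n_pat)
  pat_band <- sample.int(8L, n_pat, replace = TRUE, prob = cp$age_band)
  band_lo <- c(0, 15, 30, 45, 60, 70, 80, 90)
  band_hi <- c(14, 29, 44, 59, 69, 79, 89, 100)
  pat_age <- floor(band_lo[pat_band] +
                     runif(n_pat) * (band_hi[pat_band] - band_lo[pat_band] + 1))

  entry_hour <- sample(0:23, n_visits, replace = TRUE)
  exit_hour <- sample(0:23, n_visits, replace = TRUE)
  to_ts <- function(date, hour) {
    as.POSIXct(as.numeric(as.POSIXct(date, tz = "UTC")) + hour * 3600,
               origin = "1970-01-01", tz = "UTC")
  }
  ward_entry <- to_ts(entry_date, entry_hour)
  ward_exit <- to_ts(exit_date, exit_hour)

  admission_id <- sprintf("ADM_%06d", seq_len(n_visits))
  patient_id <- sprintf("PAT_%06d", patient_of)

  # Index-ward stays plus one row per prior ward, in 6-hour blocks
  # immediately before the index entry.
  stay_rows <- list(tibble::tibble(
    admission_id = admission_id,
    ward = ward,
    entry_time = ward_entry,
    exit_time = ward_exit,
    bed_id = sprintf("BED_%02d", sample.int(80L, n_visits, replace = TRUE))
  ))
  has_prior <- which(n_prior > 0L)
  if (length(has_prior) > 0L) {
    idx <- rep(has_prior, n_prior[has_prior])
    k <- sequence(n_prior[has_prior])  # 1..n_prior within each admission
    back <- rep(n_prior[has_prior], n_prior[has_prior]) - k + 1L
    stay_rows[[2]] <- tibble::tibble(
      admission_id = admission_id[idx],
      ward = sprintf("WARD_%02d", sample.int(12L, length(idx), replace = TRUE)),
      entry_time = ward_entry[idx] - back * 6 * 3600,
      exit_time = ward_entry[idx] - (back - 1L) * 6 * 3600,
      bed_id = sprintf("BED_%02d", sample.int(80L, length(idx), replace = TRUE))
    )
  }
  ward_stay <- dplyr::bind_rows(stay_rows) |>
    dplyr::arrange(.data$admission_id, .data$entry_time)

  admissions <- tibble::tibble(
    patient_id = patient_id,
    admission_id = admission_id,
    admit_time = ward_entry - n_prior * 6 * 3600,
    discharge_time = ward_exit,
    patient_class = patient_class,
    admission_type = admission_type,
    referral = referral
  )

  patients <- tibble::tibble(
    patient_id = sprintf("PAT_%06d", seq_len(n_pat)),
    age = as.numeric(pat_age),
    gender = pat_gender
  )

  structure(
    list(patients = patients, ward_stay = ward_stay, admissions = admissions),
    class = "ward_tables", config = config, ward = ward
  )
}

#' Write the raw ward tables to CSV
#'
#' Writes `patients.csv`, `ward_stay.csv` and `admissions.csv` with ISO-8601
#' timestamps into `dir`, creating it if needed.
#'
#' @param tables A `ward_tables` object from [simulate_ward()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_ward_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "ward_tables"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(tables$patients, file.path(dir, "patients.csv"))
  readr::write_csv(tables$ward_stay, file.path(dir, "ward_stay.csv"))
  readr::write_csv(tables$admissions, file.path(dir, "admissions.csv"))
  invisible(dir)
}

#' @export
print.ward_tables <- function(x, ...) {
  cat("<ward_tables>\n")
  cat("  patients:  ", nrow(x$patients), " rows\n", sep = "")
  cat("  ward_stay: ", nrow(x$ward_stay), " rows\n", sep = "")
  cat("  admissions:", nrow(x$admissions), "rows\n")
  invisible(x)
}
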